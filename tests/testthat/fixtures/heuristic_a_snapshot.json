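{"exp1_best_S":5,"exp5_best_S":7,"exp1_vi_iterations":1194,"exp5_vi_iterations":1194}
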