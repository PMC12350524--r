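"s1","s2","order"
0,0,3
0,1,3
0,2,3
0,3,2
0,4,1
0,5,0
0,6,0
0,7,0
0,8,0
0,9,0
0,10,0
1,0,3
1,1,3
1,2,3
1,3,2
1,4,1
1,5,0
1,6,0
1,7,0
1,8,0
1,9,0
1,10,0
2,0,3
2,1,3
2,2,3
2,3,2
2,4,1
2,5,0
2,6,0
2,7,0
2,8,0
2,9,0
2,10,0
3,0,3
3,1,3
3,2,3
3,3,2
3,4,1
3,5,0
3,6,0
3,7,0
3,8,0
3,9,0
3,10,0
4,0,3
4,1,3
4,2,3
4,3,2
4,4,1
4,5,0
4,6,0
4,7,0
4,8,0
4,9,0
4,10,0
5,0,3
5,1,3
5,2,3
5,3,2
5,4,1
5,5,0
5,6,0
5,7,0
5,8,0
5,9,0
5,10,0
6,0,3
6,1,3
6,2,3
6,3,2
6,4,1
6,5,0
6,6,0
6,7,0
6,8,0
6,9,0
6,10,0
7,0,3
7,1,3
7,2,3
7,3,2
7,4,1
7,5,0
7,6,0
7,7,0
7,8,0
7,9,0
7,10,0
8,0,3
8,1,3
8,2,3
8,3,2
8,4,1
8,5,0
8,6,0
8,7,0
8,8,0
8,9,0
8,10,0
9,0,3
9,1,3
9,2,3
9,3,2
9,4,1
9,5,0
9,6,0
9,7,0
9,8,0
9,9,0
9,10,0
10,0,3
10,1,3
10,2,3
10,3,2
10,4,1
10,5,0
10,6,0
10,7,0
10,8,0
10,9,0
10,10,0
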