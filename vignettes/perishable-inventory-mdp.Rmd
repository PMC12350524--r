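---
title: "Exact and heuristic replenishment policies for perishable inventory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact and heuristic replenishment policies for perishable inventory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the computational approach

Perishable products — fresh food, blood platelets — become unusable a fixed
or random number of days after they are produced. A replenishment policy for
such stock must trade off shortages (unmet demand is lost), wastage (units
expiring unsold), holding and ordering costs, and the right decision depends
not just on how much stock is on hand but on its *age profile*. Modelled as a
Markov decision process (MDP) whose state records the stock split by
remaining useful life, the problem is solvable exactly by value iteration,
but the state space grows exponentially in the maximum useful life $m$, which
has historically confined exact solutions to very small instances.

`perishvi` implements a value-iteration solver built on a factorisation that
makes the Bellman backup embarrassingly parallel and cheap to tabulate: each
scenario declares a finite set of *random outcomes* $\omega \in \Omega$ (the
day's demand; the pair of issued quantities; demand plus the age profile of a
delivery) such that the transition is deterministic given the outcome,

$$V_{i+1}(s) \;=\; \max_{a \in \mathbb{A}} \sum_{\omega \in \Omega}
  P(\omega \mid s, a)\,\bigl[r_\omega + \gamma\, V_i(s'_\omega)\bigr],
  \qquad (r_\omega, s'_\omega) = T(s, a, \omega),$$

and the greedy policy is extracted from the converged values by the same
one-step lookahead with `arg max` in place of `max`. Everything a scenario
must provide — state, action and outcome enumerations, $T$, the outcome
probabilities, an initial value estimate and a convergence test — is the
`mdp_model()` contract; the three shipped scenarios are plug-ins to the same
solver, and user-defined problems can be too.

### Sweep semantics, batching and precision

The standard solver performs *Jacobi* sweeps: every state is updated against
the previous iterate, so the result is independent of update order. States
are processed in a padded `(device, batch, slot)` layout (`pad_states()`)
whose batch size and device count are a pure layout contract — the sweep
returns bit-identical values for every batching, which the test suite
asserts, and padding slots never touch real states. An *asynchronous*
(Gauss–Seidel) variant is also provided: within an iteration, later batches
see the updates of earlier batches. Its update order — ascending state
order in `batch_size` blocks — is a package choice (several orders are
admissible); it reaches the same fixed point, usually in fewer sweeps, and
the suite verifies fixed-point and policy agreement with the Jacobi solver.

All value arithmetic is in 64-bit floating point. The lead-time scenario in
particular runs for more than a thousand sweeps with a discount factor of
0.99; in single precision the convergence statistic can stagnate above any
reasonable tolerance, so no 32-bit path is offered.

### Convergence tests

Three stopping rules match the three problem classes:

* **Discounted sup-norm** (`convergence_sup_norm`): stop when
  $\max_s |V_{i+1}(s) - V_i(s)| < \theta$. Used by the lead-time scenario.
  At that point the sup-norm distance to $V^*$ is at most
  $\theta\gamma/(1-\gamma)$, which the tests check against small-instance
  fixed points computed by exhaustive policy enumeration.
* **Span** (`convergence_span`): for the undiscounted two-product problem,
  stop when $\max_s \Delta_i(s) - \min_s \Delta_i(s) < \theta$ with
  $\Delta_i = V_{i+1} - V_i$. The values drift without bound but the policy
  is determined by value *differences*; at convergence the common drift
  estimates the optimal gain (mean daily reward), which the suite checks
  against simulation.
* **Periodic span** (`convergence_periodic_span`): the platelet bank has
  weekday-periodic demand, so the span test is applied to the change over
  one full week, $\Delta^{(7)}_i = V_i - V_{i-7}$. Only a ring buffer of the
  last eight iterates is retained.

The tolerance $\theta$ defaults to `1e-4` in `vi_config()`. The reported
returns are of order $10^3$ and per-sweep value changes at the start of a
solve are of order $10^2$, so `1e-4` is conservative by several orders of
magnitude while keeping iteration counts modest (about 1,200 sweeps at
$\gamma = 0.99$); it is exposed so users can trade accuracy for time.
Ties in the `arg max` are broken toward the smallest action ordinal — the
smallest order quantity, lexicographic for two products — so extracted
policies are reproducible across numerically equivalent runs. The iteration
cap (default 5,000) flags non-convergence on the returned object rather than
erroring.

### Fast backup backends

The generic path compiles the model into flat tables of next-state indices
and rewards (outcome-fastest memory layout) consumed by a small C++ kernel.
Two scenarios additionally exploit structure, with test-asserted equality to
the generic backup:

* **Two products:** the next state is (aged stock, fresh arrivals) and the
  arrivals equal the order, so reshaping $V$ into an (aged stock) ×
  (order pair) matrix turns the expectation over outcomes into one sparse
  matrix product that serves *all* actions simultaneously. Issued-pair
  probabilities depend on the state only through the two stock totals and
  are cached by totals — a pure optimisation with identical results.
* **Platelet bank:** the transition does not depend on the action given the
  outcome (the order only shifts the arrival-profile probabilities and the
  fixed cost), so the backup factorises into a demand-weighted gather per
  weekday followed by two small dense products.

## The scenario models

### Lead time (single product, `scenario_a()`)

State: stock by remaining life (oldest first, each class in $[0, A_{\max}]$)
plus in-transit orders when the lead time $L > 1$; $(A_{\max}+1)^{m+L-1}$
states. Daily demand is gamma with mean $\mu$ and coefficient of variation
$c_v$ ($\sigma = \mu c_v$), rounded to the nearest integer (half-open
intervals, $d = 0$ taking $[0, \tfrac12)$) and truncated at $D_{\max}$ with
the residual upper-tail mass lumped into $D_{\max}$ — normalisation is then
exact, and with the required $D_{\max} \gg \mu + 5\sigma$ the lump is
negligible ($<10^{-15}$ at the default $\mu = 4$, $c_v = 0.5$,
$D_{\max} = 100$). Demand is issued FIFO or LIFO; units at remaining life 1
expire after issuing; survivors age; the due order arrives overnight and is
fresh. The reward is
$-(C_h \cdot \text{holding} + C_v \cdot \text{order} + C_s \cdot
\text{shortage} + C_w \cdot \text{expired})$, with holding charged on
end-of-day surviving stock only: the overnight arrival is not charged for
the day it arrives, and expired units are not held. This timing is pinned
down by the unit-conservation and reward-decomposition tests.

### Substitution (two products, `scenario_b()`)

Two products with common useful life, lead time one, independent Poisson
demands, and down-substitution: each customer with unmet product-B demand
accepts product A with probability $\rho$. Rather than enumerating (demand
A, demand B, acceptance draw) triples, the day's randomness is collapsed to
the *issued pair* $(h^a, h^b)$, $h^p \le m A^p_{\max}$ — the transition is
deterministic given it, and its distribution depends on the state only
through the stock totals. The marginalisation uses Poisson grids truncated
where the cumulative mass reaches $1 - 10^{-10}$ (residual lumped at the
truncation point, keeping normalisation exact). Within a day product A
demand is filled first, then accepted substitution demand from the
remaining product A stock, all FIFO; a substituted sale counts in $h^a$ and
earns product A's revenue $C_r^a$, which is forced by the reward depending
on the outcome pair alone. The problem is undiscounted with reward
$C_r^a h^a + C_r^b h^b - C_v^a a^a - C_v^b a^b$; the value function is
initialised at the state's expected one-day sales revenue, which
substantially shortens the span-test solve (about a dozen sweeps at the
default calibration).

### Platelet bank (`scenario_c()`)

A hospital blood bank ordering platelets daily: demand has an independent
truncated negative-binomial distribution per weekday; orders arrive
instantly but with *uncertain remaining shelf life*, drawn from a
multinomial over $1..m$ whose probabilities may depend on the order quantity
(endogenous uncertainty); issuing is oldest-unit-first-out; and each
non-zero order incurs a fixed cost $C_f$ on top of holding, shortage and
wastage costs, with holding charged also on the units expiring that day.
The state is (weekday, stock at remaining life $1..m-1$) — nothing observed
can be at full life because ageing happens before the next review — and
each age class is capped at $A_{\max}$: delivered units that would breach
the cap are rejected at the door, at no cost. That per-class rejection rule
is one of several ways to impose the capacity that makes the state space
$7(A_{\max}+1)^{m-1}$; the alternative (accept, then discard end-of-day as
wastage) would change optimal policies and is deliberately not implemented.
Demand truncation uses $D_{\max} = A_{\max} = 20$, the value forced by the
outcome-space size $(D_{\max}+1)\binom{A_{\max}+m}{m}$; both are
configurable.

The default weekday demand calibration (`platelet_weekday_demand()`)
reflects the strong weekday pattern of hospital platelet use, including the
Saturday trough. The default shelf-life-on-arrival tables
(`platelet_life_on_arrival()`) are **synthetic**: a fresh-leaning profile
(probability of remaining life $k$ proportional to $k^2$) for the exogenous
case, and for the endogenous case a mixture shifting toward older stock as
the order grows. They set a realistic shape — most units arrive usable for
two or three more days, larger orders are filled with older stock — but are
not a fit to any blood service's records, so headline returns computed under
them are specific to this calibration. Users studying a real bank should
supply their own tables (a vector, an order-indexed matrix, or a function).

## Simulators, KPIs and policy comparison

Each scenario carries a seeded stochastic simulator that *shares the
transition code* with the solver (a forced step is the transition, asserted
in the tests). A rollout starts from empty inventory (weekday 0 for the
platelet bank), runs a 100-day warm-up that is excluded from scoring — long
enough that the stationary age profile is reached within a couple of
multiples of $m$ — and then a scored 365-day horizon. The per-rollout
return is $\sum_{k=0}^{364} \gamma^k R_{k+1}$ from the end of warm-up, using
the scenario's own $\gamma$. KPIs over the horizon: service level (% of
demand met; 100% when no demand occurred), wastage (% of received units
that expired; 0% when nothing was received), and holding (mean end-of-day
units in stock). Reported spreads are standard deviations across rollouts,
not standard errors.

Every simulated day consumes a fixed, policy-independent number of uniform
draws (one for demand in the single-product scenarios; three for the
two-product day; $1 + A_{\max}$ for the platelet day, covering the
unit-level shelf-life draws whether or not units are ordered). Two
consequences, both tested: rerunning a policy from the same seed is
bit-identical, and different policies evaluated from the same seed see
*common random numbers*, which sharpens optimality-gap estimates because
the compared returns are positively correlated. The optimality gap of
policy $h$ against the value-iteration reference is
$100\,(\bar G_{VI} - \bar G_h)/|\bar G_{VI}|$, positive when the heuristic
underperforms for cost-minimising and revenue problems alike.

## Heuristic policies and simulation optimization

Three policy families match the scenarios: a base-stock (order-up-to $S$)
rule on the inventory position; a per-product waste-adjusted base-stock
rule $[S^p - I^p + [X^p_1 - \mu^p]^+]^+$, where $X^p_1$ is stock expiring
tonight, searched up to $S^p \le 2A^p_{\max}$ (the best order-up-to level
can exceed the solver's order cap, so heuristic orders are clipped to
$A_{\max}$ in the simulator); and a weekday $(s^\tau, S^\tau)$ rule — 14
integer parameters — which orders up to $S^\tau$ only when the stock on
hand is at or below $s^\tau$, and never orders for a weekday whose pair
violates the hard constraint $s^\tau < S^\tau$ (constraint handling by
action suppression, since the search itself is unconstrained).

Parameters are fitted by maximising the mean return over a shared set of
seeded rollouts (4,000 per candidate by default). One-dimensional families
are scanned exhaustively; multi-dimensional families use a seeded
generational evolutionary search over the integer box: population 50,
elitist survival of the best 50 from parents plus offspring, binary
tournament selection, uniform crossover, per-gene reset mutation with
probability $1/k$. The search stops when the incumbent best-ever candidate
has not changed for five generations, or after 100 generations. Ties in
mean return resolve to the lexicographically smallest parameter vector.
Because every candidate is scored on the same rollouts, the fitted optimum
is a deterministic function of the search configuration, which the suite
asserts by re-running searches.

## Degenerate inputs and guards

Zero demand, zero stock, empty in-transit vectors ($L = 1$), zero-width
action boxes ($A_{\max} = 0$ for one product) and $\rho \in \{0, 1\}$ are
all exercised in the tests. Infeasible issued pairs (more than the stock on
hand) carry probability zero and the transition refuses them loudly rather
than clamping. Two memory guards protect interactive use: scenario
constructors return a count-only model (sizes and simulator available,
solver refused) when the state or outcome enumeration would exceed
`max_enumerate` (default $5\times10^6$ tuples), and backup-table
construction refuses above `max_table_entries` (default $2\times10^8$
cells). The platelet bank at $m = 8$ — 12.6 billion states — is therefore
deliberately count-only: its sizes are computed in closed form and its
heuristic/simulation path runs, mirroring how such instances are handled in
practice.

## What the validation runs do and do not show

The test suite and the acceptance script solve the instances that fit
comfortably in desktop memory: the lead-time scenario at $m = 2$ (121 and
1,331 states; all eight experimental settings), the two-product scenario at
$m = 2$ (14,641 and 11,025 states), and the platelet bank at $m = 3$ (3,087
states, 37,191 outcomes). Acceptance evaluations use 10,000 rollouts; the
test suite uses 1,000–4,000 to keep the default run short, with tolerances
widened to three standard errors of the smaller samples. These sizes are
the package's validation choices; the solver itself is limited only by
memory for the backup tables. Larger printed instances (the two-product
$m = 3$ settings at up to $16.8$ million states, the platelet bank at
$m = 5$) are expressible with the bundled configs and solvable with enough
memory and patience, but are not part of the routine validation, and no
wall-time claims are made anywhere — execution speed depends on hardware
and is outside the package's scope.

Because the simulators share the solver's transition code, agreement
between simulated returns and solver values validates the *implementation*,
not the *model*: systematic effects absent from the scenario definitions —
demand correlation across days, supplier unreliability, batch deliveries,
substitution behaviour that depends on queue position — are equally absent
from both sides. The platelet-bank shelf-life calibration is synthetic (see
above), so its absolute returns characterise the calibration, not any
particular hospital.
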