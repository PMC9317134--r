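# fluxbalancer

Diagnosing and resolving infeasible flux balance scenarios in metabolic
networks.

## The problem

Constraint-based models describe steady-state metabolism by a
stoichiometric matrix *N* (m metabolites × n reactions) and linear
constraints on the flux vector *r*:

    N r = 0,        lb_i ≤ r_i ≤ ub_i,        A r ≤ b

Flux balance analysis (FBA) optimises a linear objective `max c'r` over
this polyhedron. In practice one often *fixes* a set F of reaction rates
to measured values, `r_i = f_i` for i ∈ F — substrate uptake, growth
rate, product excretion. Because measurements carry noise, fixed rates
that are algebraically redundant (linked through mass balances, e.g.
carbon balance) are almost never mutually consistent, and the LP becomes
infeasible. The same can happen through irreversibility bounds alone,
with no algebraic redundancy at all.

`fluxbalancer` is for modellers who hit that "infeasible" solver message:
it explains *why* the scenario is infeasible, *which* fixed rates are
responsible, and computes *minimal corrections* that restore feasibility,
after which FBA and flux variability analysis (FVA) run on the corrected
system.

## Methods at a glance

* **Classification** (`diagnose`): with `N_U`, `N_F` the stoichiometric
  sub-matrices of unknown/fixed reactions, the scenario is *determined*
  iff `rank(N_U) = |U|`, and carries
  `degR = rank(N) − rank(N_U)` degrees of redundancy. The redundancy
  matrix `R = N_F − N_U N_U⁺ N_F` yields the consistency condition
  `R r_F = 0`; fixed reactions with non-zero columns of `R` are the
  redundant rates.
* **Analytical correction** (`wls_correction`): the weighted
  least-squares corrections
  `δ = W R_r' (R_r W R_r')⁻¹ R_r r_F`, with `R_r` a maximal independent
  row set of `R` and `W = diag(1/w_i)`; corrected rates are `f − δ`.
* **QP balancing** (`qp_balance`): `min Σ w_i δ_i²` subject to the *full*
  constraint set — equal to the analytical solution whenever bounds and
  general constraints stay slack.
* **LP balancing** (`lp_balance`): paired non-negative slacks
  `r_i = f_i + δ_i⁺ − δ_i⁻`, minimising `Σ w_i (δ_i⁺ + δ_i⁻)`; the
  optimal value is unique, the corrected rates may not be (an optional
  check decides).
* **Generalized balancing** (`generalized_balance`): slacks on
  steady-state rows, bounds or general constraint rows instead of (or in
  addition to) the fixed rates.
* **Weights**: `W1` = 1/σ², `W2` = 1/|f|, `W3` = 1, with a large penalty
  (default 10⁶) or pinning for rates fixed at zero.
* **FBA/FVA** (`fba`, `fva`, `determined_rates`) on the corrected system,
  including identification of uniquely determined rates.

QP solves go through `quadprog` (with an exact active-set polish); LP
solves use a dense bounded-variable two-phase simplex built into the
package.

## Worked example

Two strictly coupled irreversible reactions (R4 produces metabolite D,
R10 consumes it) fixed at the inconsistent rates 2 and 4:

```r
library(fluxbalancer)
model    <- coupled_pair()
scenario <- flux_scenario(c(R4 = 2, R10 = 4), model = model)

diagnose(model, scenario)
#> Scenario diagnosis
#>   classification: determined / redundant / inconsistent
#>   rank(N) = 1  rank(NU) = 0  conservation relations = 0
#>   degrees of freedom = 0  degrees of redundancy = 1
#>   redundant rates: R4, R10
#>   max |R rF| = 2
```

One degree of redundancy (the coupling `r_R4 = r_R10`), violated by
2 − 4 = −2, and both fixed rates are implicated. Balance with weights
`w_i = 1/|f_i|` (scheme W2):

```r
qp_balance(model, scenario, weight_spec("W2"))
#> Correction result (qp), status: optimal
#>   objective value: 0.6666667
#>  reaction given corrected     change
#>       R10     4  2.666667 -1.3333333
#>        R4     2  2.666667  0.6666667
```

The QP meets at the unique weighted compromise 8/3 ≈ 2.67. The LP
instead drags the cheaper-to-move rate onto the better-weighted one:

```r
lp_balance(model, scenario, weight_spec("W2"), check_unique = TRUE)
#> Correction result (lp), status: optimal
#>   objective value: 0.5
#>  reaction given corrected change
#>       R10     4         2     -2
#>        R4     2         2      0
```

With equal weights (`W3`) the LP objective is 2 and *any* common value
in [2, 4] is optimal (`unique` is then `FALSE`), while the QP uniquely
picks (3, 3). After `apply_corrections()`, `fva()` confirms both rates
are determined at the corrected value.

The same workflow is scriptable:

```sh
inst/exec/fluxbalancer classify --model inst/extdata/coupled_pair.json \
    --scenario inst/extdata/coupled_scenario.tsv
inst/exec/fluxbalancer balance --model inst/extdata/coupled_pair.json \
    --scenario inst/extdata/coupled_scenario.tsv --method lp --weights w2 --out out/
inst/exec/fluxbalancer demo
```

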