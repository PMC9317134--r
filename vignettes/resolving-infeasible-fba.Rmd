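---
title: "Resolving infeasible flux balance scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving infeasible flux balance scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxbalancer)
```

## The model and its assumptions

A metabolic network with m metabolites and n reactions is described by
its stoichiometric matrix $N \in \mathbb{R}^{m \times n}$. The package
works with the standard constraint-based assumptions: metabolism is in a
steady state, $N r = 0$; fluxes respect bounds $lb \le r \le ub$
(irreversibility is $lb_i = 0$); optional general linear inequalities
$A r \le b$ encode, e.g., enzyme capacity limits. A *flux scenario*
additionally clamps a set $F$ of reactions to known values,
$r_i = f_i$ — typically measured exchange rates and the growth rate. We
assume throughout that the *base* system (without the clamps) is
feasible; the package makes that assumption checkable and, via
`generalized_balance()`, repairable.

Measured values are noisy, so whenever the clamped rates are linked by
mass balances the scenario is almost surely infeasible. The package
separates two distinct notions:

* **algebraic consistency** — does $\{N r = 0,\ r_F = f\}$ admit any
  solution, ignoring bounds? This is the classical metabolic flux
  analysis (MFA) view and is decided by rank arithmetic.
* **LP feasibility** — does the full system admit a solution? Bounds can
  break feasibility even when the algebra is consistent, which is why
  a scenario diagnosis and an LP feasibility check are both reported.

## Classification by rank arithmetic

Splitting $N$ into the fixed-column block $N_F$ and the unknown-column
block $N_U$ turns the steady state into $N_U r_U = -N_F r_F = z$. With
$x = |U|$ unknowns:

* degrees of freedom $= x - \operatorname{rank}(N_U)$; the scenario is
  *determined* when this is 0, otherwise *underdetermined*. Individual
  unknowns are still uniquely determined whenever their row in a
  nullspace basis $K_U$ of $N_U$ is zero.
* degrees of redundancy
  $\mathrm{degR} = \operatorname{rank}(N) - \operatorname{rank}(N_U)$;
  *redundant* when positive. Writing it against $\operatorname{rank}(N)$
  rather than $m$ makes conservation relations (dependent rows of $N$,
  $c = m - \operatorname{rank}(N)$ of them) harmless, so dependent rows
  are deliberately **not** removed from $N$.
* the redundancy matrix $R = N_F - N_U N_U^{+} N_F$ (Moore–Penrose
  pseudoinverse) gives the consistency condition $R\, r_F = 0$ and marks
  the *redundant rates* — fixed reactions with a non-zero column of $R$.
  Non-redundant systems have $R = 0$ and are always consistent.

`pseudoinverse_solution()` returns $r_U = N_U^{+} z$, the least-squares
solution of minimal Euclidean norm. In an inconsistent scenario it
violates the steady state minimally rather than satisfying it; only the
kernel-determined entries are unique.

## Correcting the measurements

Three correction engines share the weighting schemes W1
($w_i = 1/\sigma_i^2$), W2 ($w_i = 1/|f_i|$) and W3 ($w_i = 1$):

* `wls_correction()` computes the analytical corrections
  $\delta = W R_r^{T} (R_r W R_r^{T})^{-1} R_r\, r_F$, where $R_r$ is a
  maximal independent row set of $R$ and $W$ carries the reciprocals
  $1/w_i$. Corrected rates are $f - \delta$. This ignores bounds and
  general constraints.
* `qp_balance()` minimises $\sum_F w_i \delta_i^2$ subject to the full
  constraint set. The corrections are unique; they coincide with the
  analytical solution exactly when bounds and general constraints stay
  slack at the optimum (property-tested against `wls_correction()` over
  200 random redundant scenarios with widened bounds).
* `lp_balance()` minimises $\sum_F w_i (\delta_i^{+} + \delta_i^{-})$
  with $r_i = f_i + \delta_i^{+} - \delta_i^{-}$,
  $\delta_i^{\pm} \ge 0$ — the weighted sum of absolute changes. At any
  optimum one slack of each pair is zero. The optimal value is unique
  but the corrected rates need not be; `check_unique = TRUE` ranges each
  corrected rate over the optimal face (objective fixed, 2k extra LPs)
  and reports `unique` accordingly, which is off by default because it
  multiplies the solve count.

Rates fixed at zero get the large weight `zero_flux_weight`
(default $10^6$, constrained $\ge 10^3$) under W1/W2, or are excluded
from correction entirely with `pin_zero_rates = TRUE` (implemented as a
hard equality, i.e. an infinite weight; in the analytical formula the
corresponding variance entry of $W$ is zero).

`generalized_balance()` moves the slack variables onto other constraint
classes: a signed slack (QP) or slack pair (LP) per steady-state row,
and one non-negative slack per bound or general-constraint row. With
steady-state targets only, equal weights and wide bounds, the QP slacks
reproduce the steady-state residual of the pseudoinverse solution — the
two least-squares views meet, which the acceptance suite verifies to
1e-6 over 100 scenarios. If even the fully slacked system is infeasible
the model itself is malformed and the function stops with a diagnostic
error rather than returning a result.

## After the correction

`apply_corrections()` yields the corrected scenario; `fba()` optimises
the original objective over it and `fva()` ranges every reaction,
flagging as *determined* those with range below `det_tol`
(default $10^{-7}$, scaled by the value's magnitude). FVA sees bounds
and general constraints, so its determined set is a superset of the
kernel-determined set — the package tests this inclusion rather than
assuming it. FVA runs on the corrected system directly; an optional
`fix_objective_fraction` adds $c^{T} r \ge \gamma \cdot$ optimum for
users who want objective-constrained ranges instead.

## Numerical choices

* **Ranks** are computed by SVD with tolerance
  $\max(\text{dim}) \cdot \varepsilon \cdot \sigma_{\max}$, exposed as
  `rank_tol` everywhere a rank decision is made, so the diagnosis is
  reproducible under rescaling.
* **Reduction of $R$ to $R_r$** uses QR with column pivoting on $R^T$.
  Any independent row set spans the same row space and leaves the
  analytical corrections unchanged; this invariance is property-tested
  with random row recombinations rather than assumed.
* **Consistency** is declared when
  $\|R\,r_F\|_\infty \le 10^{-9} \max(1, \|f\|_\infty)$.
* **LP solves** use a dense bounded-variable two-phase simplex with
  Bland's rule (entering and leaving), written for this package because
  no suitable LP backend is available in the dependency set; it refuses
  nothing a desk-scale model produces, returns proven optimal bases, and
  is cross-checked in the test suite against `boot::simplex` and
  brute-force candidate enumeration. Feasibility/optimality tolerance is
  $10^{-9}$.
* **QP solves** use `quadprog`, which requires a positive-definite
  Hessian: variables without quadratic cost receive a ridge of
  $10^{-8} \min_i w_i$, after which the active set is read off and the
  reduced equality-constrained problem is re-solved exactly by the
  nullspace method. The polish removes the ridge bias, which is why the
  QP/analytical comparisons hold to $10^{-6}$ and beyond.
* **Post-correction re-checks** rerun a pure LP feasibility solve on
  every optimal correction at a relaxed tolerance of $10^{-6}$
  (configurable `feas_tol_relax`), since corrections are applied at
  floating-point precision; a stricter tolerance can spuriously reject
  valid corrections.
* **Degenerate inputs**: an empty fixed set yields a zero-objective
  empty correction; a fully fixed scenario yields an empty unknown-rate
  vector; unbounded FVA directions are reported as $\pm\infty$, encoded
  as $\pm 10^{30}$ only in files.

## The bundled networks and the generator

`coupled_pair()` is the minimal two-reaction chain whose fixed rates
(2, 4) give the canonical one-redundancy inconsistent scenario;
`example_network()` is a ten-reaction, six-metabolite network on which
all four determinacy/redundancy classes arise. Its internal wiring is a
reconstruction chosen to satisfy the documented structural facts (full
rank 6, exchange balance $r_1 + r_2 = r_3 + r_4$, strict R4–R7–R10
coupling through metabolites D and F, only R2/R8 reversible, and the
irreversibility bottleneck $r_4 \le r_1$); tests assert exactly these
facts and nothing tied to a particular drawing of the network.

`random_scenario()` generates property-test instances: sparse random
stoichiometry with entries in $\{-2,-1,1,2\}$, bounds $\pm 10$ (a
fraction of reactions irreversible), a ground-truth flux vector obtained
by averaging optima of random-objective LPs (an interior point of the
polytope, so it satisfies every constraint), and a noisy fixed subset
with recorded variances. Model sizes default to $m \in [3,8]$,
$n \in [6,16]$ — small enough that brute-force oracles (dense ranks,
candidate enumeration) stay exact and the full suite runs in seconds;
the acceptance loops use 100–300 such scenarios each. Noise is i.i.d.
Gaussian per fixed rate, which is what the W1 weighting models.

What the generator does *not* emulate: genome-scale dimensions,
correlated measurement errors, systematic biases (miscalibrated rates,
missing reactions), or thermodynamically coupled constraint structures.
Passing recovery tests therefore show that reconciliation behaves
correctly under the model's own noise assumptions, not that it corrects
structural model errors — on real data, large corrections concentrated
on a few rates should be read as a hint of such errors, not as values to
accept silently.

## Known limitations

* Cardinality-minimal corrections (fewest changed rates) would require
  mixed-integer programming and are out of scope, as is the enumeration
  of irreducibly inconsistent constraint subsets.
* The LP/QP machinery is dense and intended for core-model scale;
  genome-scale models load and solve, but no sparse or parallel path
  exists.
* SBML support is read-only (level 3 with the flux-bounds/objective
  package, v2); models are written in the package's JSON dialect.
* Statistical gross-error tests on the residuals (e.g. $\chi^2$) are not
  provided; the residual vector and the redundant-rate list are exposed
  for users who want to build them.
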