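---
title: "The highly adaptive testing design: models, assembly and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The highly adaptive testing design: models, assembly and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatcat)
```

## The problem

Large-scale assessments such as PISA administer items that are nested in
units sharing a stimulus, under a content blueprint with many count-type
constraints, across several correlated cognitive domains, and with
operational requirements (minimum response counts for calibration,
balanced item positions, a bearable test experience). Conventional CAT
maximizes measurement precision but ignores such constraints; multistage
designs honor them but adapt only at a few routing points. The highly
adaptive testing (HAT) design implemented here adapts at the item level
while a *shadow test* — a full-length, fully constraint-compliant test
assembled by mixed-integer programming before every single item — keeps
the realized test inside the blueprint at all times.

## Response models and information

* Dichotomous items: two-parameter logistic (2PL) in slope–intercept
  form, $P_i(\theta) = \mathrm{logit}^{-1}(a_i\theta - b_i)$, with
  $I_i(\theta) = a_i^2 P_i Q_i$.
* Polytomous items: generalized partial credit model (GPCM) in Muraki's
  common-discrimination form. For category score $c \in \{0,\dots,m\}$
  the numerator is $\exp\{\sum_{v \le c} a(\theta - b + d_v)\}$ with step
  parameters $d_v$; the information is $a^2\,\mathrm{Var}(X\mid\theta)$,
  the standard identity for a common discrimination. Numerators are
  normalized by log-sum-exp; the logistic uses `plogis`.

One scale subtlety is deliberate: the 2PL carries its difficulty on the
logit scale ($a\theta - b$, information peak at $\theta = b/a$) while the
GPCM centers on the ability scale ($a(\theta - b + d_v)$). These are the
conventional parameterizations of each model; a two-category GPCM with
its single step at zero therefore equals a 2PL with intercept $ab$, not
$b$. Tests assert exactly this identity.

## RP-shifted selection

Selecting at maximum information places success probability near .5,
which students experience as relentless difficulty. The package instead
evaluates information at $\hat\theta - \delta_i$ with
$\delta_i = a_i^{-1}\ln\{p/(1-p)\}$. For a 2PL item whose information
peaks exactly there, the success probability *at* $\hat\theta$ is the
target $p$; the default $p = .62$ matches the response probability used
to define reporting proficiency levels, and $p = .5$ recovers plain
maximum-information selection. The same $a$-based shift is applied to
GPCM items: the shift formula only involves the discrimination, and no
separate polytomous prescription exists, so one selection currency is
used for the whole pool (`pool_information()` with an `rp` argument).
The shadow-test *objective* uses the same shifted information as the
within-shadow pick, so the assembled test and the administered item are
optimized in the same currency.

## The shadow-test program

Binary variables $x_i$ (items) and $z_s$ (units); maximize
$\sum_i I_i(\hat\theta_k)\,x_i$ subject to the test-length equality, one
or two rows per categorical blueprint window, per-item link rows
$x_{i_s} - z_s \le 0$, per-unit rows
$\sum_{i_s} x_{i_s} \lessgtr n_s z_s$ (when the per-unit minimum is zero
an extra row $z_s \le \sum x_{i_s}$ ties the unit variable to usage), the
unit-count row, and the administered-inclusion equality
$\sum_{i \in S_{k-1}} x_i = k-1$. Blueprints are data (CSV with
`constraint_id`, `level`, `attribute`, `value`, `lb`, `ub`), not code;
the shipped reading, mathematics and science fixtures encode the three
published constraint sets. Two encoding choices: "Integrate (single
text)" and "Integrate (multiple texts)" are distinct `cognitive_process`
categories, and the joint "Reflect and Assess" window uses a
`|`-separated value list (set union within one attribute).

A negligible lexicographic perturbation ($\le 10^{-9}$, toward smaller
item ids) is added to the objective by default so that ties among equally
informative selections resolve deterministically; reported objective
values are always recomputed from the unperturbed coefficients.

### The solver

No mixed-integer (or even linear) programming package is part of this
package's dependency stack, so `hatcat` ships a small exact solver
(`src/milp.cpp`): a full-tableau primal simplex with variable bounds and
a big-M start for the LP relaxations, inside a depth-first branch and
bound that branches on the fraction closest to one half, explores the
rounded side first, and prunes with an absolute gap of $10^{-7}$. All
rules are deterministic, so identical models yield identical selections.
The previous step's shadow test remains feasible after the administered
set grows (the picked item was inside it), and is passed as a warm-start
incumbent. Each solve accepts a time limit (default 5 s; status
`feasible_timeout` keeps the incumbent and is audited like any other
result); operational-size problems solve in a few milliseconds, and
optimality is tested against exhaustive enumeration on small pools.

### Infeasibility during administration

A shadow solve can only become infeasible through forced inclusions. The
default is to fail fast with a diagnostic. `hat_config(carry_forward =
TRUE)` instead reuses the previous shadow test and logs it. To keep the
guarantee intact with spiraled link units (below), the items of *both*
scheduled units are committed into every shadow from position 1 — not
only once reached — so the assembler can never paint itself into a
corner it was not told about.

## Exposure control: the progressive method

With $h$ of $t$ items administered, $s = h/t$, $H$ the maximum candidate
information, and $R_i \sim U(0, H)$ per candidate, the selection weight
is $w_i = (1-s)R_i + sI_i$: pure randomness at the start (where
$\hat\theta$ is noise anyway), pure information at the end. The effect on
the *maximum* exposure rate is only visible while the pool's top items
remain contestable, i.e. when the test is short relative to the pool; on
long tests every design eventually administers the dominant items to
everyone and the maxima coincide at 1. The packaged exposure study
therefore uses 10-item tests from a 90-item pool, 500 simulees of
identical ability, and paired seeds across the progressive and
maximum-information arms.

## Item-position balancing (IPE subpools)

The domain pool is split into two equal subpools such that each half
retains enough items of every blueprint category; within a domain,
cluster 1 administers subpool A before B and cluster 2 reverses the
order, so each item's serial position is balanced across students. For a
36-item selection the halves must satisfy the halved windows
$\lfloor lb/2 \rfloor \le n \le \lceil ub/2 \rceil$ — full-test bounds
cannot hold in an 18-item half. Unit-level rules are not imposed on the
halves: with 12 units of exactly 3 items, a halved per-unit ceiling of 2
would force at least 9 units into each half, contradicting the halved
unit count of 6; the partition is an item-level assignment MIP. When a
whole pool (larger than one test form) is labeled, the halved *upper*
bounds are jointly unsatisfiable for any well-stocked category, so only
the halved lower bounds are enforced (`enforce_ub = FALSE` in
`partition_pool_ipe()`, the default inside `label_pool_subpools()`).
The first-ordered subpool's per-cluster quota is half the cluster budget
rounded up; spiraled units are exempt from the ordering (they are
non-adaptive) but their items count toward the quota. If the shadow test
offers no eligible item of the due subpool, the filter is relaxed for
that pick and flagged in the log (`ipe_relaxed`).

## Spiraled link units and forms

To guarantee minimum response counts for calibration and linking, each
student's major-domain test opens each cluster with one complete,
non-adaptively chosen unit: student $j$ receives units $j$ and $j+1$
(1-based, wrapping) of the pool's unit order. The published spiraling
example skips one student index; the regular $j/j{+}1$ rotation is
implemented. Spiraled units occupy the first slots of clusters 1 and 2;
by default only the major (first) domain has them.

The 24 test forms pair every ordered two-domain combination with both
cluster orders of each domain. Forms are assigned by rotation or
uniformly at random. Across domains, the final provisional $\hat\theta$
of the first domain initializes the second domain: it becomes both the
starting point of selection and the center of the second domain's EAP
prior. This is a direct copy — the inter-domain covariance is *not* used
to rescale it (a regression-type shrinkage would be a natural extension,
but the design specifies the copy); the covariance matters for simulee
generation only.

## Ability estimation

Provisional and final estimates are EAP on an equally spaced 81-point
grid over $[-4, 4]$ with a normal prior (sd 1, centered at the domain's
initial ability). EAP is finite for all-correct/all-incorrect patterns,
which dominate early in a test. MLE is available
(`estimate_theta(..., method = "MLE")`) and signals
`hatcat_mle_nonfinite` when the maximizer sits on the grid boundary; the
administration loop falls back to EAP. With zero responses the EAP
reproduces the prior moments up to grid truncation (the sd of a
$[-4,4]$-truncated standard normal is 0.9993, inside the $10^{-3}$
tolerance asserted in tests). Whether the operational design used EAP,
MLE or WLE is not fixed by the published description; EAP was chosen for
its finiteness and determinism.

## The synthetic pool generator

No operational pool is distributable, so studies run on synthetic pools
(`generate_synthetic_pool()`): units of configurable size, discriminations
log-normal (meanlog 0, sdlog 0.3), difficulties normal (0, 1) — values
typical of calibrated pools — a 20% share of 3-category GPCM items, and
independent categorical attributes drawn from stated frequencies. The
per-domain specs (`reading_pool_spec()`: 40 units × 3 items;
`mathematics_pool_spec()`: 30 units × 1–4; `science_pool_spec()`:
36 units × 2–5) derive their attribute frequencies from the blueprint
window midpoints, so every lower bound holds with a margin (default 1.5,
checked at generation; violations abort naming the binding constraint).
The published description gives no pool sizes or parameter
distributions; these defaults are this package's choices and are all
overridable.

What the generator does *not* emulate: attribute correlations (e.g.
between text type and cognitive process), within-unit difficulty
clustering, position-dependent parameter drift, multidimensionality
within a domain, or misfit of the response model. Passing simulations
therefore demonstrate the *mechanics* — exact blueprint compliance,
exposure behavior, estimator consistency under the model — not
operational performance on a real pool.

## Numerical choices and degenerate inputs

* Quadrature: 81 points on $[-4, 4]$; estimates are clamped to this range
  by construction.
* Selection ties break to the lexicographically smallest item id; all
  randomness flows through R's RNG so a seed fixes the whole study.
* All-zero candidate informations make the progressive weights all zero;
  the pick then falls back to id order.
* Simplex tolerances: $10^{-9}$ pivot/reduced-cost, Bland's rule after
  stalling; branch-and-bound integrality tolerance $10^{-6}$.
* Odd-sized pools are labeled by partitioning all but the
  lexicographically last item (assigned to subpool B).

## Study sizes

The packaged studies are desk-scale by design: 20 simulees for the
blueprint-compliance studies (each reading administration solves ~30
shadow MIPs), 500 paired simulees for the exposure comparison (plain CAT
mode, no MIP), 500 simulees per test length for the recovery curve, and
50 random instances for the enumeration-equivalence check. These sizes
give unambiguous results for the guaranteed properties (compliance is
exact, not statistical) while a full study runs in minutes on one CPU.

## Known limitations

* Constraint families are count-type only (no quantitative constraints
  such as word counts, no enemy pairs).
* Administration within a domain is unidimensional; the multidimensional
  ability enters through simulee generation and cross-domain carry-over.
* The IPE partition relaxes unit-level rules (see above) — the halves
  comply categorically, not unit-wise.
* The branch-and-bound solver is exact but dense; pools beyond a few
  hundred items per domain would warrant a sparse LP core or an external
  solver behind the same `solve_shadow()` interface.
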