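---
title: "Multilevel selection and the genome-enzyme division of labour in protocells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection and the genome-enzyme division of labour in protocells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(replicell)
```

## The model

`replicell` simulates a population of protocells, each containing a
population of self-replicating catalytic molecules ("replicators") of two
types, P and Q. A replicator can act in two roles: as a *template*, whose
eight heritable catalytic values `k^c_pt` are copied (with mutation) into a
product; and as a *catalyst*, whose values set the rate at which it forms a
catalyst-template complex with a partner and synthesizes a product of type
`p` from a template of type `t`. The index `c` selects which half of the
profile applies: the replicator's own type, or the type of its transcripts.
Because a molecule bound in a complex as a catalyst cannot simultaneously
be copied as a template, catalysis carries an opportunity cost at the
molecular level, while the extra synthesis it enables benefits every
molecule in the same protocell. This trade-off places molecular-level
selection (which favours losing catalytic activity) in conflict with
cellular-level selection (which favours keeping it) — and that conflict,
at sufficiently low within-cell relatedness, resolves by *symmetry
breaking*: one molecular type specializes into a non-catalytic template
(a genome) and the other into a catalyst that is no longer reverse
transcribed (an enzyme).

Replication consumes one unit of an abstract substrate S per birth; decay
returns it. The total particle number (P + Q + S) is strictly conserved at
`n_tot`. Substrate diffuses rapidly between protocells (redistributed every
step in proportion to protocell replicator counts), while replicators never
migrate. A protocell whose particle count exceeds the threshold `V` splits,
each particle assigned to a random daughter; a protocell that loses all
particles is removed.

## One time step

Each step applies, in order:

1. **Reaction**, per protocell:
   free replicators are paired into `floor(n/2)` disjoint random pairs;
   each pair forms a complex with probability
   `total / (4 k_max) * min(1, (n - 1) / V)`, where `total` is the sum of
   the four channel rates (either partner as catalyst, either product
   type) and the second factor is a mass-action collision correction (see
   below); the realized channel is drawn proportionally to the four rates.
   Complexes are then visited in random order; while substrate remains,
   each consumes one unit and yields a product whose profile is copied
   from the *template* and mutated. All complexes dissociate. Finally every
   replicator decays with probability `d`, returning a substrate unit.
2. **Diffusion**: all substrate is pooled and redistributed multinomially
   with probabilities proportional to replicator counts.
3. **Division**: every protocell with more than `V` particles splits;
   empty protocells are removed.

The unit of time is fixed by the decay probability: a replicator lives
`1/d` steps on average.

### Why the collision factor

With pairing alone, a pair's reaction probability is independent of how
full its protocell is. Protocell sizes then perform an unbiased random
walk (growth is strictly zero-sum), and the stationary size distribution
piles up at small sizes: simulations under that scheme settle near 130
protocells at `n_tot = 50 V` for any `V`, with a mean protocell only a
third full. Scaling the encounter probability by replicator density
`(n - 1)/V` — what mass-action kinetics in a compartment of fixed volume
would do — makes dilute protocells convert substrate more slowly than
full ones, so substrate flows from shrunken protocells to well-filled
ones. Sizes then concentrate between `V/2` and `V`, and the protocell
count settles near 100 for `n_tot = 50 V` irrespective of `V`, the
behaviour the rest of the analysis assumes. The literal density-free
scheme remains available via `sim_params(density_collisions = FALSE)`.

### Parameters

| parameter | meaning | default |
|---|---|---|
| `V` | division threshold (particles) | — |
| `m` | mutation probability per k-value per birth | — |
| `d` | decay probability per step | 0.02 |
| `delta_mut` | half-width of uniform mutation increments | 0.05 |
| `k_max` | reflecting upper bound on k-values | 1 |
| `n_tot` | conserved particle total | `50 V` |
| `init_cells` | founding protocells (size `n_tot/init_cells`, all values at `k_max`, types alternating, no substrate) | 50 |

Mutation adds `Uniform(-delta_mut, delta_mut)` independently to each of
the eight values with probability `m` per value; values reflect at
`k_max` and are unbounded below, but negative values contribute zero rate.
The per-entry independence matches the assumption, used in the analytical
reduction, that mutations of the P-block and Q-block are uncorrelated.

## Observables

* `mean_activities()` — the eight population-mean values (one replicator,
  one sample).
* `minority_frequency()` — per-protocell frequency of the rarer type,
  restricted to protocells holding at least `V/2` particles; its median
  measures *numerical* symmetry breaking.
* `variance_decomposition()` — between-cell variance of cell means
  (`sigma2_cel`) and mean within-cell variance (`sigma2_mol`) of the
  trait projection (a replicator's mean over one type's four values),
  all moments replicator-weighted so the law of total variance is exact;
  `R = sigma2_cel / (sigma2_cel + sigma2_mol)` is within-protocell
  relatedness.
* `price_decompose()` — the exact Price split of one generation of
  selection into cellular-level (between) and molecular-level (within)
  covariance terms.
* `reproductive_value()` — the fitness `lambda = omega_P + omega_Q` of a
  replicator replicated at rate `omega_P` and transcribed at rate
  `omega_Q`, and the left-eigenvector reproductive values
  `u = (omega_P, omega_Q)/lambda`; a role never copied has reproductive
  value zero.
* `classify_phase()` — maps end-window statistics to one of `none`,
  `incomplete`, `catalytic_informatic_only`, `threefold`,
  `uncategorized`.

### Classifier thresholds

The published phase diagrams rest on criteria spelled out only in
supplementary material; this package therefore declares its own explicit
thresholds and documents them: with `eps = 0.05 k_max`, *catalytic*
asymmetry requires the template type's mean own-activity below `eps`, at
most a tenth of the catalyst type's, and the catalyst type's above
`2 eps`; *informatic* asymmetry requires the mean reverse-transcription
activity below `eps` and at most a tenth of the transcription activity;
*numerical* asymmetry requires the median per-cell minority frequency
below 0.4. `none` additionally requires both types to retain more than
half their maximal activity. These are classification conventions, not
fitted quantities; conclusions should not hinge on their exact values.

## Ancestor tracking

Ancestry is tracked at two levels, protocells first. The engine's online
tracker (`run_simulation(ancestor_at = t)`) marks every replicator and
protocell alive at step `t`; descendants inherit the marks, so at the end
of the run each survivor maps to its unique ancestor alive at `t` without
storing the full genealogy. `ancestor_summary()` then keeps only
replicator ancestors inside the protocells ancestral to *all* surviving
protocells and reports the role spectrum: the fraction of template-type
vs catalyst-type individuals among ancestors and in the whole population.
Role is assigned by mean own-activity (the less active type is the
template type), a proxy that coincides with the instantaneous complex
role once symmetry is broken; in undifferentiated populations the
spectrum is labelled as such. The log-based functions (`cell_tree()`,
`molecular_lineage()`, `trace_replicator_ancestors()`) implement the same
two-stage tracing from event logs and are cross-checked against the
online tracker in the test suite.

## The reduced mean-trait model

Averaging the agent-based dynamics and keeping terms to second order in
the trait moments yields gradient dynamics for the two mean activities
`(kP, kQ)` on the unit square:

    dkc/dtau = omega_c * (beta * sigma2_cel - gamma * sigma2_mol)
             + omega_c' * beta * sigma2_cel,

where `omega_c = exp(-s kc) / (exp(-s kP) + exp(-s kQ))` are normalized
reproductive values (the more catalytic type is copied less). With
`beta = 1`, `gamma = s` the flow equals `sigma2_tot` times the gradient
of the inclusive-fitness potential `R B - (1 - R) C` with `B = kP + kQ`
and `C = -log(exp(-s kP) + exp(-s kQ))`; `potential_gradient_check()`
verifies the identity to floating-point accuracy.

Because the flow depends on the state only through `kP - kQ` (its
diagonal component is constant), its equilibria lie on the box boundary
except in the degenerate case `gamma sigma2_mol = 2 beta sigma2_cel`,
where the whole diagonal is stationary. `find_equilibria()` therefore
enumerates corners (one-sided flow signs) and edges (bracketing plus
`uniroot` on the tangential component), rather than running a generic
2-D Newton iteration whose Jacobian is singular here. Closed-form corner
conditions, used as the oracle in the tests, are:

* `(1,1)` stable iff `sigma2_mol <= 2 sigma2_cel / s`;
* `(1,0)` stable iff `sigma2_cel (1 + e^-s)/s <= sigma2_mol <=
  sigma2_cel (1 + e^s)/s`.

The boundary treatment is *outward one-sided* clamping: a flow component
is zeroed only where it points out of the box. Reading the boundary rule
as absorbing instead would make the all-active corner stable for every
parameter value, contradicting the reported loss of its stability at
large molecular variance, so the one-sided reading is the only consistent
one. `basins()` integrates the clamped flow with explicit Euler
(`dt = 0.15` by default, matching the short-duration flow arrows of the
original phase portraits; use a smaller `dt` for accurate basin
boundaries near saddles).

```{r phase-plane}
eq <- find_equilibria(pp_params(sigma2_mol = 2.5))
eq[eq$stability == "stable", ]
```

## Synthetic fixtures

`generate_fixture()` builds snapshots with exact prescribed
`(sigma2_cel, sigma2_mol)` via a balanced two-point design (half the
cells offset up, half down; half of each cell's members offset up, half
down). These fixtures exercise the moment and Price machinery without
simulation; they emulate only the variance structure of real snapshots —
not skewness, not type asymmetry, not the coupling between cell size and
trait — so passing parameter-recovery tests validates the estimators,
not the simulator.

## Problem sizes used in the checks

The published experiments run to 5e7 steps at V up to 1e4 (cluster
scale). The package's own checks are desk-scale by design, and the sizes
are choices of this package, stated here once:

* Protocell-count, decay-rate and conservation checks: `V = 100`,
  `m = 0.01`, runs of 2e4 and 1.2e5 steps.
* Mutation-width recovery: increments logged over 1.2e5 steps, filtered
  to pre-mutation values at least 0.1 below `k_max`.
* Symmetry-breaking contrast: `V = 1000`, `m = 0.05`,
  `delta_mut = 0.1` (a stronger mutation supply than the published
  showcase) over 2.5e5 steps, against a high-relatedness control at
  `V = 100`, `m = 0.001`. In the control, activities stay near maximal
  and the classifier reports `none`, as expected. On the
  low-relatedness side, desk-scale runs show the *onset* of the
  transition — mean activities drift down and transient catalytic
  asymmetries appear and dissolve — but complete, classifier-grade
  breaking was not observed at these sizes: the measured relatedness
  stays near 0.9 (between-cell lineage divergence dominates the
  within-cell variance, which within-cell selection keeps far below its
  neutral level), well above the `R < 1/3` threshold that the
  phase-plane analysis requires. The published threefold breaking sits
  at division thresholds and horizons (`V >= ~3000`, ~1e7 steps) beyond
  a desktop run, so at desk scale the mechanism claim rests on the
  deterministic phase-plane module, with the agent-based runs
  exhibiting the approach to the transition.

## Known limitations

* The original reaction algorithm is cited, not printed; the pairing
  scheme here (disjoint pairs, acceptance proportional to summed channel
  rates, mass-action density factor) reproduces the printed
  proportionality and the reported protocell count, but is not guaranteed
  to match the original in finer statistics such as complex lifetimes.
* Decay is applied to every replicator each step, bound or free;
  complexes never span steps, so decay cannot interrupt synthesis.
* No spatial structure within or between protocells; no sequence
  complementarity (P and Q are abstract types).
* The Price decomposition here omits the transmission-bias term, which
  vanishes because mutation is unbiased.
* At very high mutation supply (`m >= ~0.1` at `V = 1000`) both types
  lose activity and runs classify as `uncategorized`; the symmetry-broken
  regime sits between that collapse and the high-relatedness `none`
  regime.
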