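---
title: "Generating synthetic mediator trajectories with smtgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic mediator trajectories with smtgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtgen)
```

## The problem

Machine-learning models for forecasting acute-illness trajectories need
dense multivariate time series of molecular mediators (cytokines), but
clinical panels are sparse: a handful of blood draws per patient at
irregular times, a few dozen patients per cohort, and within-group
variability that dwarfs between-group mean differences.  No amount of
resampling recovers the dynamics between draws, and the sampling is far too
thin to estimate a joint distribution over even a dozen mediators — so a
statistical generator is not an option.  `smtgen` takes the mechanistic
route: a stochastic agent-based model (ABM) of acute inflammation is
calibrated so that its simulated trajectory spaces cannot be rejected by
the sparse data, and the resulting ensemble of parameterizations is run to
emit dense, outcome-labeled synthetic mediator trajectories (SMTs).

Three requirements drive the design:

1. **Expansiveness.** Observed extremes of a sparsely sampled mediator are
   samples from a wider attainable range, not its boundary.  The generator
   must be able to exceed the observed min/max in a biologically plausible
   way.
2. **Distribution-freeness.** Nothing downstream assumes a parametric
   distribution for mediator values: calibration consumes only per-bin
   min/max envelopes of the data.
3. **Ensemble, not point estimate.** Sparse data cannot identify a single
   parameterization.  Calibration therefore characterizes the full set of
   parameterizations the data cannot falsify, and synthesis samples from
   that set.

## The Model Rule Matrix

Every behavioral rule in the ABM computes a *drive*
$d_r = \sum_j M_{rj}\, c_j$ from the local mediator concentrations $c_j$,
where $M$ is the **Model Rule Matrix (MRM)**: 25 rules (rows) by 17
mediator entities (columns).  $M_{rj}$ is the signed strength of mediator
$j$'s contribution to rule $r$; a zero means the interaction is absent from
the model.  The *base* matrix is sparse (62 of 425 elements nonzero,
`default_base_interactions()`): it encodes only the canonical couplings
(e.g. PAF and IFN-γ drive macrophage TNF-α secretion, IL-10 suppresses it).
The zero elements are the latent space — unmodeled genetic, epigenetic and
signaling influences — which calibration is free to switch on within the
coefficient bounds $[-2, 2]$, giving a maximal per-element range of $4.0$
across an ensemble.

Nine of the 17 entities (IL-1b, IL-1ra, IL-6, IL-4, IL-8, IL-10, GCSF,
IFNg, TNFa) correspond to a standard multiplexed serum panel and are
matched to reference data; the other eight (PAF, sTNFr, sIL-1r, IL-12,
GM-CSF, MIP-1b, NO, TGFb) are carried at the same dimensionality as
documented placeholder identities.  The 25 rules span five families —
cytokine secretion (up-regulation), cytokine uptake/neutralization
(down-regulation), cell activation, cellular differentiation, and
lifespan (endothelial damage and healing, immune-cell apoptosis) — owned
by endothelium, macrophages, neutrophils, TH0/TH1/TH2 cells and a
precursor pool.

## The simulator

The world is a toroidal lattice (default 30×30) representing the
endothelial–blood interface: one endothelial cell per site with a damage
state in $[0,1]$, mobile immune cells on top, and one diffusing/decaying
concentration field per entity.  A run starts from a contiguous injury
patch (`injury_size` sites at damage 1) that releases a PAF bolus; system
*health* is the fraction of undamaged endothelium.

Each step is synchronous: all rule drives are computed from the
start-of-step field snapshot, so no agent order bias exists and the update
is deterministic given the seed.  Rule responses are clipped-linear
(`min(max(d, 0), 2)`) for secretion rates and logistic
(`1/(1+e^{-(d+b)})`, structural bias $b = -1$ so resting probabilities are
low) for activation, differentiation, apoptosis and healing.  Secretion
deposits into the agent's site, scaled by activation (immune cells) or by
local damage (endothelium).  Fields then decay multiplicatively and
diffuse with an explicit 4-neighbor kernel ($D \le 0.25$ for stability);
macrophages and neutrophils chemotax up the IL-8 + PAF + MIP-1b gradient
when it exceeds a threshold, all other mobile cells random-walk on the
Moore neighborhood.  Differentiated precursors are replenished from an
implicit marrow pool, keeping the supply of naive cells roughly constant.

Outcomes are classified from health: `dead` if health ever falls to 0.2
(the run truncates), `resolved` if terminal health reaches 0.8, otherwise
`persistent-inflammation`.  These thresholds are configurable; the damage
(0.15/step) and healing (0.03/step) rates were tuned once so that the
default grid spans all three regimes as injury size grows, with a
stochastic mixed-outcome regime in between — the model-design analogue of
picking an interesting operating point, done before any calibration
experiments were frozen.

All stochasticity (initial placement, movement, differentiation and death
draws) flows from R's RNG; `run_simulation(config, mrm, seed)` is
bit-reproducible, and every higher-level component derives child seeds
from its master seed with a counter-based scheme (`derive_seeds()`), so
the entire pipeline replays from one integer.

## Reference data and the falsification envelope

`reference_dataset` objects hold sparse long-format observations
(subject, cohort, clinical day, entity, value).  `build_envelope()` bins
times into clinical days (left-open bins, so a boundary time joins the
preceding bin and horizon-edge bins are never singletons) and keeps only
the per-(cohort, entity, bin) min/max band, optionally widened by a factor
`alpha` ≥ 1 about its midpoint — observed extremes understate the
attainable range, so expansion only ever widens.

`falsify()` runs stochastic replicates of a candidate matrix, sweeping
injury sizes across replicates to represent varied insults, and forms the
simulated band per (entity, bin).  A bin is *covered* when the simulated
band intersects the data band; the candidate is non-falsified only if
every constrained bin is covered.  Intersection, not containment, is the
default criterion: it is the weakest test that can still reject, which is
what a non-falsifiability search needs (strict containment is available
via `strict = TRUE`).  Because observations carry multiplicative assay
noise, the simulated band is widened by the central-95% lognormal factor
`exp(±2·noise_sdlog)` — the forward model includes the observation model;
with `noise_sdlog = 0` the raw band is used.

## The synthetic cohort generator

Real burn/trauma cytokine panels are not redistributable, so
`generate_synthetic_reference()` emulates their structure from hidden
ground truth: cohort A subjects run the base matrix; cohort B subjects run
the base matrix shifted at three declared elements
(`default_cohort_perturbation()`: stronger PAF→TNF-α secretion drive,
stronger TNF-α→NO cytotoxicity, weaker IL-10→healing), a hyperinflammatory
phenotype.  Each subject gets an independent seed, an injury size drawn
uniformly from 20–80 sites (spanning resolution to death on the 16×16
desk-scale grid), 3–8 irregular sampling times, and lognormal noise with
`sdlog = 0.3` (a ~30% assay CV, typical of multiplexed panels).  Defaults
are 20 subjects per cohort.  These choices were fixed once as the study
conditions; the generated cohorts reproduce the clinical pathologies —
sparsity, non-Gaussian values, and the overlap property (for every
mediator the between-cohort mean difference is smaller than the
within-cohort range, `cohort_overlap()`).

The hidden matrices are returned alongside the data solely so recovery
experiments can measure whether calibration brackets them.

## Calibration: GA plus active learning

`ga_search()` evolves a population (default 24) from the base matrix with
uniform elementwise crossover and additive-uniform mutation with clipping;
mutation switching zeros on is the enrichment mechanism.  Fitness is mean
envelope coverage; ties break toward fewer violations, then smaller L1
deviation from base.  Elitism makes best fitness monotone.  The GA's main
products are labeled candidates (both verdicts) and enriched valid
members.

`al_refine()` maps the boundary of the valid set in two phases.  Phase
one is pool-based active learning: a balanced random-forest surrogate
(balanced class sampling, since falsified candidates far outnumber valid
ones) scores diffuse proposals, and each round the batch with the highest
predicted-validity × range-gain is simulated, with a random exploration
fraction as insurance against surrogate miscalibration; candidates that
pass are confirmed at a fresh seed before joining the ensemble, so stored
verdicts are robust to replicate noise.  Phase two is a
systematic boundary sweep: every matrix element is probed toward each
bound from a near-base carrier, and blocked elements are retried in chain
passes from members accepted earlier — correlated corners of the valid
region (where single-axis moves are invalid but joint moves are valid)
are reachable only through such chains.  Sweep probes use a cheap
two-replicate screen followed by a fresh-seed confirmation at the full
replicate count before a member joins the ensemble.  The returned
`valid_ensemble` contains every confirmed non-falsified matrix and its
per-element range matrix — the desk-scale analogue of the ensemble range
heat map, whose element ranges approach the maximal 4.0 where the data do
not constrain the coefficient.

On the desk-scale recovery experiment the hidden matrices are
non-falsified by the envelopes their own subjects generated, and the
combined ensemble's ranges bracket the hidden coefficient values at the
declared-perturbed elements; the package's tests and
`scripts/acceptance.R` recompute these checks from scratch.

## Cohort typing and SMT generation

Because the intersection criterion is permissive, near-base matrices are
usually compatible with *both* cohorts' envelopes, so raw per-cohort
ensembles overlap and their trajectory spaces could never separate.
Cohort typing is therefore one-sided (`select_cohort_members()`): a
member is case-typed only if it is non-falsified by the case envelope
*and* falsified by the control envelope — the control data reject its
dynamics.  Control members are drawn from the control ensemble.
`generate_smt()` then runs seeded replicates per member; every trajectory
carries its member's cohort tag, outcome and provenance, dense at the
simulation cadence (every 4 steps = 0.5 days on the desk-scale grid,
versus 3–8 draws per reference subject).

`compute_separation()` reports, per entity, the time windows where the
two cohort envelopes are disjoint — windows that typically fall between
the sparse sampling times, which is precisely the argument for dense
synthetic data.  `expansion_check()` reports how far the synthetic
envelope extends beyond the observed reference extremes.

## Numerical and design notes

* **Problem sizes.** The worked examples, tests and acceptance script use
  a 16×16 grid, 80 steps (10 clinical days at 8 steps/day), 58 mobile
  cells, 2 × 20 subjects, GA population 24 × 4 generations with
  5-replicate evaluations, and an AL phase of two uncertainty rounds plus
  a full two-sided element sweep with two chain passes.  These sizes keep a
  full calibration at minutes on a single core while preserving the
  qualitative regimes of the default 30×30 grid; they are the package's
  desk-scale defaults, not limits of the method.
* **Seeds.** All child seeds derive from one master seed and stay below
  2^31; per-candidate evaluation seeds are counter-based so a candidate's
  stochastic fitness is reproducible regardless of evaluation order.
* **Ties and degenerate inputs.** Empty envelope cohorts are refused
  (vacuous non-falsification is not success); singleton ensembles give an
  all-zero range matrix; chemotaxis ties resolve to the first maximal
  neighbor; `injury_size = 0` yields health ≡ 1 and outcome `resolved`.
* **Known limitations.** The rule catalog is a structural reconstruction
  at the published dimensionality (25 × 17), not a port of the original
  inflammation ABM's equations; absolute concentrations are in arbitrary
  units, so only range/band comparisons are meaningful; the element sweep
  maps per-element boundaries conditional on the sampled ensemble, so
  range matrices are lower bounds on the true valid region; and passing
  the synthetic-cohort tests shows the pipeline recovers structure under
  the stated noise and sampling model — real panels add pathologies
  (detection limits, batch effects, informative sampling) that this
  generator does not emulate.

## A minimal session

```{r example, eval = FALSE}
library(smtgen)

# 1. a synthetic two-cohort reference panel with hidden ground truth
gen <- generate_synthetic_reference(refgen_config(), seed = 1)
env <- build_envelope(gen$data, bin_width = 1, alpha = 1)

# 2. calibrate each cohort: GA search, then boundary-mapping AL
cfg   <- default_toy_sim_config()
sweep <- round(seq(20, 80, length.out = 5))
base  <- build_base_mrm()
gaB  <- ga_search(base, env, "B", ga_config(), cfg, seed = 2,
                  injury_sizes = sweep, noise_sdlog = 0.3)
ensB <- al_refine(gaB, env, al_config(), cfg, seed = 3)

# 3. did the ensemble bracket the hidden truth?
recover_parameters_check(gen$hidden["B"], ensB, gen$perturbation)

# 4. labeled synthetic trajectory spaces and their diagnostics
gaA  <- ga_search(base, env, "A", ga_config(), cfg, seed = 4,
                  injury_sizes = sweep, noise_sdlog = 0.3)
ensA <- al_refine(gaA, env, al_config(sweep = FALSE), cfg, seed = 5)
members <- select_cohort_members(ensA, ensB, env, cfg, k = 12, seed = 6,
                                 injury_sizes = sweep, noise_sdlog = 0.3)
smt <- generate_smt(members, per_member_replicates = 4, cfg, seed = 7,
                    injury_sizes = sweep)
compute_separation(smt)
expansion_check(smt, gen$data)
export_smt(smt, "smt_out", "csv-long")
```
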