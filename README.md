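# smtgen

Synthetic mediator trajectories from ensemble-calibrated agent-based models
of acute inflammation.

## The problem

Forecasting models for acute illness (sepsis, trauma, ARDS) need dense
multivariate time series of blood mediators, but clinical cytokine panels
are sparse: 3–8 draws per patient at irregular times, a few dozen patients
per cohort, and within-cohort variability that dwarfs between-cohort mean
differences.  That sampling is far too thin to estimate a joint
distribution over a dozen mediators, so statistical synthetic-data
generators have nothing to fit.  `smtgen` takes the mechanistic route
instead and is aimed at computational immunologists and ML researchers who
need labeled, dense, biologically grounded training series.

## The method

1. **Simulator.** A stochastic 2-D agent-based model of the
   endothelial–blood interface: endothelium with a damage state, mobile
   macrophages, neutrophils, TH0/TH1/TH2 cells and precursors, and 17
   diffusing mediator fields.  Every behavioral rule r computes a drive
   from local concentrations c,

       d_r = sum_j M[r, j] * c_j ,

   where **M** is the Model Rule Matrix (MRM): 25 rules x 17 entities,
   element M[r, j] the signed strength of mediator j's contribution to
   rule r, zeros marking latent (unmodeled) interactions, coefficients
   bounded in [-2, 2].  Outcomes (resolved / persistent-inflammation /
   dead) follow from endothelial health.

2. **Falsification.** Sparse observations are reduced to per-(cohort,
   entity, day) min/max envelopes — no distributional assumptions.  A
   candidate MRM is *non-falsified* when the band swept by its stochastic
   replicates (across an injury-severity sweep, widened by the known assay
   noise) intersects every constrained envelope bin.

3. **Calibration.** A genetic algorithm evolves enriched MRMs (mutation
   switches latent zeros on); active learning with a random-forest
   surrogate plus a systematic per-element boundary sweep maps the full
   ensemble of non-falsifiable MRMs and its per-element range matrix.

4. **Synthesis.** Cohort-typed ensemble members (a case-type member is
   non-falsified by the case envelope *and* falsified by the control
   envelope) are run with seeded replicates to emit dense, outcome-labeled
   synthetic mediator trajectories (SMTs), with cohort-separation and
   range-expansion diagnostics.

Because the real burn/trauma panels are not redistributable, the package
ships a synthetic clinical-cohort generator with hidden ground-truth MRMs,
which doubles as the recovery-testing harness.

## Worked example

```r
library(smtgen)

# sparse two-cohort reference panel (hidden ground truth returned too)
gen <- generate_synthetic_reference(refgen_config(), seed = 1)
env <- build_envelope(gen$data, bin_width = 1, alpha = 1)
gen$data
#> Reference dataset: 1998 observations, 40 subjects, 9 entities; cohorts: A, B

# calibrate the hyperinflammatory cohort: GA search + boundary-mapping AL
cfg   <- default_toy_sim_config()
sweep <- round(seq(20, 80, length.out = 5))
gaB  <- ga_search(build_base_mrm(), env, "B", ga_config(), cfg, seed = 2,
                  injury_sizes = sweep, noise_sdlog = 0.3)
ensB <- al_refine(gaB, env, al_config(), cfg, seed = 3)
ensB
#> Valid ensemble: 698 non-falsified MRMs (cohort B ); max element range 3.899

# does the ensemble bracket the hidden truth?
recover_parameters_check(gen$hidden["B"], ensB, gen$perturbation)
#>   hidden containment containment_perturbed
#> 1      B           1                     1
```

`containment` is the fraction of the hidden matrix's 425 elements lying
inside the ensemble's per-element [min, max]; `containment_perturbed`
restricts that to the declared cohort-B coefficient shifts.  A light
calibration of cohort A plus `select_cohort_members()`, `generate_smt()`,
`compute_separation()` and `expansion_check()` then yield the labeled SMT
export — see the methods vignette (`vignettes/smtgen-methods.Rmd`) for the
full session and the scientific rationale of every step.

A command-line wrapper over the same functions lives at
`inst/cli/smtgen.R`:

```sh
Rscript inst/cli/smtgen.R make-reference --config run.yaml --out ref
Rscript inst/cli/smtgen.R calibrate --config run.yaml --reference ref/reference.csv --out ens
Rscript inst/cli/smtgen.R generate --config run.yaml --ensemble ens --out smt --reference ref/reference.csv
```

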