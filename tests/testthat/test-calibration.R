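# falsification and search tests run on the tiny 10x10 world

test_that("an MRM is never falsified by the envelope of its own outputs", {
  cfg <- tiny_sim_config()
  m <- enriched_test_mrm(seed = 1, rate = 0.05, scale = 0.4)
  ts <- run_replicates(cfg, m, n = 3, base_seed = 5)
  day <- cfg$steps_per_day
  obs <- do.call(rbind, lapply(seq_along(ts$replicates), function(i) {
    tr <- ts$replicates[[i]]
    ok <- !is.na(tr$health)
    ent <- m$entities$observed
    data.frame(subject_id = paste0("r", i), cohort = "A",
               time = rep(tr$times[ok] / day, length(ent)),
               entity = rep(ent, each = sum(ok)),
               value = as.vector(tr$values[ok, ent]))
  }))
  env <- build_envelope(reference_dataset(obs), 1, alpha = 1)
  # matched seeds: the falsification replicates are the envelope's own runs
  rep <- falsify(m, env, "A", cfg, n_replicates = 3, base_seed = 5)
  expect_equal(rep$verdict, "non-falsified")
  expect_equal(rep$coverage_fraction, 1.0)
})

test_that("an unreachable envelope bin falsifies the candidate", {
  cfg <- tiny_sim_config()
  m <- build_base_mrm()
  # GCSF column zeroed out of every rule: nothing can secrete it
  m$values["mac_gcsf_secretion", ] <- 0
  env <- structure(list(bands = data.frame(
    cohort = "A", entity = c("TNFa", "GCSF"), bin_start = c(1, 1),
    lo = c(0, 50), hi = c(1e6, 60)), bin_width = 1, alpha = 1),
    class = "envelope")
  rep <- falsify(m, env, "A", cfg, n_replicates = 2, base_seed = 3)
  expect_equal(rep$verdict, "falsified")
  expect_equal(rep$violations$entity, "GCSF")
  expect_true(rep$bins$covered[rep$bins$entity == "TNFa"])
  # coverage is non-decreasing in alpha for fixed candidate and seeds
  gen <- generate_synthetic_reference(tiny_refgen_config(), seed = 31)
  cov <- vapply(c(1, 1.5, 2.5), function(a) {
    e <- build_envelope(gen$data, 1, alpha = a)
    falsify(build_base_mrm(), e, "A", cfg, n_replicates = 2,
            base_seed = 7)$coverage_fraction
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
  # vacuous falsification is refused
  envB <- structure(list(bands = env$bands[0, ], bin_width = 1, alpha = 1),
                    class = "envelope")
  expect_error(falsify(m, envB, "A", cfg), class = "smtgen_param_error")
  expect_error(falsify(m, env, "A", cfg, n_replicates = 1),
               class = "smtgen_param_error")
})

test_that("strict band containment is at least as demanding as intersection", {
  cfg <- tiny_sim_config()
  gen <- generate_synthetic_reference(tiny_refgen_config(), seed = 33)
  env <- build_envelope(gen$data, 1, 1)
  m <- build_base_mrm()
  loose <- falsify(m, env, "A", cfg, n_replicates = 2, base_seed = 11)
  tight <- falsify(m, env, "A", cfg, n_replicates = 2, base_seed = 11,
                   strict = TRUE)
  expect_lte(tight$coverage_fraction, loose$coverage_fraction)
})

test_that("the measurement-noise allowance only widens the simulated band", {
  cfg <- tiny_sim_config()
  gen <- generate_synthetic_reference(tiny_refgen_config(), seed = 35)
  env <- build_envelope(gen$data, 1, 1)
  m <- build_base_mrm()
  c0 <- falsify(m, env, "A", cfg, 2, base_seed = 13)$coverage_fraction
  c1 <- falsify(m, env, "A", cfg, 2, base_seed = 13,
                noise_sdlog = 0.3)$coverage_fraction
  expect_gte(c1, c0)
})

test_that("GA keeps elitist monotone best fitness and records candidates", {
  cfg <- tiny_sim_config()
  gen <- generate_synthetic_reference(tiny_refgen_config(), seed = 41)
  env <- build_envelope(gen$data, 1, 1)
  base <- build_base_mrm()
  ga <- ga_search(base, env, "A",
                  ga_config(pop_size = 6, generations = 3,
                            n_replicates = 2),
                  cfg, seed = 17, injury_sizes = c(10, 25),
                  noise_sdlog = 0.3)
  expect_true(all(diff(ga$best_by_generation) >= 0))
  expect_equal(nrow(ga$records), length(ga$candidates))
  expect_true(all(ga$records$fitness >= 0 & ga$records$fitness <= 1))
  # rerunning with the same master seed reproduces the records exactly
  ga2 <- ga_search(base, env, "A",
                   ga_config(pop_size = 6, generations = 3,
                             n_replicates = 2),
                   cfg, seed = 17, injury_sizes = c(10, 25),
                   noise_sdlog = 0.3)
  expect_equal(ga$records, ga2$records)
  # GA-evolved population is denser than the sparse base (enrichment)
  pop <- ga$candidates[ga$population_ids]
  expect_gte(stats::median(vapply(pop, mrm_nonzero_count, numeric(1))),
             mrm_nonzero_count(base))
})

test_that("a clone population is a GA fixed point with reproducible fitness", {
  cfg <- tiny_sim_config()
  m <- enriched_test_mrm(seed = 2, rate = 0.02, scale = 0.3)
  ts <- run_replicates(cfg, m, n = 2, base_seed = 19)
  day <- cfg$steps_per_day
  obs <- do.call(rbind, lapply(seq_along(ts$replicates), function(i) {
    tr <- ts$replicates[[i]]
    ent <- m$entities$observed
    ok <- !is.na(tr$health)
    data.frame(subject_id = paste0("r", i), cohort = "A",
               time = rep(tr$times[ok] / day, length(ent)),
               entity = rep(ent, each = sum(ok)),
               value = as.vector(tr$values[ok, ent]))
  }))
  env <- build_envelope(reference_dataset(obs), 1, 1)
  ga <- ga_search(m, env, "A",
                  ga_config(pop_size = 4, generations = 1,
                            mutation_rate = 0, crossover_prob = 0,
                            n_replicates = 2),
                  cfg, seed = 19, noise_sdlog = 0)
  # every candidate is an exact clone of the seed matrix
  expect_true(all(ga$records$deviation == 0))
  # each recorded fitness equals the coverage recomputed independently at
  # the candidate's stored counter-based evaluation seed
  for (i in seq_len(nrow(ga$records))) {
    f <- falsify(m, env, "A", cfg, n_replicates = 2,
                 base_seed = ga$records$eval_seed[i])
    expect_equal(ga$records$fitness[i], f$coverage_fraction)
  }
})

test_that("active learning maps a wider boundary than the GA alone", {
  cfg <- default_toy_sim_config()
  gen <- generate_synthetic_reference(refgen_config(n_subjects = c(A = 6, B = 6)),
                                      seed = 43)
  env <- build_envelope(gen$data, 1, 1)
  base <- build_base_mrm()
  ga <- ga_search(base, env, "A",
                  ga_config(pop_size = 8, generations = 2, n_replicates = 3),
                  cfg, seed = 23, injury_sizes = c(20, 50, 80),
                  noise_sdlog = 0.3)
  expect_true(any(ga$records$non_falsified) &&
                !all(ga$records$non_falsified))
  ens <- al_refine(ga, env,
                   al_config(rounds = 1, batch_size = 4, sweep = FALSE,
                             n_replicates = 3),
                   cfg, seed = 29)
  ga_valid <- ga$candidates[ga$records$non_falsified]
  expect_gte(length(ens$members), length(ga_valid))
  # range-matrix monotonicity under the superset
  expect_true(all(unclass(ens$range_matrix) >=
                    unclass(element_ranges(ga_valid)) - 1e-12))
  # epsilon = Inf stops phase one after exactly one round
  ens1 <- al_refine(ga, env,
                    al_config(rounds = 5, batch_size = 4, sweep = FALSE,
                              epsilon = Inf, n_replicates = 3),
                    cfg, seed = 29)
  expect_true(all(ens1$info$round <= 1))
  # single-class seed labels are rejected with guidance
  ga_all_valid <- ga
  ga_all_valid$records$non_falsified <- TRUE
  expect_error(al_refine(ga_all_valid, env, al_config(), cfg),
               class = "smtgen_param_error", regexp = "widen")
})

test_that("ensemble members survive a stochastic re-test at fresh seeds", {
  cfg <- default_toy_sim_config()
  gen <- generate_synthetic_reference(refgen_config(), seed = 43)
  env <- build_envelope(gen$data, 1, 1)
  base <- build_base_mrm()
  sweep <- c(20, 35, 50, 65, 80)
  ga <- ga_search(base, env, "A",
                  ga_config(pop_size = 8, generations = 2, n_replicates = 5),
                  cfg, seed = 37, injury_sizes = sweep, noise_sdlog = 0.3)
  ens <- al_refine(ga, env,
                   al_config(rounds = 3, batch_size = 8, sweep = FALSE,
                             n_replicates = 5),
                   cfg, seed = 41)
  # per-member re-verdict = majority over three independent fresh-seed
  # falsification tests at the stored evaluation settings
  redo <- vapply(ens$members, function(m) {
    ok <- vapply(c(997, 1337, 2024), function(rs) {
      falsify(m, env, "A", cfg, n_replicates = 5, base_seed = rs,
              injury_sizes = sweep, noise_sdlog = 0.3)$verdict ==
        "non-falsified"
    }, logical(1))
    mean(ok) > 0.5
  }, logical(1))
  expect_gte(mean(redo), 0.9)
})

test_that("recovery summary reports containment of hidden matrices", {
  base <- build_base_mrm()
  set.seed(51)
  m2 <- mrm_mutate(base, 0.1, 0.6)
  ens <- valid_ensemble(list(base, m2))
  # a hidden matrix that IS a member is fully contained
  rec <- recover_parameters_check(list(base), ens)
  expect_equal(rec$containment, 1.0)
  # an interior blend is contained elementwise
  blend <- base
  blend$values <- (base$values + m2$values) / 2
  expect_equal(recover_parameters_check(list(blend), ens)$containment, 1.0)
  # a matrix far outside the ensemble is not
  far <- base
  far$values[] <- clamp(base$values + 1.9, -2, 2)
  expect_lt(recover_parameters_check(list(far), ens)$containment, 0.5)
  # perturbed-element summary tracks the declared subset
  pert <- data.frame(rule = "mac_tnf_secretion", entity = "PAF")
  h <- base
  h$values["mac_tnf_secretion", "PAF"] <-
    m2$values["mac_tnf_secretion", "PAF"]
  rp <- recover_parameters_check(list(h), ens, perturbation = pert)
  expect_equal(rp$containment_perturbed, 1.0)
})

test_that("combined per-cohort ensembles keep tags and widen ranges", {
  base <- build_base_mrm()
  set.seed(53)
  ea <- valid_ensemble(list(base, mrm_mutate(base, 0.05, 0.4)), cohorts = "A")
  eb <- valid_ensemble(list(mrm_mutate(base, 0.05, 0.8)), cohorts = "B")
  comb <- combine_ensembles(ea, eb)
  expect_equal(length(comb$members), 3)
  expect_setequal(unique(comb$info$cohort), c("A", "B"))
  expect_true(all(unclass(comb$range_matrix) >=
                    unclass(ea$range_matrix) - 1e-12))
})
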