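# small fixed ensemble used across SMT tests
smt_fixture <- function(n_members = 2, reps = 2, seed = 61) {
  base <- build_base_mrm()
  set.seed(seed)
  ea <- valid_ensemble(list(base), cohorts = "A")
  eb <- valid_ensemble(lapply(seq_len(n_members - 1), function(i)
    mrm_mutate(base, 0.05, 0.5)), cohorts = "B")
  ens <- combine_ensembles(ea, eb)
  generate_smt(ens, per_member_replicates = reps, tiny_sim_config(),
               seed = seed)
}

test_that("dataset size, labels and envelopes follow the ensemble", {
  base <- build_base_mrm()
  e1 <- valid_ensemble(list(base), cohorts = "A")
  one <- generate_smt(e1, per_member_replicates = 1, tiny_sim_config(),
                      seed = 63)
  expect_equal(nrow(one$runs), 1)

  smt <- smt_fixture(n_members = 3, reps = 2)
  expect_equal(nrow(smt$runs), 3 * 2)
  # label fidelity: every run's cohort matches its source member's tag
  expect_equal(as.integer(table(smt$runs$cohort)[c("A", "B")]), c(2L, 4L))
  # every trajectory lies inside its cohort envelope
  for (co in names(smt$envelopes)) {
    env <- smt$envelopes[[co]]
    tr <- smt$trajectories[smt$trajectories$cohort == co, ]
    ti <- match(round(tr$time * smt$config$steps_per_day), env$times)
    ei <- match(tr$entity, colnames(env$env_lo))
    expect_true(all(tr$value >= env$env_lo[cbind(ti, ei)] - 1e-9))
    expect_true(all(tr$value <= env$env_hi[cbind(ti, ei)] + 1e-9))
  }
  # density: dense at the simulation cadence (dead runs truncate early);
  # a full-length run has 11 sampled times vs 3-8 reference draws
  times_per_run <- tapply(smt$trajectories$time, smt$trajectories$run_id,
                          function(t) length(unique(t)))
  full <- smt$runs$run_id[smt$runs$outcome != "dead"]
  expect_true(all(times_per_run[full] == 11))
  expect_gte(max(times_per_run), 10)
  expect_error(generate_smt(valid_ensemble(list(base))[-1],
                            config = tiny_sim_config()),
               class = "smtgen_param_error")
})

test_that("regeneration from the same master seed is identical", {
  a <- smt_fixture(seed = 67)
  b <- smt_fixture(seed = 67)
  expect_equal(a$trajectories, b$trajectories)
  expect_equal(a$runs, b$runs)
  expect_identical(a$config_hash, b$config_hash)
})

test_that("separation finds disjoint windows exactly where bands separate", {
  smt <- smt_fixture(n_members = 2, reps = 2)
  # identical cohorts: relabel the same envelope -> zero separation
  same <- smt
  same$envelopes <- list(A = smt$envelopes[["A"]], B = smt$envelopes[["A"]])
  sep0 <- compute_separation(same)
  expect_true(all(sep0$overlap_fraction == 1))
  expect_true(all(sep0$n_disjoint == 0))
  # hand-built bands [0,1] vs [2,3] at all times for one entity
  forced <- smt
  ents <- colnames(forced$envelopes[[1]]$env_lo)
  nt <- length(forced$envelopes[[1]]$times)
  mk <- function(lo, hi) {
    m_lo <- matrix(0, nt, length(ents), dimnames = list(NULL, ents))
    m_hi <- m_lo
    m_lo[, "TNFa"] <- lo; m_hi[, "TNFa"] <- hi
    list(times = forced$envelopes[[1]]$times, env_lo = m_lo, env_hi = m_hi)
  }
  forced$envelopes <- list(A = mk(0, 1), B = mk(2, 3))
  sep1 <- compute_separation(forced)
  tn <- sep1$entities[["TNFa"]]
  expect_equal(nrow(tn$intervals), 1)
  expect_equal(tn$intervals$start, min(forced$times))
  expect_equal(tn$intervals$end, max(forced$times))
  expect_equal(tn$overlap_fraction, 0)
  # other entities share the band [0,0] vs [0,0]: always overlapping
  expect_equal(sep1$entities[["IL-6"]]$overlap_fraction, 1)
  # single-cohort dataset is refused
  single <- smt
  single$envelopes <- smt$envelopes["A"]
  expect_error(compute_separation(single), class = "smtgen_param_error")
})

test_that("expansion summary measures extension beyond observed extremes", {
  smt <- smt_fixture()
  # a clipped control: observations spanning exactly the SMT range per entity
  tr <- smt$trajectories
  obs_ents <- intersect(unique(tr$entity), default_observed_entities())
  ctrl <- do.call(rbind, lapply(obs_ents, function(e) {
    v <- range(tr$value[tr$entity == e])
    data.frame(subject_id = c("c1", "c2"), cohort = c("A", "B"),
               time = 1, entity = e, value = v)
  }))
  ctrl_ref <- reference_dataset(ctrl)
  ex0 <- expansion_check(smt, ctrl_ref)
  expect_true(all(ex0$ext_low == 0 & ex0$ext_high == 0))
  expect_false(any(ex0$expands))
  # narrower observations -> strictly positive extension
  ctrl2 <- ctrl
  nonzero <- ctrl2$entity %in% tr$entity[tr$value > 0]
  ctrl2$value <- ctrl2$value * 0.5
  ex1 <- expansion_check(smt, reference_dataset(ctrl2))
  expect_true(any(ex1$expands))
  expect_true(all(ex1$ext_low >= 0 & ex1$ext_high >= 0))
})

test_that("exports round-trip and manifests hash the configuration", {
  smt <- smt_fixture()
  d1 <- file.path(tempdir(), "smt_export_a")
  export_smt(smt, d1, "csv-long")
  back <- load_smt(d1)
  expect_equal(back$trajectories, smt$trajectories, tolerance = 1e-12)
  expect_equal(back$runs, smt$runs, tolerance = 1e-12)
  expect_identical(back$config_hash, smt$config_hash)
  for (co in names(smt$envelopes)) {
    expect_equal(back$envelopes[[co]]$env_lo, smt$envelopes[[co]]$env_lo,
                 tolerance = 1e-9)
  }
  # csv-wide: one row per (run, time), one column per entity
  d2 <- file.path(tempdir(), "smt_export_b")
  export_smt(smt, d2, "csv-wide")
  wide <- utils::read.csv(file.path(d2, "smt_wide.csv"))
  per_run_times <- tapply(smt$trajectories$time, smt$trajectories$run_id,
                          function(t) length(unique(t)))
  expect_equal(nrow(wide), sum(per_run_times))
  expect_true(all(default_observed_entities() %in%
                    sub("^X", "", gsub("\\.", "-", names(wide)))) ||
                all(c("TNFa", "GCSF") %in% gsub("\\.", "", names(wide))) ||
                ncol(wide) >= 4 + 17)
  # manifest hash changes iff the configuration changes
  man1 <- jsonlite::fromJSON(file.path(d1, "smt_manifest.json"))
  smt2 <- smt_fixture(seed = 61)   # identical build
  expect_identical(smt2$config_hash, man1$config_hash)
  cfg2 <- tiny_sim_config(injury_size = 16)
  base <- build_base_mrm()
  smt3 <- generate_smt(valid_ensemble(list(base), cohorts = "A"), 2, cfg2,
                       seed = 61)
  expect_false(identical(smt3$config_hash, man1$config_hash))
})
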