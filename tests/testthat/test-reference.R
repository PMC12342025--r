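test_that("reference CSV parsing validates and round-trips", {
  df <- data.frame(subject_id = c("s1", "s1", "s2"),
                   cohort = c("A", "A", "B"),
                   time = c(0.5, 2, 1),
                   entity = c("TNFa", "IL-6", "TNFa"),
                   value = c(1.5, 2.5, 0.2))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  d <- load_reference(f)
  expect_s3_class(d, "reference_dataset")
  expect_equal(nrow(d$observations), 3)
  # save -> load preserves the record multiset
  f2 <- tempfile(fileext = ".csv")
  save_reference(d, f2)
  d2 <- load_reference(f2)
  expect_equal(d2$observations[order(d2$observations$subject_id,
                                     d2$observations$time,
                                     d2$observations$entity), ],
               d$observations[order(d$observations$subject_id,
                                    d$observations$time,
                                    d$observations$entity), ],
               ignore_attr = TRUE)

  bad <- df; bad$value[2] <- -1
  expect_error(reference_dataset(bad), class = "smtgen_validation_error",
               regexp = "2")
  bad2 <- df; bad2$entity[1] <- "NotACytokine"
  expect_error(reference_dataset(bad2), class = "smtgen_validation_error")
  bad3 <- rbind(df, df[1, ])
  expect_error(reference_dataset(bad3), class = "smtgen_validation_error",
               regexp = "duplicate")
  bad4 <- df; bad4$cohort[2] <- "B"  # s1 in two cohorts
  expect_error(reference_dataset(bad4), class = "smtgen_validation_error")
})

test_that("envelopes bin observations and widen symmetrically with alpha", {
  df <- data.frame(subject_id = c("s1", "s2", "s3"),
                   cohort = "A", time = c(0.25, 0.75, 3),
                   entity = "TNFa", value = c(2, 6, 4))
  d <- reference_dataset(df)
  e1 <- build_envelope(d, bin_width = 1, alpha = 1)
  b0 <- e1$bands[e1$bands$bin_start == 0, ]
  expect_equal(c(b0$lo, b0$hi), c(2, 6))
  # single observation in a bin: degenerate band (t = 3 is on a boundary,
  # so it belongs to the left-open bin starting at 2)
  b3 <- e1$bands[e1$bands$bin_start == 2, ]
  expect_equal(c(b3$lo, b3$hi), c(4, 4))
  # alpha widens about the midpoint: {2, 6} at alpha 1.5 -> [1, 7]
  e15 <- build_envelope(d, 1, 1.5)
  b0w <- e15$bands[e15$bands$bin_start == 0, ]
  expect_equal(c(b0w$lo, b0w$hi), c(1, 7))
  # monotone widening: alpha 2 interval contains alpha 1 interval
  e2 <- build_envelope(d, 1, 2)
  expect_true(all(e2$bands$lo <= e1$bands$lo + 1e-12))
  expect_true(all(e2$bands$hi >= e1$bands$hi - 1e-12))
  expect_error(build_envelope(d, 1, 0.5), class = "smtgen_param_error")
  # adding observations never narrows a bin's raw band
  d2 <- reference_dataset(rbind(df, data.frame(subject_id = "s4",
                                               cohort = "A", time = 0.5,
                                               entity = "TNFa", value = 9)))
  e3 <- build_envelope(d2, 1, 1)
  b0b <- e3$bands[e3$bands$bin_start == 0, ]
  expect_lte(b0b$lo, b0$lo)
  expect_gte(b0b$hi, b0$hi)
  # JSON round trip
  f <- tempfile(fileext = ".json")
  save_envelope(e1, f)
  expect_equal(load_envelope(f)$bands, e1$bands, tolerance = 1e-12)
})

test_that("a time on a bin boundary folds into the preceding bin", {
  df <- data.frame(subject_id = c("s1", "s2"), cohort = "A",
                   time = c(1.0, 0.2), entity = "TNFa", value = c(5, 1))
  e <- build_envelope(reference_dataset(df), bin_width = 1, alpha = 1)
  expect_equal(nrow(e$bands), 1)
  expect_equal(e$bands$bin_start, 0)
  expect_equal(c(e$bands$lo, e$bands$hi), c(1, 5))
})

test_that("synthetic reference reproduces the clinical data pathologies", {
  gen <- generate_synthetic_reference(tiny_refgen_config(
    n_subjects = c(A = 8, B = 8)), seed = 77)
  o <- gen$data$observations
  expect_setequal(unique(o$cohort), c("A", "B"))
  expect_setequal(unique(o$entity), default_observed_entities())
  expect_true(all(o$value >= 0))
  # sparsity: at most 8 sampling times per subject
  times_per_subj <- tapply(o$time, o$subject_id,
                           function(t) length(unique(t)))
  expect_true(all(times_per_subj <= 8))
  expect_true(all(times_per_subj >= 3))
  # cohort overlap: within-group range exceeds between-group mean difference
  ov <- cohort_overlap(gen$data)
  expect_true(all(ov$overlap))
  # regeneration with the same seed is identical
  gen2 <- generate_synthetic_reference(tiny_refgen_config(
    n_subjects = c(A = 8, B = 8)), seed = 77)
  expect_equal(gen2$data$observations, gen$data$observations)
  expect_equal(gen2$subjects, gen$subjects)
  # hidden truth: cohort A is the base matrix, cohort B differs exactly at
  # the declared perturbed elements
  base <- build_base_mrm()
  expect_equal(gen$hidden$A[[1]]$values, base$values)
  diff_idx <- which(gen$hidden$B[[1]]$values != base$values)
  pert <- gen$perturbation
  expected <- sort((match(pert$entity, base$entities$names) - 1L) * 25L +
                     match(pert$rule, base$rules$rules$id))
  expect_equal(sort(diff_idx), expected)
})

test_that("noiseless observations equal the simulator aggregates exactly", {
  gc <- tiny_refgen_config(n_subjects = c(A = 2, B = 2), noise_sdlog = 0)
  gen <- generate_synthetic_reference(gc, seed = 9)
  o <- gen$data$observations
  for (sid in unique(o$subject_id)) {
    meta <- gen$subjects[gen$subjects$subject_id == sid, ]
    cfg <- gc$sim_config
    cfg$injury_size <- meta$injury_size
    tr <- run_simulation(cfg, gen$hidden[[meta$cohort]][[meta$hidden_idx]],
                         seed = meta$seed)
    os <- o[o$subject_id == sid, ]
    step_idx <- match(round(os$time * cfg$steps_per_day), tr$times)
    ent_idx <- match(os$entity, colnames(tr$values))
    expect_equal(os$value, tr$values[cbind(step_idx, ent_idx)],
                 tolerance = 1e-12)
  }
})
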