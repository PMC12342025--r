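# shared fixtures: all built in code, sized for fast unit tests

# minimal simulation config: 10x10 grid, 40 steps (5 clinical days)
tiny_sim_config <- function(...) {
  args <- list(grid_width = 10, grid_height = 10,
               census = list(macrophage = 8, neutrophil = 8, TH0 = 5,
                             TH1 = 2, TH2 = 2, precursor = 5),
               injury_size = 15, duration = 40, sampling_interval = 4,
               steps_per_day = 8, replicate_count = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

tiny_refgen_config <- function(...) {
  args <- list(sim_config = tiny_sim_config(),
               n_subjects = c(A = 4, B = 4),
               samples_range = c(3, 6),
               injury_range = c(8, 30))
  over <- list(...)
  args[names(over)] <- over
  do.call(refgen_config, args)
}

# a deterministic enriched matrix for tests that need a non-base MRM
enriched_test_mrm <- function(seed = 42, rate = 0.1, scale = 0.5) {
  set.seed(seed)
  mrm_mutate(build_base_mrm(), rate, scale)
}

expect_identical_mrm <- function(a, b) {
  expect_equal(a$values, b$values)
  expect_identical(a$base_mask, b$base_mask)
  expect_identical(a$entities$names, b$entities$names)
  expect_identical(a$rules$rules$id, b$rules$rules$id)
}
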