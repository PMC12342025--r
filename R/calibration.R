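#' Test an MRM for falsification against a cohort envelope
#'
#' Runs `n_replicates` stochastic simulations of the candidate and, for
#' every constrained (entity, bin) of the cohort's envelope, forms the
#' simulated band: the min/max of the entity's grid aggregate over all
#' replicates at all sampled times mapping into the bin (simulation steps
#' are converted to clinical days through `steps_per_day`).  A bin is
#' covered when the simulated band intersects the envelope interval; the
#' candidate is non-falsified only if every constrained bin is covered.
#' Intersection (not containment) is the criterion: a configuration is
#' rejected only when its replicate band and the data band cannot touch.
#' Set `strict = TRUE` to require the envelope to contain the simulated
#' band instead.
#'
#' @param mrm candidate `model_rule_matrix`.
#' @param envelope an `envelope` from [build_envelope()].
#' @param cohort cohort label to test against.
#' @param config a [sim_config()].
#' @param n_replicates stochastic replicates (>= 2).
#' @param base_seed seed of the replicate stream.
#' @param injury_sizes optional insult sweep: injury sizes cycled across the
#'   replicates so the simulated band spans the insult heterogeneity of the
#'   reference subjects (varied individuals responding to varied insults).
#' @param noise_sdlog known multiplicative (lognormal) measurement-noise
#'   scale of the observations; the simulated band is widened by the
#'   central 95% noise factor `exp(2 * noise_sdlog)` so the forward model
#'   includes the observation model.  0 disables the allowance.
#' @param strict require band containment instead of intersection.
#' @return a `falsification_report`: `verdict`, `coverage_fraction`,
#'   per-bin flags and the violation list.
#' @export
falsify <- function(mrm, envelope, cohort, config,
                    n_replicates = 3, base_seed = 1L, injury_sizes = NULL,
                    noise_sdlog = 0, strict = FALSE) {
  if (n_replicates < 2) stop_param("falsification needs >= 2 replicates")
  bands <- envelope$bands[envelope$bands$cohort == cohort, ]
  bands <- bands[bands$entity %in% mrm$entities$observed, ]
  if (nrow(bands) == 0) {
    stop_param("no constrained bins for cohort '", cohort,
               "': refusing vacuous falsification")
  }
  ts <- run_replicates(config, mrm, n = n_replicates, base_seed = base_seed,
                       injury_sizes = injury_sizes)
  day <- config$steps_per_day
  bin_of <- time_bin(ts$times / day, envelope$bin_width)

  # bins where every replicate has died yield empty min/max (Inf/-Inf),
  # handled below as unreachable
  sim_lo <- suppressWarnings(
    apply(ts$env_lo, 2, function(col) tapply(col, bin_of, min, na.rm = TRUE)))
  sim_hi <- suppressWarnings(
    apply(ts$env_hi, 2, function(col) tapply(col, bin_of, max, na.rm = TRUE)))
  sim_bins <- as.numeric(rownames(sim_lo))

  bi <- match(bands$bin_start, sim_bins)
  ei <- match(bands$entity, colnames(ts$env_lo))
  slo <- sim_lo[cbind(bi, ei)] * exp(-2 * noise_sdlog)
  shi <- sim_hi[cbind(bi, ei)] * exp(2 * noise_sdlog)
  # bins beyond the simulated horizon, or after all replicates died, are
  # unmatchable and count as violations
  reachable <- !is.na(slo) & is.finite(slo)
  covered <- reachable &
    (if (strict) slo >= bands$lo & shi <= bands$hi
     else slo <= bands$hi & shi >= bands$lo)
  report <- data.frame(bands, sim_lo = slo, sim_hi = shi, covered = covered)
  structure(list(
    verdict = if (all(covered)) "non-falsified" else "falsified",
    coverage_fraction = mean(covered),
    bins = report,
    violations = report[!report$covered, , drop = FALSE],
    cohort = cohort, n_replicates = n_replicates, base_seed = base_seed,
    strict = strict),
    class = "falsification_report")
}

#' @export
print.falsification_report <- function(x, ...) {
  cat("Falsification vs cohort", x$cohort, ":", x$verdict,
      sprintf("(coverage %.3f, %d/%d bins)\n", x$coverage_fraction,
              sum(x$bins$covered), nrow(x$bins)))
  invisible(x)
}

#' GA configuration
#'
#' @param pop_size population size (>= 2).
#' @param generations maximum generations.
#' @param elite number of elite survivors (< pop_size).
#' @param mutation_rate,mutation_scale per-element mutation probability and
#'   uniform noise half-width (see [mrm_mutate()]).
#' @param crossover_prob probability an offspring is produced by uniform
#'   crossover before mutation.
#' @param n_replicates stochastic replicates per fitness evaluation.
#' @param early_stop stop after this many consecutive generations at
#'   fitness 1 (0 disables early stopping).
#' @export
ga_config <- function(pop_size = 24, generations = 4, elite = 2,
                      mutation_rate = 0.03, mutation_scale = 0.4,
                      crossover_prob = 0.7, n_replicates = 5,
                      early_stop = 0) {
  if (pop_size < 2) stop_param("population must be >= 2")
  if (elite >= pop_size) stop_param("elite must be < population size")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 elite = as.integer(elite),
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 crossover_prob = crossover_prob,
                 n_replicates = as.integer(n_replicates),
                 early_stop = as.integer(early_stop)),
            class = "ga_config")
}

# evaluate one candidate against each cohort; counter-based seed makes the
# (stochastic) fitness of a candidate reproducible given the master seed
.evaluate_candidate <- function(mrm, envelope, cohorts, config, n_replicates,
                                eval_seed, injury_sizes = NULL,
                                noise_sdlog = 0) {
  reports <- lapply(cohorts, function(co)
    falsify(mrm, envelope, co, config, n_replicates, base_seed = eval_seed,
            injury_sizes = injury_sizes, noise_sdlog = noise_sdlog))
  names(reports) <- cohorts
  cov <- vapply(reports, function(r) r$coverage_fraction, numeric(1))
  viol <- vapply(reports, function(r) nrow(r$violations), numeric(1))
  list(fitness = mean(cov), violations = sum(viol),
       non_falsified = all(vapply(reports, function(r)
         r$verdict == "non-falsified", logical(1))),
       reports = reports)
}

#' Genetic-algorithm search for non-falsifiable enriched MRMs
#'
#' Evolves a population seeded with the base matrix and mutants of it.
#' Fitness is the mean envelope coverage fraction across the supplied
#' cohorts; ties break toward fewer envelope violations and then toward a
#' smaller L1 deviation from the base matrix.  Selection is binary
#' tournament with elitism, so the best fitness is monotone non-decreasing
#' across generations.  Mutation can turn latent (zero) elements nonzero,
#' which is how the sparse base matrix becomes enriched.
#'
#' @param base the base `model_rule_matrix`.
#' @param envelope calibration `envelope`.
#' @param cohorts cohort labels fitness is averaged over (typically one).
#' @param ga a [ga_config()].
#' @param config a [sim_config()].
#' @param seed master seed; candidate-evaluation seeds derive from it.
#' @param injury_sizes insult sweep passed to [falsify()].
#' @param noise_sdlog measurement-noise allowance passed to [falsify()].
#' @param verbose print per-generation progress.
#' @return a `ga_result`: `candidates` (all evaluated MRMs), `records`
#'   (fitness table), `best_by_generation`, and the final population.
#' @export
ga_search <- function(base, envelope, cohorts, ga = ga_config(),
                      config = default_toy_sim_config(), seed = 1L,
                      injury_sizes = NULL, noise_sdlog = 0,
                      verbose = FALSE) {
  set.seed(seed)
  eval_seeds <- derive_seeds(seed, ga$pop_size * (ga$generations + 1L),
                             stream = 23L)
  confirm_seeds <- derive_seeds(seed, ga$pop_size * (ga$generations + 1L),
                                stream = 29L)
  confirm_seeds2 <- derive_seeds(seed, ga$pop_size * (ga$generations + 1L),
                                 stream = 31L)
  n_eval <- 0L
  candidates <- list(); records <- list()

  evaluate <- function(mrm, gen) {
    n_eval <<- n_eval + 1L
    ev <- .evaluate_candidate(mrm, envelope, cohorts, config,
                              ga$n_replicates, eval_seeds[n_eval],
                              injury_sizes, noise_sdlog)
    if (ev$non_falsified) {
      # a non-falsified flag requires three independent evaluations to
      # agree, so downstream ensembles never rest on a marginal verdict
      for (cs in c(confirm_seeds[n_eval], confirm_seeds2[n_eval])) {
        if (!ev$non_falsified) break
        ev2 <- .evaluate_candidate(mrm, envelope, cohorts, config,
                                   ga$n_replicates, cs,
                                   injury_sizes, noise_sdlog)
        ev$non_falsified <- ev2$non_falsified
      }
    }
    dev <- sum(abs(mrm$values - base$values))
    candidates[[n_eval]] <<- mrm
    records[[n_eval]] <<- data.frame(
      id = n_eval, generation = gen, fitness = ev$fitness,
      violations = ev$violations, deviation = dev,
      non_falsified = ev$non_falsified,
      nonzero = mrm_nonzero_count(mrm),
      eval_seed = eval_seeds[n_eval])
    ev$fitness
  }

  # initial population: the base matrix plus mutants of it
  pop <- c(list(base),
           lapply(seq_len(ga$pop_size - 1L), function(i)
             mrm_mutate(base, ga$mutation_rate, ga$mutation_scale)))
  fit <- vapply(pop, evaluate, numeric(1), gen = 0L)
  ids <- seq_len(ga$pop_size)

  rank_of <- function(idx) {
    rec <- do.call(rbind, records[idx])
    order(-rec$fitness, rec$violations, rec$deviation)
  }
  best_hist <- max(fit)
  at_top <- 0L
  for (gen in seq_len(ga$generations)) {
    ord <- rank_of(ids)
    elite_idx <- ids[ord[seq_len(ga$elite)]]
    new_pop <- candidates[elite_idx]
    new_ids <- elite_idx
    while (length(new_pop) < ga$pop_size) {
      pick <- function() {
        two <- sample(seq_along(ids), 2)
        ids[two[which.max(fit[two])]]
      }
      child <- if (stats::runif(1) < ga$crossover_prob) {
        mrm_crossover(candidates[[pick()]], candidates[[pick()]])
      } else candidates[[pick()]]
      child <- mrm_mutate(child, ga$mutation_rate, ga$mutation_scale)
      f <- evaluate(child, gen)
      new_pop <- c(new_pop, list(child))
      new_ids <- c(new_ids, n_eval)
    }
    ids <- new_ids
    fit <- vapply(records[ids], function(r) r$fitness, numeric(1))
    best_hist <- c(best_hist, max(fit))
    if (verbose) {
      message(sprintf("gen %2d: best %.3f mean %.3f", gen, max(fit),
                      mean(fit)))
    }
    if (ga$early_stop > 0 && max(fit) >= 1) {
      at_top <- at_top + 1L
      if (at_top >= ga$early_stop) break
    }
  }
  recs <- do.call(rbind, records)
  structure(list(candidates = candidates, records = recs,
                 best_by_generation = best_hist,
                 population_ids = ids, base = base,
                 cohorts = cohorts, seed = seed,
                 injury_sizes = injury_sizes, noise_sdlog = noise_sdlog),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("GA search:", nrow(x$records), "evaluations over",
      max(x$records$generation), "generations; best fitness",
      round(max(x$records$fitness), 3), ";",
      sum(x$records$non_falsified), "non-falsified candidates\n")
  invisible(x)
}

#' Active-learning configuration
#'
#' The refinement has two phases.  Phase one is classic pool-based active
#' learning: a probabilistic surrogate trained on the falsification labels
#' scores a pool of diffuse proposals (bounded perturbations of valid
#' members) and each round the candidates with the highest expected
#' range-gain-times-validity are simulated, with an exploration fraction
#' drawn at random.  Phase two is a systematic boundary sweep: every matrix
#' element is probed toward each bound from a low-deviation (near-base)
#' carrier, and elements whose probes are rejected are retried in later
#' chain passes from members accepted earlier in the sweep -- correlated
#' boundary corners are reachable only through such chained joint moves.
#'
#' @param batch_size candidates simulated per phase-one round.
#' @param rounds phase-one rounds (>= 1).
#' @param pool_factor pool proposals per simulated candidate in phase one.
#' @param perturb_rate,perturb_scale per-element probability and uniform
#'   half-width of the diffuse proposal perturbations.
#' @param axis_frac fraction of diffuse proposals that are single-element
#'   pushes to a uniform value over the bounds.
#' @param explore_frac fraction of each phase-one batch drawn uniformly from
#'   the pool instead of by surrogate score, guarding against a miscalibrated
#'   surrogate starving regions of evaluations.
#' @param sweep enable the phase-two boundary sweep.
#' @param chain_passes additional sweep passes retrying blocked elements
#'   from members accepted in the previous pass.
#' @param chain_tries carrier attempts per blocked element in each chain
#'   pass (a blocked element stays blocked only if every try fails).
#' @param sweep_replicates replicates of the cheap screening test used for
#'   sweep probes.
#' @param confirmations independent fresh-seed confirmations (each at
#'   `n_replicates`) a screened candidate must pass before joining the
#'   ensemble; verdicts then rest on several agreeing evaluations.
#' @param epsilon phase one stops early when the ensemble range matrix
#'   changes elementwise by less than this between rounds (`Inf` stops
#'   after one round).
#' @param n_replicates replicates per confirmed falsification test.
#' @export
al_config <- function(batch_size = 8, rounds = 4, pool_factor = 10,
                      perturb_rate = 0.05, perturb_scale = 0.4,
                      axis_frac = 0.5, explore_frac = 0.25, sweep = TRUE,
                      chain_passes = 2, chain_tries = 2,
                      sweep_replicates = 2, confirmations = 2,
                      epsilon = 0.005, n_replicates = 3) {
  if (rounds < 1) stop_param("rounds must be >= 1")
  if (batch_size < 1) stop_param("batch size must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 rounds = as.integer(rounds),
                 pool_factor = as.integer(pool_factor),
                 perturb_rate = perturb_rate, perturb_scale = perturb_scale,
                 axis_frac = axis_frac, explore_frac = explore_frac,
                 sweep = isTRUE(sweep),
                 chain_passes = as.integer(chain_passes),
                 chain_tries = as.integer(chain_tries),
                 sweep_replicates = as.integer(sweep_replicates),
                 confirmations = as.integer(confirmations),
                 epsilon = epsilon, n_replicates = as.integer(n_replicates)),
            class = "al_config")
}

#' Active-learning refinement of the valid-ensemble boundary
#'
#' Maps the boundary of the non-falsifiable region around the GA's labeled
#' seed candidates: surrogate-guided uncertainty/gain sampling first (see
#' [al_config()]), then a systematic per-element boundary sweep with chain
#' passes.  Returns every non-falsified member observed, so the final range
#' matrix contains the GA-only range matrix elementwise.
#'
#' @param ga_result a [ga_search()] result supplying labeled seed
#'   candidates (must contain both verdicts).
#' @param envelope calibration `envelope`.
#' @param al an [al_config()].
#' @param config a [sim_config()].
#' @param seed master seed for proposals and evaluation streams.
#' @param cohort cohort label; defaults to the GA's cohorts.
#' @param injury_sizes insult sweep passed to [falsify()]; defaults to the
#'   GA's sweep.
#' @param noise_sdlog measurement-noise allowance; defaults to the GA's.
#' @return a `valid_ensemble`: non-falsified `members`, provenance `info`,
#'   and `range_matrix`.
#' @export
al_refine <- function(ga_result, envelope, al = al_config(),
                      config = default_toy_sim_config(), seed = 1L,
                      cohort = NULL, injury_sizes = NULL,
                      noise_sdlog = NULL) {
  cohorts <- cohort %||% ga_result$cohorts
  injury_sizes <- injury_sizes %||% ga_result$injury_sizes
  noise_sdlog <- noise_sdlog %||% ga_result$noise_sdlog %||% 0
  recs <- ga_result$records
  labels <- recs$non_falsified
  if (all(labels) || !any(labels)) {
    stop_param("active learning needs both falsified and non-falsified seed ",
               "candidates; widen the GA search")
  }
  set.seed(seed)
  base <- ga_result$base
  n_el <- length(base$values)
  bounds <- base$bounds
  eval_seeds <- derive_seeds(seed,
                             (2L + al$confirmations) *
                               (al$rounds * al$batch_size +
                                  2L * n_el * (1L + al$chain_passes) *
                                    max(1L, al$chain_tries)),
                             stream = 37L)
  n_eval <- 0L
  X <- t(vapply(ga_result$candidates, function(m) as.vector(m$values),
                numeric(n_el)))
  y <- factor(labels, levels = c(FALSE, TRUE))

  test_candidate <- function(m, n_rep) {
    n_eval <<- n_eval + 1L
    ev <- .evaluate_candidate(m, envelope, cohorts, config, n_rep,
                              eval_seeds[n_eval], injury_sizes, noise_sdlog)
    X <<- rbind(X, as.vector(m$values))
    y <<- factor(c(as.logical(as.character(y)), ev$non_falsified),
                 levels = c(FALSE, TRUE))
    list(ok = ev$non_falsified, fitness = ev$fitness,
         seed = eval_seeds[n_eval])
  }
  confirm <- function(m) {
    for (k in seq_len(al$confirmations)) {
      res <- test_candidate(m, al$n_replicates)
      if (!res$ok) return(NULL)
    }
    res
  }
  accept <- function(m, round, origin, res) {
    valid[[length(valid) + 1L]] <<- m
    info <<- rbind(info, data.frame(origin = origin, round = round,
                                    fitness = res$fitness,
                                    eval_seed = res$seed))
  }

  ranges_of <- function() {
    vmat <- vapply(valid, function(m) as.vector(m$values), numeric(n_el))
    list(vmat = vmat,
         emin = apply(vmat, 1, min), emax = apply(vmat, 1, max))
  }

  valid <- ga_result$candidates[labels]
  info <- data.frame(origin = "ga", round = 0L,
                     fitness = recs$fitness[labels],
                     eval_seed = recs$eval_seed[labels])

  # ---- phase one: surrogate-guided uncertainty/gain sampling -------------
  prev_rng <- unclass(element_ranges(valid))
  for (round in seq_len(al$rounds)) {
    nmin <- min(table(y))
    # balanced class sampling: falsified candidates usually far outnumber
    # valid ones and an unbalanced forest would vote everything invalid
    surrogate <- randomForest::randomForest(X, y, ntree = 200,
                                            sampsize = c(nmin, nmin))
    rg <- ranges_of()
    pool <- lapply(seq_len(al$batch_size * al$pool_factor), function(i) {
      m <- valid[[sample.int(length(valid), 1)]]
      if (stats::runif(1) < al$axis_frac) {
        j <- sample.int(n_el, 1)
        m$values[j] <- stats::runif(1, bounds[1], bounds[2])
        m
      } else {
        mrm_mutate(m, al$perturb_rate, al$perturb_scale)
      }
    })
    Xp <- t(vapply(pool, function(m) as.vector(m$values), numeric(n_el)))
    p <- stats::predict(surrogate, Xp, type = "prob")[, "TRUE"]
    gain <- vapply(pool, function(m) {
      v <- as.vector(m$values)
      sum(pmax(0, rg$emin - v) + pmax(0, v - rg$emax))
    }, numeric(1))
    score <- (0.05 + p) * gain
    n_unc <- ceiling(al$batch_size * (1 - al$explore_frac))
    ord <- order(-score, stats::runif(length(p)))
    take <- ord[seq_len(min(n_unc, length(ord)))]
    rest <- setdiff(seq_along(pool), take)
    take <- c(take, sample(rest, min(al$batch_size - length(take),
                                     length(rest))))
    for (i in take) {
      res <- test_candidate(pool[[i]], al$n_replicates)
      if (res$ok) {
        res2 <- confirm(pool[[i]])
        if (!is.null(res2)) accept(pool[[i]], round, "al", res2)
      }
    }
    rng <- unclass(element_ranges(valid))
    if (max(abs(rng - prev_rng)) < al$epsilon) break
    prev_rng <- rng
  }

  # ---- phase two: systematic per-element boundary sweep ------------------
  if (al$sweep) {
    # probe every (element, side) from a near-base carrier; carriers with a
    # minimal footprint keep the rest-vector clean so a rejection reflects
    # the probed element, and accepted probes become carriers for retrying
    # blocked elements (chained joint moves reach correlated corners)
    todo <- rbind(cbind(seq_len(n_el), 1L), cbind(seq_len(n_el), 0L))
    todo <- todo[sample.int(nrow(todo)), , drop = FALSE]
    carriers_new <- list(base)
    for (pass in seq_len(1L + al$chain_passes)) {
      if (nrow(todo) == 0 || length(carriers_new) == 0) break
      carriers <- carriers_new
      carriers_new <- list()
      rg <- ranges_of()
      tries <- if (pass == 1L) 1L else al$chain_tries
      blocked <- matrix(0L, 0, 2)
      for (r in seq_len(nrow(todo))) {
        j <- todo[r, 1]; lo_side <- todo[r, 2] == 1L
        room <- if (lo_side) rg$emin[j] - bounds[1] else
          bounds[2] - rg$emax[j]
        if (room <= 0.05) next
        done <- FALSE
        for (try in seq_len(tries)) {
          m <- carriers[[sample.int(length(carriers), 1)]]
          u <- stats::runif(1, 0.4, 1)
          m$values[j] <- if (lo_side) rg$emin[j] - u * room else
            rg$emax[j] + u * room
          res <- test_candidate(m, al$sweep_replicates)
          if (res$ok) {
            # confirm the screening verdict at full replicates, fresh seeds
            res2 <- confirm(m)
            if (!is.null(res2)) {
              accept(m, pass, "sweep", res2)
              carriers_new[[length(carriers_new) + 1L]] <- m
              done <- TRUE
              break
            }
          }
        }
        if (!done) blocked <- rbind(blocked, todo[r, , drop = FALSE])
      }
      todo <- blocked
    }
  }
  valid_ensemble(valid, info, cohorts = cohorts,
                 settings = list(al = unclass(al),
                                 n_replicates = al$n_replicates,
                                 injury_sizes = injury_sizes,
                                 noise_sdlog = noise_sdlog))
}

#' Construct a valid ensemble
#'
#' @param members nonempty list of non-falsified `model_rule_matrix`.
#' @param info provenance data.frame (one row per member).
#' @param cohorts cohort label(s) the members were tested against.
#' @param settings evaluation settings the verdicts were stored under.
#' @export
valid_ensemble <- function(members, info = NULL, cohorts = NULL,
                           settings = NULL) {
  if (length(members) == 0) stop_param("valid ensemble must be nonempty")
  structure(list(members = members,
                 info = info %||%
                   data.frame(origin = rep(NA_character_, length(members))),
                 cohorts = cohorts,
                 settings = settings,
                 range_matrix = element_ranges(members)),
            class = "valid_ensemble")
}

#' @export
print.valid_ensemble <- function(x, ...) {
  cat("Valid ensemble:", length(x$members), "non-falsified MRMs (cohort",
      paste(x$cohorts, collapse = "+"), "); max element range",
      round(max(x$range_matrix), 3), "\n")
  invisible(x)
}

#' Combine per-cohort valid ensembles
#'
#' Members keep their cohort tags; the combined range matrix is computed
#' over the union and therefore contains each part's range matrix
#' elementwise.
#'
#' @param ... `valid_ensemble` objects, one per cohort.
#' @export
combine_ensembles <- function(...) {
  parts <- list(...)
  members <- do.call(c, lapply(parts, function(p) p$members))
  info <- do.call(rbind, lapply(parts, function(p) {
    cbind(p$info, cohort = paste(p$cohorts, collapse = "+"))
  }))
  valid_ensemble(members, info,
                 cohorts = unlist(lapply(parts, function(p) p$cohorts)),
                 settings = parts[[1]]$settings)
}

#' Parameter-recovery diagnostics
#'
#' For each hidden ground-truth MRM: the fraction of matrix elements whose
#' hidden value lies inside the ensemble's per-element [min, max] interval
#' (overall and restricted to the declared-perturbed elements), and
#' optionally whether the hidden matrix itself is non-falsified against the
#' calibration envelope.
#'
#' @param hidden list of hidden `model_rule_matrix` (per cohort as returned
#'   by [generate_synthetic_reference()], or a flat list).
#' @param ensemble a `valid_ensemble`.
#' @param perturbation the declared (`rule`, `entity`) perturbed subset, or
#'   NULL to skip that summary.
#' @param envelope,config,cohort,n_replicates,base_seed,injury_sizes,noise_sdlog
#'   when envelope, config and cohort are supplied, each hidden MRM is also
#'   re-tested with [falsify()].
#' @param tol slack added to the ensemble interval when testing containment
#'   (elements equal to an interval endpoint count as contained).
#' @return data.frame, one row per hidden MRM.
#' @export
recover_parameters_check <- function(hidden, ensemble, perturbation = NULL,
                                     envelope = NULL, config = NULL,
                                     cohort = NULL, n_replicates = 3,
                                     base_seed = 1L, injury_sizes = NULL,
                                     noise_sdlog = 0, tol = 1e-9) {
  if (!is.null(names(hidden)) &&
      all(vapply(hidden, is.list, logical(1))) &&
      !inherits(hidden[[1]], "model_rule_matrix")) {
    flat <- unlist(hidden, recursive = FALSE)
  } else flat <- hidden
  vals <- lapply(ensemble$members, function(m) m$values)
  arr <- array(unlist(vals), dim = c(dim(vals[[1]]), length(vals)))
  emin <- apply(arr, c(1, 2), min); emax <- apply(arr, c(1, 2), max)
  pert_idx <- NULL
  if (!is.null(perturbation) && nrow(perturbation)) {
    m1 <- flat[[1]]
    pert_idx <- cbind(match(perturbation$rule, m1$rules$rules$id),
                      match(perturbation$entity, m1$entities$names))
  }
  out <- lapply(seq_along(flat), function(i) {
    h <- flat[[i]]$values
    inside <- h >= emin - tol & h <= emax + tol
    row <- data.frame(hidden = names(flat)[i] %||% i,
                      containment = mean(inside),
                      containment_perturbed =
                        if (is.null(pert_idx)) NA_real_
                        else mean(inside[pert_idx]))
    if (!is.null(envelope) && !is.null(config) && !is.null(cohort)) {
      rep <- falsify(flat[[i]], envelope, cohort, config, n_replicates,
                     base_seed, injury_sizes = injury_sizes,
                     noise_sdlog = noise_sdlog)
      row$hidden_verdict <- rep$verdict
      row$hidden_coverage <- rep$coverage_fraction
    }
    row
  })
  do.call(rbind, out)
}
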