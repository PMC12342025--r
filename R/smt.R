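#' Generate a labeled synthetic mediator trajectory (SMT) dataset
#'
#' Runs every member of the valid ensemble with `per_member_replicates`
#' seeded stochastic replicates.  Each trajectory carries its source
#' member's cohort tag, the simulated outcome, and full provenance
#' (mrm_id, seed), and is dense at the simulation sampling cadence --
#' typically an order of magnitude denser than the sparse clinical-style
#' reference it was calibrated against.
#'
#' @param ensemble a `valid_ensemble` whose `info` carries a `cohort`
#'   column (see [combine_ensembles()]), or a single-cohort ensemble.
#' @param per_member_replicates stochastic replicates per member.
#' @param config a [sim_config()].
#' @param seed master seed; per-member replicate streams derive from it.
#' @param injury_sizes optional insult sweep cycled across replicates.
#' @return an `smt_dataset`: `trajectories` (long data.frame), `runs`
#'   (per-run provenance and outcome), `envelopes` (per cohort), `times`
#'   (clinical days), `config`, `config_hash`, `seed`.
#' @export
generate_smt <- function(ensemble, per_member_replicates = 5,
                         config = default_toy_sim_config(), seed = 1L,
                         injury_sizes = NULL) {
  if (!inherits(ensemble, "valid_ensemble") || length(ensemble$members) == 0) {
    stop_param("generate_smt needs a nonempty valid ensemble")
  }
  members <- ensemble$members
  cohorts <- ensemble$info$cohort %||%
    rep(paste(ensemble$cohorts, collapse = "+"), length(members))
  member_seeds <- derive_seeds(seed, length(members), stream = 53L)
  day <- config$steps_per_day

  traj <- vector("list", length(members) * per_member_replicates)
  runs <- vector("list", length(traj))
  spaces <- list()
  k <- 0L
  for (mi in seq_along(members)) {
    ts <- run_replicates(config, members[[mi]], n = per_member_replicates,
                         base_seed = member_seeds[mi],
                         injury_sizes = injury_sizes)
    mrm_id <- ts$replicates[[1]]$mrm_id
    co <- as.character(cohorts[mi])
    spaces[[co]] <- c(spaces[[co]], ts$replicates)
    for (ri in seq_along(ts$replicates)) {
      tr <- ts$replicates[[ri]]
      k <- k + 1L
      run_id <- sprintf("run%05d", k)
      ok <- !is.na(tr$health)
      ent <- colnames(tr$values)
      traj[[k]] <- data.frame(
        run_id = run_id, mrm_id = mrm_id, cohort = co, seed = tr$seed,
        time = rep(tr$times[ok] / day, times = length(ent)),
        entity = rep(ent, each = sum(ok)),
        value = as.vector(tr$values[ok, ]),
        stringsAsFactors = FALSE)
      runs[[k]] <- data.frame(run_id = run_id, mrm_id = mrm_id, cohort = co,
                              member = mi, seed = tr$seed,
                              outcome = tr$outcome,
                              terminal_health = terminal_health(tr),
                              stringsAsFactors = FALSE)
    }
  }
  envelopes <- lapply(spaces, trajectory_envelope)
  structure(list(trajectories = do.call(rbind, traj),
                 runs = do.call(rbind, runs),
                 envelopes = envelopes,
                 times = envelopes[[1]]$times / day,
                 config = config,
                 config_hash = config_hash(list(config = unclass(config),
                                                seed = seed,
                                                reps = per_member_replicates)),
                 seed = seed),
            class = "smt_dataset")
}

#' @export
print.smt_dataset <- function(x, ...) {
  cat("SMT dataset:", nrow(x$runs), "trajectories (",
      length(unique(x$runs$mrm_id)), "MRMs ) x", length(x$times),
      "sampled times; cohorts:",
      paste(names(x$envelopes), collapse = ", "), "\n")
  print(table(x$runs$cohort, x$runs$outcome))
  invisible(x)
}

#' Select cohort-typed members for trajectory-space generation
#'
#' Both cohorts' valid ensembles contain near-base members compatible with
#' either dataset, so raw per-cohort envelopes would overlap everywhere.
#' Cohort typing is one-sided: a member is case-typed (cohort 2) only when
#' it is non-falsified by the case envelope AND falsified by the control
#' envelope -- its dynamics are rejected by the control data.  Control-typed
#' members are drawn from the control ensemble.  Case candidates are
#' re-tested in decreasing order of deviation from the base matrix (the
#' most enriched members are the most likely to be distinctive) until `k`
#' are confirmed.
#'
#' @param ens_control,ens_case per-cohort `valid_ensemble`s.
#' @param envelope the calibration `envelope` (both cohorts).
#' @param config a [sim_config()].
#' @param k members per cohort.
#' @param seed seed for subsampling and re-tests.
#' @param injury_sizes,noise_sdlog,n_replicates falsification settings.
#' @param cohorts the (control, case) labels.
#' @return a combined tagged `valid_ensemble`.
#' @export
select_cohort_members <- function(ens_control, ens_case, envelope, config,
                                  k = 12, seed = 1L, injury_sizes = NULL,
                                  noise_sdlog = 0, n_replicates = 3,
                                  cohorts = c("A", "B")) {
  set.seed(seed)
  seeds <- derive_seeds(seed, length(ens_case$members) + 1L, stream = 61L)
  # control side: random subsample of its valid ensemble
  na <- min(k, length(ens_control$members))
  ia <- sort(sample.int(length(ens_control$members), na))
  ctrl <- valid_ensemble(ens_control$members[ia],
                         data.frame(origin = "control", round = 0L,
                                    fitness = NA_real_,
                                    eval_seed = NA_integer_)[rep(1, na), ],
                         cohorts = cohorts[1])
  # case side: most-deviant members confirmed distinctive
  base <- build_base_mrm(ens_case$members[[1]]$entities,
                         ens_case$members[[1]]$rules)
  dev <- vapply(ens_case$members, function(m)
    sum(abs(m$values - base$values)), numeric(1))
  picked <- list()
  for (i in order(-dev)) {
    if (length(picked) >= k) break
    m <- ens_case$members[[i]]
    fc <- falsify(m, envelope, cohorts[1], config, n_replicates,
                  base_seed = seeds[i], injury_sizes = injury_sizes,
                  noise_sdlog = noise_sdlog)
    if (fc$verdict != "falsified") next
    fk <- falsify(m, envelope, cohorts[2], config, n_replicates,
                  base_seed = seeds[i] + 1L, injury_sizes = injury_sizes,
                  noise_sdlog = noise_sdlog)
    if (fk$verdict == "non-falsified") picked <- c(picked, list(m))
  }
  if (length(picked) == 0) {
    stop_param("no case-distinctive members found; enlarge the case ",
               "ensemble or its boundary sweep")
  }
  case <- valid_ensemble(picked,
                         data.frame(origin = "case", round = 0L,
                                    fitness = NA_real_,
                                    eval_seed = NA_integer_)[
                                      rep(1, length(picked)), ],
                         cohorts = cohorts[2])
  combine_ensembles(ctrl, case)
}

#' Cohort-separation profile of an SMT dataset
#'
#' For each entity and sampled time, the two cohort envelopes either overlap
#' or are disjoint; contiguous disjoint times merge into intervals.  These
#' separation windows are where the dense synthetic trajectory spaces
#' distinguish the cohorts even though the sparse reference samples may
#' never fall inside them.
#'
#' @param dataset an `smt_dataset` containing exactly two cohorts.
#' @return a `separation_profile`: per-entity disjoint time intervals and
#'   overlap fractions.
#' @export
compute_separation <- function(dataset) {
  if (length(dataset$envelopes) != 2) {
    stop_param("separation needs exactly two cohorts, got ",
               length(dataset$envelopes))
  }
  ea <- dataset$envelopes[[1]]; eb <- dataset$envelopes[[2]]
  ents <- colnames(ea$env_lo)
  times <- dataset$times
  profile <- lapply(ents, function(e) {
    disjoint <- ea$env_lo[, e] > eb$env_hi[, e] |
      eb$env_lo[, e] > ea$env_hi[, e]
    disjoint[is.na(disjoint)] <- FALSE
    r <- rle(disjoint)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    iv <- data.frame(start = times[starts[r$values]],
                     end = times[ends[r$values]])
    list(entity = e, intervals = iv,
         overlap_fraction = 1 - mean(disjoint))
  })
  names(profile) <- ents
  structure(list(entities = profile,
                 cohorts = names(dataset$envelopes),
                 overlap_fraction = vapply(profile, function(p)
                   p$overlap_fraction, numeric(1)),
                 n_disjoint = vapply(profile, function(p)
                   nrow(p$intervals), numeric(1))),
            class = "separation_profile")
}

#' @export
print.separation_profile <- function(x, ...) {
  cat("Separation profile (", paste(x$cohorts, collapse = " vs "), "):\n")
  for (e in names(x$entities)) {
    p <- x$entities[[e]]
    if (nrow(p$intervals)) {
      cat(sprintf("  %-8s overlap %.2f; disjoint: %s\n", e,
                  p$overlap_fraction,
                  paste(sprintf("[%.2f, %.2f]", p$intervals$start,
                                p$intervals$end), collapse = " ")))
    }
  }
  cat(" ", sum(x$n_disjoint), "disjoint windows across",
      sum(x$n_disjoint > 0), "entities\n")
  invisible(x)
}

#' Range-expansion summary: SMT envelope vs observed reference extremes
#'
#' Reports, per entity, how far the synthetic trajectory envelope extends
#' beyond the observed reference minimum and maximum.  A sound synthetic
#' data generator must be able to exceed observed extremes: the observed
#' outliers are samples from a wider attainable range, not its boundary.
#'
#' @param dataset an `smt_dataset`.
#' @param reference a `reference_dataset` sharing entities.
#' @return data.frame per shared entity: reference and SMT ranges and the
#'   (non-negative) extension magnitudes below and above.
#' @export
expansion_check <- function(dataset, reference) {
  o <- reference$observations
  tr <- dataset$trajectories
  ents <- intersect(unique(o$entity), unique(tr$entity))
  out <- lapply(ents, function(e) {
    rv <- o$value[o$entity == e]
    sv <- tr$value[tr$entity == e]
    data.frame(entity = e,
               ref_min = min(rv), ref_max = max(rv),
               smt_min = min(sv), smt_max = max(sv),
               ext_low = max(0, min(rv) - min(sv)),
               ext_high = max(0, max(sv) - max(rv)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$expands <- res$ext_low > 0 | res$ext_high > 0
  res
}

#' Export an SMT dataset
#'
#' `csv-long` writes one row per (run, time, entity); `csv-wide` one row per
#' (run, time) with one column per entity plus label columns.  A manifest
#' JSON with the config hash, seed and run provenance accompanies either
#' format, making the export reproducible and reloadable.
#'
#' @param dataset an `smt_dataset`.
#' @param path output directory (created if needed).
#' @param format `"csv-long"` or `"csv-wide"`.
#' @return invisibly, the paths written.
#' @export
export_smt <- function(dataset, path, format = c("csv-long", "csv-wide")) {
  format <- match.arg(format)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_validation("cannot create output directory: ", path)
  }
  files <- character(0)
  if (format == "csv-long") {
    f <- file.path(path, "smt_long.csv")
    utils::write.csv(dataset$trajectories, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  } else {
    tr <- dataset$trajectories
    wide <- stats::reshape(tr, idvar = c("run_id", "time"),
                           timevar = "entity", v.names = "value",
                           direction = "wide",
                           new.row.names = NULL)
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- wide[order(wide$run_id, wide$time), ]
    f <- file.path(path, "smt_wide.csv")
    utils::write.csv(wide, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  fr <- file.path(path, "smt_runs.csv")
  utils::write.csv(dataset$runs, fr, row.names = FALSE, quote = FALSE)
  fm <- file.path(path, "smt_manifest.json")
  jsonlite::write_json(list(format = format,
                            config_hash = dataset$config_hash,
                            seed = dataset$seed,
                            n_runs = nrow(dataset$runs),
                            n_times = length(dataset$times),
                            config = unclass(dataset$config)),
                       fm, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fr, fm))
}

#' Reload an exported long-format SMT dataset
#'
#' Rebuilds the trajectories, runs table, per-cohort envelopes and times
#' grid from a `csv-long` export directory; the result compares equal to
#' the exported dataset on all of these components.
#'
#' @param path directory written by [export_smt()].
#' @export
load_smt <- function(path) {
  f <- file.path(path, "smt_long.csv")
  if (!file.exists(f)) stop_validation("no smt_long.csv under ", path)
  tr <- utils::read.csv(f, stringsAsFactors = FALSE)
  runs <- utils::read.csv(file.path(path, "smt_runs.csv"),
                          stringsAsFactors = FALSE)
  man <- jsonlite::fromJSON(file.path(path, "smt_manifest.json"))
  times <- sort(unique(tr$time))
  ents <- unique(tr$entity)
  envelopes <- lapply(split(tr, tr$cohort), function(d) {
    lo <- tapply(d$value, list(match(d$time, times), d$entity), min)
    hi <- tapply(d$value, list(match(d$time, times), d$entity), max)
    full_lo <- matrix(NA_real_, length(times), length(ents),
                      dimnames = list(NULL, ents))
    full_hi <- full_lo
    full_lo[as.integer(rownames(lo)), colnames(lo)] <- lo
    full_hi[as.integer(rownames(hi)), colnames(hi)] <- hi
    list(times = times, env_lo = full_lo, env_hi = full_hi)
  })
  structure(list(trajectories = tr, runs = runs, envelopes = envelopes,
                 times = times, config = man$config,
                 config_hash = man$config_hash, seed = man$seed),
            class = "smt_dataset")
}
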