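#' Simulation configuration
#'
#' Parameters of the 2-D agent-based model of the endothelial-blood
#' interface.  The grid is toroidal; endothelium tiles it (one endothelial
#' cell per lattice site) and mobile immune cells move over it.  Time is in
#' abstract steps; `steps_per_day` declares the linear mapping to clinical
#' days used when aligning simulations with reference observations.
#'
#' @param grid_width,grid_height lattice dimensions (cells).
#' @param census named list of initial mobile-cell counts
#'   (macrophage, neutrophil, TH0, TH1, TH2, precursor).
#' @param injury_size number of contiguous endothelial cells initially
#'   destroyed (damage 1).
#' @param duration simulation length in steps.
#' @param sampling_interval steps between recorded samples (>= 1).
#' @param steps_per_day simulation steps per clinical day.
#' @param replicate_count default number of stochastic replicates.
#' @param death_threshold,resolve_threshold outcome cutoffs on terminal
#'   system health (fraction of undamaged endothelium).
#' @param secrete_rate,downreg_rate per-step field increment/decrement scale.
#' @param damage_rate,heal_rate per-step endothelial damage/heal scale.
#' @param act_relax relaxation rate of activation toward its rule target.
#' @param act_decay passive per-step activation decay factor.
#' @param diff_prob,apop_prob maximal per-step differentiation/apoptosis
#'   probabilities (scaled by the rule response).
#' @param logistic_bias structural intercept of logistic-response rules; a
#'   negative bias keeps resting probabilities low at zero mediator drive.
#' @param diffusion per-entity 4-neighbor diffusion coefficient in [0, 0.25]
#'   (scalar recycled).
#' @param decay per-entity multiplicative decay per step (scalar recycled).
#' @param injury_bolus damage-signal (PAF) released per injured site at t=0.
#' @param chemo_threshold gradient needed before chemotaxis overrides the
#'   random walk.
#' @param lifespans named list of lifespans (steps) per mobile cell type.
#' @return a `sim_config` object (validated list).
#' @export
sim_config <- function(grid_width = 30, grid_height = 30,
                       census = list(macrophage = 40, neutrophil = 40,
                                     TH0 = 30, TH1 = 10, TH2 = 10,
                                     precursor = 30),
                       injury_size = 60,
                       duration = 200, sampling_interval = 1,
                       steps_per_day = 20,
                       replicate_count = 10,
                       death_threshold = 0.2, resolve_threshold = 0.8,
                       secrete_rate = 1.0, downreg_rate = 1.0,
                       damage_rate = 0.15, heal_rate = 0.03,
                       act_relax = 0.5, act_decay = 0.98,
                       diff_prob = 0.15, apop_prob = 0.1,
                       logistic_bias = -1,
                       diffusion = 0.15, decay = 0.05,
                       injury_bolus = 5,
                       chemo_threshold = 0.05,
                       lifespans = list(macrophage = 250, neutrophil = 50,
                                        TH0 = 150, TH1 = 150, TH2 = 150,
                                        precursor = Inf)) {
  cfg <- list(grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              census = census, injury_size = as.integer(injury_size),
              duration = as.integer(duration),
              sampling_interval = as.integer(sampling_interval),
              steps_per_day = steps_per_day,
              replicate_count = as.integer(replicate_count),
              death_threshold = death_threshold,
              resolve_threshold = resolve_threshold,
              secrete_rate = secrete_rate, downreg_rate = downreg_rate,
              damage_rate = damage_rate, heal_rate = heal_rate,
              act_relax = act_relax, act_decay = act_decay,
              diff_prob = diff_prob, apop_prob = apop_prob,
              logistic_bias = logistic_bias,
              diffusion = diffusion, decay = decay,
              injury_bolus = injury_bolus,
              chemo_threshold = chemo_threshold,
              lifespans = lifespans)
  n <- cfg$grid_width * cfg$grid_height
  if (cfg$grid_width < 2 || cfg$grid_height < 2) {
    stop_config("grid must be at least 2 x 2")
  }
  if (any(unlist(census) < 0)) stop_config("census counts must be >= 0")
  if (sum(unlist(census)) > n) {
    stop_config("mobile-cell census (", sum(unlist(census)),
                ") exceeds grid capacity (", n, ")")
  }
  if (cfg$injury_size < 0 || cfg$injury_size > n) {
    stop_config("injury_size must be in [0, grid area]")
  }
  if (cfg$sampling_interval < 1 || cfg$duration < cfg$sampling_interval) {
    stop_config("need duration >= sampling_interval >= 1")
  }
  if (any(diffusion < 0) || any(diffusion > 0.25)) {
    stop_config("diffusion coefficients must lie in [0, 0.25]")
  }
  if (any(decay < 0) || any(decay > 1)) stop_config("decay must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

.MOBILE_TYPES <- c("macrophage", "neutrophil", "TH0", "TH1", "TH2",
                   "precursor")

# toroidal neighbor index tables; n x 4 (von Neumann) and n x 8 (Moore)
.neighbor_tables <- function(nx, ny) {
  n <- nx * ny
  ix <- (seq_len(n) - 1L) %% nx       # 0-based column
  iy <- (seq_len(n) - 1L) %/% nx      # 0-based row
  at <- function(dx, dy) {
    ((iy + dy) %% ny) * nx + ((ix + dx) %% nx) + 1L
  }
  nb4 <- cbind(at(1L, 0L), at(-1L, 0L), at(0L, 1L), at(0L, -1L))
  nb8 <- cbind(nb4, at(1L, 1L), at(1L, -1L), at(-1L, 1L), at(-1L, -1L))
  list(nb4 = nb4, nb8 = nb8)
}

# contiguous random patch of k sites grown from a random seed site
.grow_patch <- function(k, nb4, n) {
  if (k == 0) return(integer(0))
  start <- sample.int(n, 1)
  patch <- start
  frontier <- start
  in_patch <- logical(n)
  in_patch[start] <- TRUE
  while (length(patch) < k) {
    cand <- unique(as.vector(nb4[frontier, , drop = FALSE]))
    cand <- cand[!in_patch[cand]]
    if (length(cand) == 0) break  # grid exhausted
    take <- sample(cand, min(length(cand), k - length(patch)))
    in_patch[take] <- TRUE
    patch <- c(patch, take)
    frontier <- take
  }
  patch
}

#' Initialize the simulation world
#'
#' Endothelium tiles the grid; mobile cells are placed uniformly at random;
#' a random contiguous patch of `injury_size` endothelial cells is destroyed
#' and releases an initial damage-signal (PAF) bolus.  All randomness comes
#' from R's RNG: call [set.seed()] (or pass `seed`) for reproducibility.
#'
#' @param config a [sim_config()].
#' @param entities an [entity_catalog()].
#' @param seed optional integer; if given, seeds the RNG first.
#' @return a `world_state` list.
#' @export
abm_initialize <- function(config, entities = entity_catalog(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nx <- config$grid_width; ny <- config$grid_height
  n <- nx * ny
  nb <- .neighbor_tables(nx, ny)
  ne <- length(entities$names)
  fields <- matrix(0, n, ne, dimnames = list(NULL, entities$names))
  damage <- numeric(n)

  counts <- vapply(.MOBILE_TYPES,
                   function(t) as.integer(config$census[[t]] %||% 0L),
                   integer(1))
  type <- rep(seq_along(.MOBILE_TYPES), counts)
  n_ag <- length(type)
  pos <- sample.int(n, n_ag, replace = TRUE)
  act <- numeric(n_ag)
  age <- numeric(n_ag)

  injured <- .grow_patch(config$injury_size, nb$nb4, n)
  if (length(injured)) {
    damage[injured] <- 1
    fields[injured, "PAF"] <- config$injury_bolus
  }

  structure(list(cfg = config, entities = entities, n = n,
                 nb4 = nb$nb4, nb8 = nb$nb8,
                 fields = fields, damage = damage,
                 type = type, pos = pos, act = act, age = age,
                 step = 0L),
            class = "world_state")
}

#' @export
print.world_state <- function(x, ...) {
  cat("ABM world:", x$cfg$grid_width, "x", x$cfg$grid_height,
      "grid;", length(x$type), "mobile agents; health",
      round(world_health(x), 3), "; step", x$step, "\n")
  invisible(x)
}

#' System health: fraction of undamaged endothelium
#' @param world a `world_state`.
#' @export
world_health <- function(world) 1 - mean(world$damage)

# precompile rule metadata and per-step constants so the step loop only
# indexes integers and reuses preallocated matrices
.compile_kernel <- function(mrm, cfg, n) {
  rl <- mrm$rules$rules
  ent <- mrm$entities$names
  ne <- length(ent)
  fam <- match(rl$family, c("cytokine-upregulation", "cytokine-downregulation",
                            "cell-activation", "cellular-differentiation",
                            "lifespan"))
  owner <- match(rl$cell_type, c("endothelial", .MOBILE_TYPES)) - 1L
  # owner: 0 = endothelial, 1..6 mobile type codes
  dec <- rep_len(cfg$decay, ne)
  dif <- rep_len(cfg$diffusion, ne)
  target_entity <- match(rl$target, ent)              # NA unless a field
  mob_sec <- which(owner > 0L & fam %in% c(1L, 2L))   # batched in the step
  list(df = rl, fam = fam, owner = owner,
       target_entity = target_entity,
       target_type = match(rl$target, .MOBILE_TYPES), # NA unless lineage
       logistic = rl$response == "logistic",
       M = t(mrm$values),  # entities x rules, drives = C %*% M
       DECM = matrix(rep(1 - dec, each = n), n, ne),
       DIFM = matrix(rep(dif, each = n), n, ne),
       lsp = unlist(cfg$lifespans[.MOBILE_TYPES]),
       chemo_cols = match(c("IL-8", "PAF", "MIP-1b"), ent),
       mob_sec = mob_sec,
       mob_sec_owner = owner[mob_sec],
       mob_sec_entoff = (target_entity[mob_sec] - 1L) * n,
       mob_sec_rate = ifelse(fam[mob_sec] == 1L, cfg$secrete_rate,
                             -cfg$downreg_rate),
       other_rules = which(!(owner > 0L & fam %in% c(1L, 2L))))
}

#' Advance the world by one step
#'
#' One synchronous update: all rule drives are computed from the
#' start-of-step field snapshot (removing update-order bias), effects are
#' applied, fields decay and diffuse, mobile cells move (random walk, or up
#' the chemoattractant gradient when it exceeds the chemotaxis threshold),
#' and cells age, die and are replenished from the precursor pool.
#'
#' @param world a `world_state`.
#' @param mrm a `model_rule_matrix` (or the result of the internal rule
#'   compilation, reused across steps by [run_simulation()]).
#' @return the successor `world_state`.
#' @export
abm_step <- function(world, mrm) {
  rc <- if (inherits(mrm, "model_rule_matrix"))
    .compile_kernel(mrm, world$cfg, world$n) else mrm
  cfg <- world$cfg
  n <- world$n
  fields <- world$fields
  damage <- world$damage
  typev <- world$type; posv <- world$pos
  actv <- world$act * cfg$act_decay
  agev <- world$age
  F0 <- fields                          # snapshot drives are computed from
  n_ag <- length(typev)
  alive <- rep(TRUE, n_ag)

  # drives for every (agent, rule) at once: one n_agents x 25 product
  drv_ag <- if (n_ag) F0[posv, , drop = FALSE] %*% rc$M else
    matrix(0, 0, ncol(rc$M))

  new_type <- typev
  apop_p <- numeric(n_ag)
  diff_p1 <- rep(NA_real_, n_ag); diff_t1 <- integer(n_ag)
  diff_p2 <- rep(NA_real_, n_ag); diff_t2 <- integer(n_ag)

  # field changes are accumulated and applied together after the rule loop,
  # so every rule reads the unmodified start-of-step snapshot
  dep_key <- vector("list", 8L); dep_amt <- vector("list", 8L); ndep <- 0L
  dmg_idx <- which(damage > 0)

  # all mobile-cell secretion/uptake rules in one vectorized block: the
  # (agent, rule) amount is nonzero only for the rule's owner type
  if (n_ag && length(rc$mob_sec)) {
    D <- drv_ag[, rc$mob_sec, drop = FALSE]
    G <- linclip(D)
    lg <- rc$logistic[rc$mob_sec]
    if (any(lg)) G[, lg] <- logistic(D[, lg, drop = FALSE] + cfg$logistic_bias)
    nsr <- length(rc$mob_sec)
    AMT <- G * actv *
      (rc$mob_sec_owner[col(G)] == typev) * rc$mob_sec_rate[col(G)]
    nz <- which(AMT != 0)
    if (length(nz)) {
      rows <- (nz - 1L) %% n_ag + 1L
      cols <- (nz - 1L) %/% n_ag + 1L
      ndep <- ndep + 1L
      dep_key[[ndep]] <- posv[rows] + rc$mob_sec_entoff[cols]
      dep_amt[[ndep]] <- AMT[nz]
    }
  }

  for (k in rc$other_rules) {
    own <- rc$owner[k]
    fam <- rc$fam[k]
    if (own == 0L) {                            # endothelial rules, all sites
      if (fam == 1L) {                          # damage-scaled secretion
        if (length(dmg_idx)) {
          g <- linclip(F0[dmg_idx, , drop = FALSE] %*% rc$M[, k])
          amt <- cfg$secrete_rate * damage[dmg_idx] * g[, 1]
          nz <- which(amt > 0)
          if (length(nz)) {
            ndep <- ndep + 1L
            dep_key[[ndep]] <- dmg_idx[nz] + (rc$target_entity[k] - 1L) * n
            dep_amt[[ndep]] <- amt[nz]
          }
        }
      } else {
        d <- (F0 %*% rc$M[, k])[, 1]
        if (rc$df$target[k] == "damage") {
          damage <- clamp(damage + cfg$damage_rate * linclip(d), 0, 1)
        } else {                                # heal
          g <- logistic(d + cfg$logistic_bias)
          damage <- clamp(damage - cfg$heal_rate * g, 0, 1)
        }
      }
      next
    }
    sel <- which(typev == own)
    if (!length(sel)) next
    d <- drv_ag[sel, k]
    if (fam == 3L) {                            # activation
      g <- logistic(d + cfg$logistic_bias)
      actv[sel] <- clamp(actv[sel] + cfg$act_relax * (g - actv[sel]), 0, 1)
    } else if (fam == 4L) {                     # differentiation
      g <- logistic(d + cfg$logistic_bias)
      p <- cfg$diff_prob * g
      first <- is.na(diff_p1[sel])
      diff_p1[sel][first] <- p[first]; diff_t1[sel][first] <- rc$target_type[k]
      diff_p2[sel][!first] <- p[!first]; diff_t2[sel][!first] <- rc$target_type[k]
    } else {                                    # lifespan (apoptosis)
      g <- logistic(d + cfg$logistic_bias)
      apop_p[sel] <- apop_p[sel] + cfg$apop_prob * g
    }
  }

  # apply accumulated secretion/uptake; concentrations floor at zero
  if (ndep) {
    dep <- rowsum(unlist(dep_amt[seq_len(ndep)]),
                  unlist(dep_key[seq_len(ndep)]), reorder = FALSE)
    idx <- as.integer(rownames(dep))
    fields[idx] <- pmax(0, fields[idx] + dep[, 1])
  }

  # resolve stochastic differentiation (at most two competing lineages)
  cand <- which(!is.na(diff_p1))
  if (length(cand)) {
    u <- stats::runif(length(cand))
    p1 <- diff_p1[cand]
    p2 <- diff_p2[cand]; p2[is.na(p2)] <- 0
    to1 <- u < p1
    to2 <- !to1 & u < p1 + p2
    new_type[cand[to1]] <- diff_t1[cand[to1]]
    new_type[cand[to2]] <- diff_t2[cand[to2]]
    converted <- cand[to1 | to2]
    # differentiated precursors are replaced from the marrow pool
    prec_code <- match("precursor", .MOBILE_TYPES)
    repl <- converted[typev[converted] == prec_code]
    if (length(repl)) {
      k <- length(repl)
      typev <- c(typev, rep(prec_code, k))
      posv <- c(posv, sample.int(n, k, replace = TRUE))
      actv <- c(actv, numeric(k))
      agev <- c(agev, numeric(k))
      new_type <- c(new_type, rep(prec_code, k))
      alive <- c(alive, rep(TRUE, k))
      apop_p <- c(apop_p, numeric(k))
      n_ag <- length(typev)
    }
  }
  typev <- new_type

  # apoptosis and senescence
  ap <- which(apop_p > 0)
  if (length(ap)) {
    alive[ap] <- alive[ap] & stats::runif(length(ap)) >= pmin(apop_p[ap], 1)
  }
  agev <- agev + 1
  alive <- alive & agev <= rc$lsp[typev]
  if (!all(alive)) {
    typev <- typev[alive]; posv <- posv[alive]
    actv <- actv[alive]; agev <- agev[alive]
    n_ag <- length(typev)
  }

  # field decay then 4-neighbor diffusion (explicit, stable for D <= 0.25)
  Fd <- fields * rc$DECM
  nbsum <- Fd[world$nb4[, 1], ] + Fd[world$nb4[, 2], ] +
    Fd[world$nb4[, 3], ] + Fd[world$nb4[, 4], ]
  fields <- Fd + (nbsum - 4 * Fd) * rc$DIFM

  # movement: chemotaxis up the attractant gradient, else random Moore walk
  if (n_ag) {
    chemo <- fields[, rc$chemo_cols[1]] + fields[, rc$chemo_cols[2]] +
      fields[, rc$chemo_cols[3]]
    nbpos <- world$nb8[posv, , drop = FALSE]
    nbc <- matrix(chemo[nbpos], n_ag, 8)
    best <- max.col(nbc, ties.method = "first")
    bestv <- nbc[cbind(seq_len(n_ag), best)]
    taxis <- typev %in% 1:2 &                  # macrophages and neutrophils
      (bestv - chemo[posv]) > cfg$chemo_threshold
    choice <- sample.int(8, n_ag, replace = TRUE)
    choice[taxis] <- best[taxis]
    posv <- nbpos[cbind(seq_len(n_ag), choice)]
  }

  world$fields <- fields
  world$damage <- damage
  world$type <- typev; world$pos <- posv
  world$act <- actv; world$age <- agev

  world$step <- world$step + 1L
  world
}

#' Run one stochastic simulation
#'
#' Runs `config$duration` steps from a seeded initialization, sampling the
#' grid-aggregated mediator concentrations every `sampling_interval` steps,
#' and classifies the outcome from system health (fraction of undamaged
#' endothelium): `dead` if health ever falls to the death threshold (the run
#' truncates), `resolved` if terminal health reaches the resolve threshold,
#' otherwise `persistent-inflammation`.
#'
#' @param config a [sim_config()].
#' @param mrm a `model_rule_matrix`.
#' @param seed integer seed governing every stochastic draw of the run.
#' @return a `trajectory` object: `times` (sampled steps), `values`
#'   (time x entity aggregate matrix), `health`, `outcome`, `seed`, `mrm_id`.
#' @export
run_simulation <- function(config, mrm, seed = 1L) {
  set.seed(seed)
  world <- abm_initialize(config, mrm$entities)
  rc <- .compile_kernel(mrm, config, world$n)
  n_samp <- config$duration %/% config$sampling_interval + 1L
  times <- seq(0L, by = config$sampling_interval, length.out = n_samp)
  vals <- matrix(NA_real_, n_samp, ncol(world$fields),
                 dimnames = list(NULL, mrm$entities$names))
  health <- rep(NA_real_, n_samp)
  vals[1, ] <- colSums(world$fields)
  health[1] <- world_health(world)
  outcome <- NA_character_
  si <- 1L
  for (s in seq_len(config$duration)) {
    world <- abm_step(world, rc)
    if (s %% config$sampling_interval == 0L) {
      si <- si + 1L
      vals[si, ] <- colSums(world$fields)
      health[si] <- world_health(world)
    }
    if (world_health(world) <= config$death_threshold) {
      outcome <- "dead"
      break
    }
  }
  if (is.na(outcome)) {
    outcome <- if (health[n_samp] >= config$resolve_threshold) "resolved"
    else "persistent-inflammation"
  }
  structure(list(times = times, values = vals, health = health,
                 outcome = outcome, seed = seed,
                 mrm_id = attr(mrm, "mrm_id") %||%
                   substr(config_hash(mrm$values), 1, 12)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  k <- sum(!is.na(x$health))
  cat("Trajectory:", k, "samples,", ncol(x$values), "entities; outcome",
      x$outcome, "; terminal health",
      round(x$health[max(which(!is.na(x$health)))], 3), "\n")
  invisible(x)
}

#' Terminal health of a trajectory (last recorded sample)
#' @param traj a `trajectory`.
#' @export
terminal_health <- function(traj) {
  h <- traj$health[!is.na(traj$health)]
  h[length(h)]
}

#' Run stochastic replicates and compute the trajectory-space envelope
#'
#' Replicate seeds are drawn from a seeded stream, so the first `n` seeds of
#' a longer stream coincide with a shorter one (nested envelopes).  The
#' envelope is the per-time per-entity min/max band across replicates;
#' samples after a truncated (dead) run are ignored.
#'
#' @param config a [sim_config()].
#' @param mrm a `model_rule_matrix`.
#' @param n number of replicates (>= 1).
#' @param base_seed seed of the replicate-seed stream.
#' @param injury_sizes optional vector of injury sizes cycled across
#'   replicates (the insult sweep); default: the config's single size.
#' @return a `trajectory_space`: `replicates`, `times`, `env_lo`, `env_hi`.
#' @export
run_replicates <- function(config, mrm, n = config$replicate_count,
                           base_seed = 1L, injury_sizes = NULL) {
  if (n < 1) stop_param("replicate count must be >= 1")
  set.seed(base_seed)
  seeds <- sample.int(.SEED_MOD, n, replace = TRUE)
  inj <- if (is.null(injury_sizes)) rep(config$injury_size, n) else
    rep_len(as.integer(injury_sizes), n)
  reps <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$injury_size <- inj[i]
    run_simulation(cfg, mrm, seeds[i])
  })
  structure(c(trajectory_envelope(reps), list(replicates = reps)),
            class = "trajectory_space")
}

#' Envelope (per-time per-entity min/max) of a list of trajectories
#' @param reps list of `trajectory` objects on a shared sampling grid.
#' @export
trajectory_envelope <- function(reps) {
  arr <- array(unlist(lapply(reps, function(t) t$values)),
               dim = c(dim(reps[[1]]$values), length(reps)))
  # times past the horizon of every (truncated) replicate have no finite
  # values; they become NA bands below
  lo <- suppressWarnings(apply(arr, c(1, 2), min, na.rm = TRUE))
  hi <- suppressWarnings(apply(arr, c(1, 2), max, na.rm = TRUE))
  lo[!is.finite(lo)] <- NA; hi[!is.finite(hi)] <- NA
  dimnames(lo) <- dimnames(hi) <- dimnames(reps[[1]]$values)
  list(times = reps[[1]]$times, env_lo = lo, env_hi = hi)
}

#' @export
print.trajectory_space <- function(x, ...) {
  cat("Trajectory space:", length(x$replicates), "replicates,",
      length(x$times), "sampled times\n")
  cat(" outcomes:", paste(names(table(vapply(x$replicates,
        function(t) t$outcome, character(1)))), collapse = ", "), "\n")
  invisible(x)
}
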