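#' @keywords internal
"_PACKAGE"

# Largest seed handed to set.seed(); all derived seeds stay below 2^31.
.SEED_MOD <- 2147483629L  # prime just under 2^31

#' Derive a stream of child seeds from a master seed
#'
#' Counter-based derivation: child i is a fixed affine function of the master
#' seed, so any component's seed is reproducible without consuming the global
#' RNG stream and independent of how many siblings were derived before it.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @param stream integer stream offset separating independent consumers
#'   (e.g. GA candidates vs replicate runs) of the same master seed.
#' @return integer vector of `n` seeds in `[1, 2^31)`.
#' @export
derive_seeds <- function(master, n, stream = 0L) {
  master <- as.double(master)
  i <- seq_len(n)
  # 64-bit-safe modular arithmetic in doubles (all operands < 2^53)
  s <- (master %% .SEED_MOD) * 48271 + stream * 16807 + i * 69621
  as.integer(s %% .SEED_MOD) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

# clipped-linear response used by secretion rules: zero below 0, saturates at 2
linclip <- function(x, hi = 2) pmin(pmax(x, 0), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# clinical-time binning with left-open intervals (k*w, (k+1)*w]: a time on a
# bin boundary belongs to the preceding bin, so horizon-edge bins never hold
# a single boundary sample; t = 0 stays in bin 0
time_bin <- function(t, width) {
  b <- ceiling(t / width) - 1
  b[t <= 0] <- 0
  b * width
}

stop_config <- function(...) {
  stop(structure(class = c("smtgen_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_param <- function(...) {
  stop(structure(class = c("smtgen_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("smtgen_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# stable hash of an R object via its canonical JSON serialization
config_hash <- function(x) {
  j <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  # md5 of the JSON text; used only for provenance stamps, not security
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(j, tmp)
  unname(tools::md5sum(tmp))
}
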