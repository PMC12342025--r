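#' Model Rule Matrix
#'
#' The Model Rule Matrix (MRM) is the central parameterization object: a real
#' matrix with one row per behavioral rule (default 25) and one column per
#' mediator entity (default 17).  Element (r, j) gives the signed strength of
#' mediator j's contribution to the drive of rule r; a zero denotes an absent
#' (latent) interaction.  The base MRM carries nonzero values only at the
#' explicitly modeled interactions (`base_mask`); calibration may enrich any
#' element within the coefficient bounds.
#'
#' @param values numeric matrix, rules x entities.
#' @param entities an [entity_catalog()].
#' @param rules a [rule_catalog()].
#' @param base_mask logical matrix marking explicitly modeled elements.
#' @param bounds length-2 numeric, closed coefficient interval.
#' @return a `model_rule_matrix` object.
#' @export
model_rule_matrix <- function(values, entities, rules, base_mask,
                              bounds = c(-2, 2)) {
  nr <- nrow(rules$rules); ne <- length(entities$names)
  if (!all(dim(values) == c(nr, ne))) {
    stop_config("MRM values must be ", nr, " x ", ne, ", got ",
                paste(dim(values), collapse = " x "))
  }
  if (!all(dim(base_mask) == c(nr, ne))) {
    stop_config("base_mask shape mismatch")
  }
  if (bounds[1] >= bounds[2]) stop_config("bounds must be increasing")
  if (any(values < bounds[1] - 1e-12) || any(values > bounds[2] + 1e-12)) {
    stop_config("MRM values outside bounds [", bounds[1], ", ", bounds[2], "]")
  }
  dimnames(values) <- list(rules$rules$id, entities$names)
  structure(list(values = values, entities = entities, rules = rules,
                 base_mask = base_mask, bounds = as.numeric(bounds)),
            class = "model_rule_matrix")
}

#' Build the base (sparse) Model Rule Matrix
#'
#' Places the default signed coefficients of the explicitly modeled
#' interactions and zero everywhere else; the zero elements form the latent
#' interaction space that calibration may enrich.
#'
#' @param entities an [entity_catalog()].
#' @param rules a [rule_catalog()].
#' @param interactions data.frame (`rule`, `entity`, `coef`) of base
#'   couplings; defaults to [default_base_interactions()].
#' @param bounds coefficient interval, default `c(-2, 2)` giving a maximal
#'   achievable per-element range of 4.
#' @return a `model_rule_matrix` whose `base_mask` marks exactly the listed
#'   interactions.
#' @export
build_base_mrm <- function(entities = entity_catalog(),
                           rules = rule_catalog(),
                           interactions = default_base_interactions(),
                           bounds = c(-2, 2)) {
  nr <- nrow(rules$rules); ne <- length(entities$names)
  v <- matrix(0, nr, ne)
  mask <- matrix(FALSE, nr, ne)
  ri <- match(interactions$rule, rules$rules$id)
  ei <- match(interactions$entity, entities$names)
  if (anyNA(ri)) {
    stop_config("unknown rule in interaction list: ",
                paste(unique(interactions$rule[is.na(ri)]), collapse = ", "))
  }
  if (anyNA(ei)) {
    stop_config("unknown entity in interaction list: ",
                paste(unique(interactions$entity[is.na(ei)]), collapse = ", "))
  }
  idx <- cbind(ri, ei)
  v[idx] <- interactions$coef
  mask[idx] <- TRUE
  model_rule_matrix(v, entities, rules, mask, bounds)
}

#' Mutate a Model Rule Matrix
#'
#' GA mutation operator: each element is independently perturbed with
#' probability `rate` by additive uniform noise on `[-scale, scale]`, then
#' clipped to the coefficient bounds.  Zero (latent) elements may become
#' nonzero -- this is the enrichment mechanism by which calibration uncovers
#' latent interactions.
#'
#' @param mrm a `model_rule_matrix`.
#' @param rate per-element mutation probability in `[0, 1]`.
#' @param scale half-width of the additive uniform noise (> 0).
#' @return a mutated `model_rule_matrix` (base_mask unchanged).
#' @export
mrm_mutate <- function(mrm, rate = 0.1, scale = 0.5) {
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop_param("mutation rate must be in [0, 1]")
  }
  if (!is.numeric(scale) || scale <= 0) stop_param("mutation scale must be > 0")
  v <- mrm$values
  hit <- matrix(stats::runif(length(v)) < rate, nrow(v), ncol(v))
  if (any(hit)) {
    v[hit] <- v[hit] + stats::runif(sum(hit), -scale, scale)
    v <- clamp(v, mrm$bounds[1], mrm$bounds[2])
  }
  out <- mrm
  out$values[] <- v
  out
}

#' Uniform elementwise crossover of two Model Rule Matrices
#'
#' Each element of the child is drawn from parent `a` or parent `b` with
#' equal probability.
#'
#' @param a,b `model_rule_matrix` objects sharing catalogs.
#' @return a child `model_rule_matrix`.
#' @export
mrm_crossover <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(a$entities$names, b$entities$names) ||
      !identical(a$rules$rules$id, b$rules$rules$id)) {
    stop_config("crossover parents must share catalogs")
  }
  pick <- matrix(stats::runif(length(a$values)) < 0.5,
                 nrow(a$values), ncol(a$values))
  out <- a
  out$values[!pick] <- b$values[!pick]
  out
}

#' Per-element value ranges across an ensemble of MRMs
#'
#' @param ensemble nonempty list of `model_rule_matrix` sharing catalogs.
#' @return a `range_matrix`: numeric matrix of per-element max - min, all in
#'   `[0, width(bounds)]` (4 under default bounds); an ensemble of one gives
#'   all zeros.
#' @export
element_ranges <- function(ensemble) {
  if (length(ensemble) == 0) stop_param("ensemble must be nonempty")
  vals <- lapply(ensemble, function(m) m$values)
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) all(dim(v) == d), logical(1)))) {
    stop_config("ensemble members must share catalogs")
  }
  arr <- array(unlist(vals), dim = c(d, length(vals)))
  rng <- apply(arr, c(1, 2), max) - apply(arr, c(1, 2), min)
  dimnames(rng) <- dimnames(vals[[1]])
  structure(rng, class = c("range_matrix", class(rng)))
}

#' Count nonzero elements of an MRM
#' @param mrm a `model_rule_matrix`.
#' @param tol values with absolute size at or below `tol` count as zero.
#' @export
mrm_nonzero_count <- function(mrm, tol = 0) sum(abs(mrm$values) > tol)

#' Serialize / deserialize a Model Rule Matrix as JSON
#'
#' The JSON carries the catalogs, bounds, row-major values and base mask, so
#' a matrix round-trips standalone: `deserialize_mrm(serialize_mrm(m))`
#' reproduces `m` exactly at the stored decimal precision.
#'
#' @param mrm a `model_rule_matrix`.
#' @param digits significant digits stored (`NA` = full precision).
#' @return `serialize_mrm`: a JSON string; `deserialize_mrm`: a
#'   `model_rule_matrix`.
#' @export
serialize_mrm <- function(mrm, digits = NA) {
  payload <- list(
    entities = mrm$entities$names,
    observed = mrm$entities$observed,
    rules = mrm$rules$rules,
    bounds = mrm$bounds,
    values = mrm$values,          # serialized row-wise by jsonlite
    base_mask = mrm$base_mask
  )
  as.character(jsonlite::toJSON(payload, digits = digits, auto_unbox = TRUE))
}

#' @rdname serialize_mrm
#' @param text JSON produced by `serialize_mrm`.
#' @export
deserialize_mrm <- function(text) {
  p <- tryCatch(jsonlite::fromJSON(text),
                error = function(e) stop_validation("MRM parse error: ",
                                                    conditionMessage(e)))
  req <- c("entities", "rules", "bounds", "values", "base_mask")
  if (!all(req %in% names(p))) {
    stop_validation("MRM JSON missing fields: ",
                    paste(setdiff(req, names(p)), collapse = ", "))
  }
  ents <- entity_catalog(p$entities, p$observed %||% p$entities)
  rules <- rule_catalog(as.data.frame(p$rules))
  v <- matrix(as.numeric(p$values), nrow(p$values), ncol(p$values))
  mask <- matrix(as.logical(p$base_mask), nrow(p$base_mask), ncol(p$base_mask))
  model_rule_matrix(v, ents, rules, mask, as.numeric(p$bounds))
}

#' Write / read an MRM JSON file
#' @param mrm a `model_rule_matrix`.
#' @param path file path.
#' @export
write_mrm <- function(mrm, path) {
  writeLines(serialize_mrm(mrm), path)
  invisible(path)
}

#' @rdname write_mrm
#' @export
read_mrm <- function(path) deserialize_mrm(paste(readLines(path), collapse = "\n"))

#' @export
print.model_rule_matrix <- function(x, ...) {
  cat("Model Rule Matrix:", nrow(x$values), "rules x", ncol(x$values),
      "entities;", mrm_nonzero_count(x), "nonzero elements; bounds [",
      x$bounds[1], ",", x$bounds[2], "]\n")
  invisible(x)
}
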