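#' Default mediator entity catalog
#'
#' The simulator tracks 17 molecular mediators.  Nine of them correspond to
#' cytokines routinely measured in multiplexed blood-serum panels after severe
#' injury (IL-1b, IL-1ra, IL-6, IL-4, IL-8, IL-10, GCSF, IFNg, TNFa); these
#' form the default `observed` subset matched against clinical-style reference
#' data.  The remaining eight slots are additional innate-immune mediators
#' (platelet-activating factor, soluble receptors, NO and friends) carried at
#' the same dimensionality; their names are documented placeholders for
#' mediators a full-fidelity model would resolve.
#'
#' @param names character vector of entity names (unique).
#' @param observed character vector, subset of `names`, matched to reference
#'   measurements.
#' @return an `entity_catalog` object: list with `names`, `units`,
#'   `observed` (names) and `observed_idx` (indices).
#' @export
entity_catalog <- function(names = default_entity_names(),
                           observed = default_observed_entities()) {
  if (anyDuplicated(names)) stop_config("entity names must be unique")
  if (!all(observed %in% names)) {
    stop_config("observed entities not in catalog: ",
                paste(setdiff(observed, names), collapse = ", "))
  }
  structure(list(
    names = as.character(names),
    units = rep("au", length(names)),
    observed = as.character(observed),
    observed_idx = match(observed, names)
  ), class = "entity_catalog")
}

#' @rdname entity_catalog
#' @export
default_entity_names <- function() {
  c("IL-1b", "IL-1ra", "IL-6", "IL-4", "IL-8", "IL-10", "GCSF", "IFNg",
    "TNFa",
    # non-observed mediator slots (placeholder identities, see above)
    "PAF", "sTNFr", "sIL-1r", "IL-12", "GM-CSF", "MIP-1b", "NO", "TGFb")
}

#' @rdname entity_catalog
#' @export
default_observed_entities <- function() default_entity_names()[1:9]

#' Default behavioral rule catalog
#'
#' Twenty-five cell behavioral rules distributed across the five rule
#' families of the simulator: cytokine upregulation (secretion), cytokine
#' downregulation (uptake/neutralization), cell activation, cellular
#' differentiation, and lifespan (damage, healing, apoptosis).  Each rule is
#' owned by one cell type and reads its mediator coefficients from the
#' matching row of a Model Rule Matrix.
#'
#' Response kinds: `"linear"` rules pass their drive through a clipped-linear
#' ramp (secretion rates); `"logistic"` rules through a logistic squashing
#' (probabilities and activation targets).
#'
#' @param rules data.frame with columns `id`, `cell_type`, `family`,
#'   `target`, `response`.
#' @return a `rule_catalog` object wrapping the data.frame.
#' @export
rule_catalog <- function(rules = default_rules()) {
  req <- c("id", "cell_type", "family", "target", "response")
  if (!all(req %in% names(rules))) stop_config("rule table missing columns")
  if (anyDuplicated(rules$id)) stop_config("rule ids must be unique")
  fams <- c("cytokine-upregulation", "cytokine-downregulation",
            "cell-activation", "cellular-differentiation", "lifespan")
  if (!all(rules$family %in% fams)) {
    stop_config("unknown rule family: ",
                paste(setdiff(rules$family, fams), collapse = ", "))
  }
  structure(list(rules = rules), class = "rule_catalog")
}

#' @rdname rule_catalog
#' @export
default_rules <- function() {
  r <- function(id, cell_type, family, target, response)
    data.frame(id = id, cell_type = cell_type, family = family,
               target = target, response = response,
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    # -- endothelium --------------------------------------------------------
    r("endo_il8_secretion",  "endothelial", "cytokine-upregulation",   "IL-8",       "linear"),
    r("endo_paf_secretion",  "endothelial", "cytokine-upregulation",   "PAF",        "linear"),
    r("endo_damage",         "endothelial", "lifespan",                "damage",     "linear"),
    r("endo_heal",           "endothelial", "lifespan",                "heal",       "logistic"),
    # -- macrophages --------------------------------------------------------
    r("mac_activation",      "macrophage",  "cell-activation",         "activation", "logistic"),
    r("mac_tnf_secretion",   "macrophage",  "cytokine-upregulation",   "TNFa",       "linear"),
    r("mac_il1_secretion",   "macrophage",  "cytokine-upregulation",   "IL-1b",      "linear"),
    r("mac_il6_secretion",   "macrophage",  "cytokine-upregulation",   "IL-6",       "linear"),
    r("mac_il10_secretion",  "macrophage",  "cytokine-upregulation",   "IL-10",      "linear"),
    r("mac_gcsf_secretion",  "macrophage",  "cytokine-upregulation",   "GCSF",       "linear"),
    r("mac_tnf_downreg",     "macrophage",  "cytokine-downregulation", "TNFa",       "linear"),
    # -- neutrophils --------------------------------------------------------
    r("neut_activation",     "neutrophil",  "cell-activation",         "activation", "logistic"),
    r("neut_no_secretion",   "neutrophil",  "cytokine-upregulation",   "NO",         "linear"),
    r("neut_il1ra_secretion","neutrophil",  "cytokine-upregulation",   "IL-1ra",     "linear"),
    r("neut_apoptosis",      "neutrophil",  "lifespan",                "apoptosis",  "logistic"),
    # -- T-helper lineage ---------------------------------------------------
    r("th0_activation",      "TH0",         "cell-activation",         "activation", "logistic"),
    r("th0_diff_th1",        "TH0",         "cellular-differentiation","TH1",        "logistic"),
    r("th0_diff_th2",        "TH0",         "cellular-differentiation","TH2",        "logistic"),
    r("th1_ifng_secretion",  "TH1",         "cytokine-upregulation",   "IFNg",       "linear"),
    r("th1_gmcsf_secretion", "TH1",         "cytokine-upregulation",   "GM-CSF",     "linear"),
    r("th1_apoptosis",       "TH1",         "lifespan",                "apoptosis",  "logistic"),
    r("th2_il4_secretion",   "TH2",         "cytokine-upregulation",   "IL-4",       "linear"),
    r("th2_il10_secretion",  "TH2",         "cytokine-upregulation",   "IL-10",      "linear"),
    r("th2_apoptosis",       "TH2",         "lifespan",                "apoptosis",  "logistic"),
    # -- precursor pool -----------------------------------------------------
    r("prec_differentiation","precursor",   "cellular-differentiation","neutrophil", "logistic")
  ))
}

#' Base interaction list for the default rule catalog
#'
#' The explicitly modeled mediator-to-rule couplings: each row gives one
#' nonzero element of the base Model Rule Matrix (rule id, entity, signed
#' coefficient).  Everything not listed here is a latent (zero) element that
#' calibration may switch on.
#'
#' @return data.frame with columns `rule`, `entity`, `coef`.
#' @export
default_base_interactions <- function() {
  b <- function(rule, entity, coef)
    data.frame(rule = rule, entity = entity, coef = coef,
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    b("endo_il8_secretion",   "TNFa",   0.8),
    b("endo_il8_secretion",   "IL-1b",  0.6),
    b("endo_paf_secretion",   "TNFa",   0.5),
    b("endo_damage",          "NO",     0.8),
    b("endo_damage",          "TNFa",   0.4),
    b("endo_heal",            "IL-10",  0.5),
    b("endo_heal",            "TNFa",  -0.5),
    b("endo_heal",            "IL-1b", -0.3),
    b("mac_activation",       "PAF",    1.0),
    b("mac_activation",       "TNFa",   0.6),
    b("mac_activation",       "IFNg",   0.5),
    b("mac_activation",       "IL-10", -1.0),
    b("mac_tnf_secretion",    "PAF",    0.6),
    b("mac_tnf_secretion",    "IFNg",   0.4),
    b("mac_tnf_secretion",    "IL-10", -0.8),
    b("mac_il1_secretion",    "TNFa",   0.5),
    b("mac_il1_secretion",    "PAF",    0.5),
    b("mac_il1_secretion",    "IL-10", -0.6),
    b("mac_il6_secretion",    "IL-1b",  0.6),
    b("mac_il6_secretion",    "TNFa",   0.5),
    b("mac_il6_secretion",    "IL-10", -0.4),
    b("mac_il10_secretion",   "IL-6",   0.5),
    b("mac_il10_secretion",   "TNFa",   0.3),
    b("mac_gcsf_secretion",   "IL-1b",  0.5),
    b("mac_gcsf_secretion",   "TNFa",   0.4),
    b("mac_tnf_downreg",      "sTNFr",  0.8),
    b("mac_tnf_downreg",      "IL-10",  0.5),
    b("neut_activation",      "IL-8",   1.0),
    b("neut_activation",      "PAF",    0.6),
    b("neut_activation",      "GCSF",   0.4),
    b("neut_activation",      "IL-10", -0.8),
    b("neut_no_secretion",    "TNFa",   0.5),
    b("neut_no_secretion",    "IL-8",   0.4),
    b("neut_il1ra_secretion", "IL-10",  0.6),
    b("neut_il1ra_secretion", "IL-6",   0.3),
    b("neut_apoptosis",       "IL-10",  0.6),
    b("neut_apoptosis",       "GCSF",  -0.5),
    b("th0_activation",       "IL-6",   0.5),
    b("th0_activation",       "IL-12",  0.5),
    b("th0_diff_th1",         "IL-12",  0.8),
    b("th0_diff_th1",         "IFNg",   0.6),
    b("th0_diff_th1",         "IL-4",  -0.7),
    b("th0_diff_th2",         "IL-4",   0.8),
    b("th0_diff_th2",         "IL-10",  0.5),
    b("th0_diff_th2",         "IFNg",  -0.7),
    b("th0_diff_th2",         "IL-12", -0.4),
    b("th1_ifng_secretion",   "IL-12",  0.7),
    b("th1_ifng_secretion",   "TNFa",   0.3),
    b("th1_ifng_secretion",   "IL-4",  -0.5),
    b("th1_gmcsf_secretion",  "IFNg",   0.4),
    b("th1_gmcsf_secretion",  "IL-1b",  0.3),
    b("th1_apoptosis",        "IL-10",  0.5),
    b("th1_apoptosis",        "TGFb",   0.4),
    b("th2_il4_secretion",    "IL-4",   0.4),
    b("th2_il4_secretion",    "IL-6",   0.3),
    b("th2_il4_secretion",    "IFNg",  -0.5),
    b("th2_il10_secretion",   "IL-6",   0.4),
    b("th2_il10_secretion",   "IL-4",   0.4),
    b("th2_apoptosis",        "IFNg",   0.4),
    b("th2_apoptosis",        "TGFb",   0.4),
    b("prec_differentiation", "GCSF",   0.8),
    b("prec_differentiation", "GM-CSF", 0.5)
  ))
}

#' @export
print.entity_catalog <- function(x, ...) {
  cat("Entity catalog:", length(x$names), "mediators (",
      length(x$observed), "observed )\n")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.rule_catalog <- function(x, ...) {
  cat("Rule catalog:", nrow(x$rules), "rules\n")
  print(table(x$rules$family))
  invisible(x)
}
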