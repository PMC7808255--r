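# Stability screen: conversion of folding free-energy changes (ddG,
# kcal/mol, positive = destabilizing) to the two-state unfolded fraction,
# severity classification, the predicted-effect labeling rule, per-residue
# foldability aggregation, and the identity-mutation internal control.

.R_GAS <- 1.9872e-3 # kcal / (mol K)

#' Two-state unfolding propensity from ddG
#'
#' The unfolding parameter: the fraction of protein in the unfolded state
#' under a two-state (folded/unfolded) Boltzmann model,
#' u = 1 / (1 + exp(-ddG / (R T))) with R = 1.9872e-3 kcal/(mol K).
#' u(0) = 0.5 exactly, u is strictly increasing in ddG, and
#' u(-x) = 1 - u(x).
#'
#' @param ddg folding free-energy change(s) in kcal/mol (finite).
#' @param temperature absolute temperature in K (default 298).
#' @return unfolded fraction(s) in (0, 1); saturates at the extremes.
#' @export
unfolding_propensity <- function(ddg, temperature = 298) {
  if (temperature <= 0) stop("temperature must be positive")
  if (!all(is.finite(ddg))) stop("ddg must be finite")
  1 / (1 + exp(-ddg / (.R_GAS * temperature)))
}

#' Severity class of an unfolding propensity
#'
#' The propensity is rounded to 2 decimals and binned: 0-0.19 weak,
#' 0.20-0.80 moderate, 0.81-1 severe. (Rounding first closes the printed
#' bin gaps at 0.19-0.20 and 0.80-0.81.)
#'
#' @param u unfolding propensity value(s) in \[0, 1\].
#' @return character vector in {"weak", "moderate", "severe"}.
#' @export
classify_severity <- function(u) {
  if (any(u < 0 | u > 1)) stop("unfolding propensity must be in [0, 1]")
  ur <- round(u, 2)
  ifelse(ur <= 0.19, "weak", ifelse(ur <= 0.80, "moderate", "severe"))
}

#' Predicted effect label of a mutation
#'
#' Severity class of the unfolding propensity, except that mutations with
#' ddG < 0 are labeled Severe: such structures are assumed to be more
#' stable but still non-native, hence disease-causing.
#'
#' @param ddg folding free-energy change(s) in kcal/mol.
#' @param u unfolding propensity value(s); computed from `ddg` at
#'   `temperature` when omitted.
#' @param temperature absolute temperature in K (default 298).
#' @return character vector in {"Weak", "Moderate", "Severe"}.
#' @export
predicted_effect <- function(ddg, u = unfolding_propensity(ddg, temperature),
                             temperature = 298) {
  cls <- classify_severity(u)
  cap <- paste0(toupper(substr(cls, 1, 1)), substr(cls, 2, nchar(cls)))
  ifelse(ddg < 0, "Severe", cap)
}

#' Per-residue foldability score
#'
#' Sum of severity-weighted unfolding propensities over the substitutions
#' generated at one residue: sum of weight(class(u_i)) * u_i. Default
#' weights {weak 0, moderate 0.5, severe 1} make weak substitutions
#' contribute nothing; weights are fully configurable.
#'
#' @param propensities 1 to 20 unfolding propensities for one residue.
#' @param classes severity classes; derived via [classify_severity] when
#'   omitted.
#' @param weights named non-negative weights for classes weak, moderate,
#'   severe.
#' @return non-negative foldability score.
#' @export
foldability <- function(propensities, classes = classify_severity(propensities),
                        weights = c(weak = 0, moderate = 0.5, severe = 1)) {
  n <- length(propensities)
  if (n < 1 || n > 20)
    stop("between 1 and 20 propensities are expected per residue")
  if (length(classes) != n) stop("one class per propensity is required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!all(c("weak", "moderate", "severe") %in% names(weights)))
    stop("weights must name weak, moderate and severe")
  sum(weights[classes] * propensities)
}

#' Internal control on identity mutations
#'
#' Quality check of a structure model: every residue is "mutated" to
#' itself; the resulting identity ddG values are converted to unfolding
#' propensities, each of which should be 0.5. Reports mean, sample SD,
#' t-based 95% confidence interval, and the two-sided one-sample t-test
#' against 0.5.
#'
#' @param identity_ddgs identity-mutation ddG values (n >= 2), kcal/mol.
#' @param temperature absolute temperature in K (default 298).
#' @return object of class `internal_control`: `n`, `mean`, `sd`, `ci95`
#'   (low, high), `p_value`, `propensities`.
#' @export
internal_control <- function(identity_ddgs, temperature = 298) {
  n <- length(identity_ddgs)
  if (n < 2) stop("at least 2 identity ddG values are required")
  u <- unfolding_propensity(identity_ddgs, temperature)
  m <- mean(u); s <- sd(u)
  if (s == 0) {
    ci <- c(m, m)
    p <- if (m == 0.5) 1 else 0
  } else {
    se <- s / sqrt(n)
    tq <- qt(0.975, df = n - 1)
    ci <- c(m - tq * se, m + tq * se)
    tstat <- (m - 0.5) / se
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  structure(list(n = n, mean = m, sd = s, ci95 = ci, p_value = p,
                 propensities = u),
            class = "internal_control")
}

#' @export
print.internal_control <- function(x, ...) {
  cat(sprintf(
    "<internal_control> n = %d: mean %.4f, sd %.4f, 95%% CI [%.4f, %.4f], p = %.3g\n",
    x$n, x$mean, x$sd, x$ci95[1], x$ci95[2], x$p_value))
  cat("  (each identity propensity should be 0.5)\n")
  invisible(x)
}

#' Annotate a mutation table with unfolding propensities and labels
#'
#' Adds `unfolding` (rounded to 2 decimals, the reporting convention),
#' `severity_class` and `predicted_effect` columns to a table carrying
#' `mutation` and `ddg` columns.
#'
#' @param table data.frame with columns `mutation` and `ddg` (kcal/mol).
#' @param temperature absolute temperature in K (default 298).
#' @return the annotated data.frame.
#' @export
stability_table <- function(table, temperature = 298) {
  if (!all(c("mutation", "ddg") %in% names(table)))
    stop("table must carry 'mutation' and 'ddg' columns")
  u <- unfolding_propensity(table$ddg, temperature)
  table$unfolding <- round(u, 2)
  table$severity_class <- classify_severity(u)
  table$predicted_effect <- predicted_effect(table$ddg, u)
  table
}

#' Packaged OCA1 mutation tables
#'
#' The published ddG tables for the eight OCA1B mutants and the eleven
#' active-site histidine OCA1A mutants of human tyrosinase, shipped as
#' TSV fixtures. ddG values are FoldX outputs and are inputs to this
#' pipeline, not reproduced by it.
#'
#' @param which `"oca1b"` (mutation, ddg, dd_v) or `"oca1a"` (mutation,
#'   ddg, dd_v, dd_sa).
#' @return data.frame.
#' @export
oca1_mutations <- function(which = c("oca1b", "oca1a")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0(which, "_mutations.tsv"), package = "tyrcav",
                   mustWork = TRUE)
  read_table(f)
}

#' Packaged reference measurements
#'
#' Published simulation outcomes shipped for comparison and plotting,
#' not reproduced by this pipeline (they depend on the unpublished MD
#' endpoint structures): `"copper_distances"` — Cu-Cu separations at
#' 0/4/25 ns for the wild type and the active-site mutants simulated
#' without the bridging dioxygen; `"interface_cavity"` — EGF-Tyr
#' interface cavity sizes at 100 ns per mutant.
#'
#' @param which which reference table to load.
#' @return data.frame.
#' @export
oca1_reference <- function(which = c("copper_distances",
                                     "interface_cavity")) {
  which <- match.arg(which)
  f <- switch(which,
              copper_distances = "copper_distances_no_o2.tsv",
              interface_cavity = "interface_cavity_reference.tsv")
  read_table(system.file("extdata", f, package = "tyrcav",
                         mustWork = TRUE))
}
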