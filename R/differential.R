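# Paired difference statistics between wild-type and mutant structures at
# two timepoints. For metric M: delta = M(t1) - M(t0) within a structure,
# and delta-delta = delta_mut - delta_wt between structures, e.g.
# ddSA = dSA_mut - dSA_wt, ddV = dV_mut - dV_wt, ddVcav = dVcav_mut -
# dVcav_wt.

#' Within-structure change of a metric
#'
#' @param metric_t1,metric_t0 metric values at the later and earlier
#'   timepoint (same metric kind and units).
#' @return `metric_t1 - metric_t0`.
#' @export
delta <- function(metric_t1, metric_t0) metric_t1 - metric_t0

#' Between-structure difference of changes
#'
#' @param delta_mut,delta_wt within-structure changes of the same metric
#'   in the mutant and the wild type.
#' @return `delta_mut - delta_wt`.
#' @export
delta_delta <- function(delta_mut, delta_wt) delta_mut - delta_wt

#' Measure the structural metrics of one frame
#'
#' Computes the per-structure metrics consumed by the difference
#' analysis: solvent-accessible surface area, solvent-accessible volume,
#' the top-3 cavity-volume sum, and (when both domain residue sets are
#' given) the interface-cavity volume.
#'
#' @param structure a `tyr_structure`.
#' @param label structure id for the output row (defaults to the
#'   structure's own id).
#' @param timepoint time label in ns (defaults to the structure's own).
#' @param sasa_probe,sasa_points Shrake-Rupley parameters.
#' @param volume_probe,volume_spacing accessible-volume parameters.
#' @param cavity_parameters a [cavity_params] object.
#' @param domain_a,domain_b optional disjoint residue-number sets for the
#'   interface cavity (e.g. the EGF-like domain vs the rest).
#' @return data.frame row: label, timepoint, sa, volume, cavity_top3,
#'   interface_cavity (NA when domains are not given or no cavity
#'   qualifies... a qualifying absence is reported as 0).
#' @export
structure_metrics <- function(structure, label = structure$id,
                              timepoint = structure$time,
                              sasa_probe = 1.4, sasa_points = 960,
                              volume_probe = 1.4, volume_spacing = 0.5,
                              cavity_parameters = cavity_params(),
                              domain_a = NULL, domain_b = NULL) {
  if (is.null(timepoint)) stop("a timepoint label is required")
  sa <- sasa(structure, probe_radius = sasa_probe,
             n_sphere_points = sasa_points)$total_area
  vol <- accessible_volume(structure, probe_radius = volume_probe,
                           grid_spacing = volume_spacing)$total_volume
  cavs <- detect_cavities(structure, cavity_parameters)
  top3 <- total_cavity_volume(cavs, 3)
  iface <- NA_real_
  if (!is.null(domain_a) && !is.null(domain_b)) {
    cv <- interface_cavity(cavs, domain_a, domain_b)
    iface <- if (is.null(cv)) 0 else cv$volume
  }
  data.frame(label = label, timepoint = timepoint, sa = sa, volume = vol,
             cavity_top3 = top3, interface_cavity = iface,
             stringsAsFactors = FALSE)
}

#' Build the delta-delta table
#'
#' One record per mutant with ddSA, ddV and ddVcav (and, when interface
#' cavities were measured, ddViface) relative to the wild type. Every
#' structure must be present at the same two timepoints.
#'
#' @param metrics data.frame of [structure_metrics] rows for the wild
#'   type and all mutants at two timepoints.
#' @param wt_label the wild-type label in `metrics`.
#' @return data.frame with columns mutation, dd_sa, dd_v, dd_vcav (and
#'   dd_viface if available).
#' @export
build_dd_table <- function(metrics, wt_label = "WT") {
  need <- c("label", "timepoint", "sa", "volume", "cavity_top3")
  if (!all(need %in% names(metrics)))
    stop("metrics must carry columns: ", paste(need, collapse = ", "))
  tps <- sort(unique(metrics$timepoint))
  if (length(tps) != 2L)
    stop("exactly two timepoints are required, found ",
         length(tps))
  for (lb in unique(metrics$label)) {
    have <- sort(metrics$timepoint[metrics$label == lb])
    if (!identical(have, tps))
      stop("structure '", lb, "' is missing a timepoint")
  }
  if (!wt_label %in% metrics$label)
    stop("wild-type label '", wt_label, "' not found")
  one <- function(lb, col, tp)
    metrics[metrics$label == lb & metrics$timepoint == tp, col]
  d_of <- function(lb, col) delta(one(lb, col, tps[2]), one(lb, col, tps[1]))
  muts <- setdiff(unique(metrics$label), wt_label)
  has_iface <- "interface_cavity" %in% names(metrics) &&
    !anyNA(metrics$interface_cavity)
  rows <- lapply(muts, function(m) {
    out <- data.frame(
      mutation = m,
      dd_sa = delta_delta(d_of(m, "sa"), d_of(wt_label, "sa")),
      dd_v = delta_delta(d_of(m, "volume"), d_of(wt_label, "volume")),
      dd_vcav = delta_delta(d_of(m, "cavity_top3"),
                            d_of(wt_label, "cavity_top3")),
      stringsAsFactors = FALSE)
    if (has_iface)
      out$dd_viface <- delta_delta(d_of(m, "interface_cavity"),
                                   d_of(wt_label, "interface_cavity"))
    out
  })
  do.call(rbind, rows)
}
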