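# Binuclear metal-site geometry: copper-pair separation and histidine
# coordination counts, in single frames and across frame sets. The
# tyrosinase active site holds two coppers 2.7-2.8 A apart, each
# coordinated by three histidines through their side-chain nitrogens.

#' Distance between the two atoms of a metal pair
#'
#' @param structure a `tyr_structure` containing exactly two atoms of the
#'   element.
#' @param element element symbol (default "Cu").
#' @return Euclidean separation in Angstrom.
#' @export
metal_pair_distance <- function(structure, element = "Cu") {
  el <- .normalize_element(element)
  m <- structure$atoms[structure$atoms$element == el, , drop = FALSE]
  if (nrow(m) != 2L)
    stop("expected 2 ", el, " atoms, found ", nrow(m))
  sqrt(sum((as.numeric(m[1, c("x", "y", "z")]) -
              as.numeric(m[2, c("x", "y", "z")]))^2))
}

#' Ligand atoms coordinating a metal
#'
#' Counts ligand atoms within `cutoff` of the metal center, sorted by
#' distance. The default ligand selection is the histidine side-chain
#' nitrogens (ND1/NE2), the atoms that coordinate copper in the
#' tyrosinase active site. The 3.0 A default cutoff covers the typical
#' Cu-N bond (1.9-2.2 A) with slack.
#'
#' @param structure a `tyr_structure`.
#' @param metal_serial serial number of the metal atom.
#' @param ligand one-sided formula selecting ligand atoms (see
#'   [select_atoms]); default His ND1/NE2.
#' @param cutoff coordination cutoff in Angstrom (> 0).
#' @return list with `count` and `atoms` (data.frame of coordinating
#'   atoms with a `distance` column, nearest first).
#' @export
coordination_count <- function(structure, metal_serial,
                               ligand = ~ name %in% c("ND1", "NE2") &
                                 resid == "HIS",
                               cutoff = 3.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- structure$atoms
  mi <- which(a$serial == metal_serial)
  if (length(mi) != 1L)
    stop("no unique atom with serial ", metal_serial)
  lig <- select_atoms(structure, expr = ligand)$atoms
  lig <- lig[lig$serial != metal_serial, , drop = FALSE]
  if (!nrow(lig))
    return(list(count = 0L, atoms = cbind(lig, distance = numeric(0))))
  center <- as.numeric(a[mi, c("x", "y", "z")])
  d <- sqrt((lig$x - center[1])^2 + (lig$y - center[2])^2 +
              (lig$z - center[3])^2)
  keep <- d <= cutoff
  out <- lig[keep, , drop = FALSE]
  out$distance <- d[keep]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  list(count = nrow(out), atoms = out)
}

#' Metal-site report for one frame
#'
#' Pair separation plus per-metal coordination, with a loss-of-coordination
#' flag: a metal coordinated by `loss_threshold` or fewer ligand atoms is
#' considered no longer held in place.
#'
#' @inheritParams coordination_count
#' @param element metal element symbol (default "Cu").
#' @param loss_threshold coordination count at or below which the loss
#'   flag fires (default 1).
#' @return object of class `metal_site_report`: `metal_pair_distance`,
#'   `coordination` (list per metal with serial, count, atoms,
#'   `lost` flag), `frame_label`.
#' @export
metal_site_report <- function(structure, element = "Cu",
                              ligand = ~ name %in% c("ND1", "NE2") &
                                resid == "HIS",
                              cutoff = 3.0, loss_threshold = 1L) {
  el <- .normalize_element(element)
  m <- structure$atoms[structure$atoms$element == el, , drop = FALSE]
  if (nrow(m) != 2L)
    stop("expected 2 ", el, " atoms, found ", nrow(m))
  coord <- lapply(m$serial, function(s) {
    cc <- coordination_count(structure, s, ligand = ligand, cutoff = cutoff)
    list(serial = s, count = cc$count, atoms = cc$atoms,
         lost = cc$count <= loss_threshold)
  })
  structure(list(metal_pair_distance = metal_pair_distance(structure, el),
                 coordination = coord,
                 frame_label = structure$time),
            class = "metal_site_report")
}

#' @export
print.metal_site_report <- function(x, ...) {
  cat(sprintf("<metal_site_report> pair separation %.2f A%s\n",
              x$metal_pair_distance,
              if (!is.null(x$frame_label))
                sprintf(" (t = %g ns)", x$frame_label) else ""))
  for (cc in x$coordination)
    cat(sprintf("  metal serial %d: %d coordinating atoms%s\n",
                cc$serial, cc$count,
                if (cc$lost) "  [coordination lost]" else ""))
  invisible(x)
}

#' Metal-pair separation along a frame set
#'
#' @param trajectory a `tyr_trajectory` whose every frame holds exactly
#'   two atoms of the element.
#' @param element metal element symbol (default "Cu").
#' @return object of class `distance_series`: data.frame with `time` (ns)
#'   and `distance` (A).
#' @export
track_metal_distance <- function(trajectory, element = "Cu") {
  stopifnot(inherits(trajectory, "tyr_trajectory"))
  d <- vapply(seq_along(trajectory$frames), function(k) {
    tryCatch(metal_pair_distance(trajectory$frames[[k]], element),
             error = function(e)
               stop("frame ", k, ": ", conditionMessage(e), call. = FALSE))
  }, numeric(1))
  out <- data.frame(time = trajectory$times, distance = d)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Coordination counts and loss flags along a frame set
#'
#' @inheritParams track_metal_distance
#' @inheritParams metal_site_report
#' @return data.frame with one row per frame: `time`, `distance`,
#'   `count_a`, `count_b`, `lost_a`, `lost_b`.
#' @export
track_coordination <- function(trajectory, element = "Cu",
                               ligand = ~ name %in% c("ND1", "NE2") &
                                 resid == "HIS",
                               cutoff = 3.0, loss_threshold = 1L) {
  stopifnot(inherits(trajectory, "tyr_trajectory"))
  rows <- lapply(seq_along(trajectory$frames), function(k) {
    rep <- metal_site_report(trajectory$frames[[k]], element = element,
                             ligand = ligand, cutoff = cutoff,
                             loss_threshold = loss_threshold)
    data.frame(time = trajectory$times[k],
               distance = rep$metal_pair_distance,
               count_a = rep$coordination[[1]]$count,
               count_b = rep$coordination[[2]]$count,
               lost_a = rep$coordination[[1]]$lost,
               lost_b = rep$coordination[[2]]$lost)
  })
  do.call(rbind, rows)
}
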