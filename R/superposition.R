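# Rigid-body structure comparison: residue pairing by global sequence
# alignment (Needleman-Wunsch, BLOSUM-62, affine gaps), least-squares
# (Kabsch) superposition, and the iterative-pruning RMSD in which atom
# pairs farther than a cutoff under the current best fit are discarded
# and the fit repeated until no pair exceeds the cutoff.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.blosum62_x0 <- function() {
  mat <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  mat["X", ] <- 0L  # X tolerated, scored 0
  mat[, "X"] <- 0L
  mat
}

#' Pair residues by global sequence alignment
#'
#' Optimal Needleman-Wunsch global alignment under BLOSUM-62 with affine
#' gap penalties (defaults: open -11, extend -1 per residue). Unknown
#' residues `X` are tolerated and scored 0. Returned pairs are the
#' aligned (non-gap) columns, one-to-one and order-preserving.
#'
#' @param seq_a,seq_b amino-acid strings over the 20-letter alphabet
#'   (plus X).
#' @param gap_open,gap_extend gap penalties (negative scores).
#' @return object of class `residue_pairing`: `pairs` (two-column matrix
#'   of 1-based positions in seq_a and seq_b) and `score`.
#' @export
align_sequences <- function(seq_a, seq_b, gap_open = -11, gap_extend = -1) {
  for (nm in c("seq_a", "seq_b")) {
    s <- toupper(get(nm))
    ch <- strsplit(s, "")[[1]]
    if (!length(ch)) stop(nm, " is empty")
    bad <- which(!(ch %in% .aa_alphabet))
    if (length(bad))
      stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
           " of ", nm)
    assign(nm, s)
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = .blosum62_x0(),
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  structure(list(pairs = cbind(a = ia[both], b = ib[both]),
                 score = Biostrings::score(al)),
            class = "residue_pairing")
}

#' @export
print.residue_pairing <- function(x, ...) {
  cat(sprintf("<residue_pairing> %d pairs, alignment score %g\n",
              nrow(x$pairs), x$score))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' ||B R + t - A||^2 over the paired coordinate rows (B is moved onto A).
#' The SVD reflection case is sign-corrected so det(R) = +1.
#'
#' @param coords_a,coords_b N x 3 coordinate matrices of paired atoms,
#'   N >= 3.
#' @return object of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd_all`, `rmsd_pruned` (NA here),
#'   `retained_pairs`, `n_initial`, `pruned` (FALSE), `degenerate` flag.
#' @export
kabsch <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B) || ncol(A) != 3L || ncol(B) != 3L)
    stop("coords_a and coords_b must be N x 3 with equal N")
  n <- nrow(A)
  if (n < 3L) stop("at least 3 atom pairs are required")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Bc, Ac)          # 3x3; maximize tr(R' H)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- ca - as.numeric(cb %*% R)
  fitted <- sweep(B %*% R, 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rotation = R, translation = t_vec,
                 rmsd_all = rmsd, rmsd_pruned = NA_real_,
                 retained_pairs = n, n_initial = n,
                 pruned = FALSE,
                 degenerate = min(sv$d) < 1e-8 * max(sv$d, 1e-12)),
            class = "superposition")
}

# Apply a superposition transform to an N x 3 matrix.
.apply_fit <- function(fit, B) {
  sweep(as.matrix(B) %*% fit$rotation, 2, fit$translation, `+`)
}

#' Superposition with iterative pruning of long atom pairs
#'
#' Repeats {fit Kabsch on the retained pairs; drop every pair whose
#' post-fit distance exceeds `cutoff`} until no pair is dropped (the
#' quoted stopping rule: no pair exceeds the cutoff) or dropping would
#' leave fewer than 3 pairs, in which case the last valid fit is kept and
#' the result flagged. `rmsd_pruned` covers the retained pairs;
#' `rmsd_all` covers all initial pairs under the final transform.
#'
#' @inheritParams kabsch
#' @param pairing optional `residue_pairing` restricting which rows are
#'   paired (defaults to row-by-row pairing of the full matrices).
#' @param cutoff pruning distance in Angstrom (default 2.0).
#' @param max_iterations iteration cap.
#' @param batch drop all offending pairs per iteration (default, the
#'   stated stopping rule) or only the single worst pair per iteration.
#' @return a `superposition` with `rmsd_pruned`, `retained_pairs` and a
#'   `warning_state` flag when fewer than 3 pairs could be retained.
#' @export
prune_superpose <- function(coords_a, coords_b, pairing = NULL,
                            cutoff = 2.0, max_iterations = 100,
                            batch = TRUE) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!is.null(pairing)) {
    stopifnot(inherits(pairing, "residue_pairing"))
    A <- A[pairing$pairs[, "a"], , drop = FALSE]
    B <- B[pairing$pairs[, "b"], , drop = FALSE]
  }
  n <- nrow(A)
  if (n < 3L) stop("at least 3 initial pairs are required")
  retained <- seq_len(n)
  fit <- NULL
  warning_state <- FALSE
  for (it in seq_len(max_iterations)) {
    fit <- kabsch(A[retained, , drop = FALSE], B[retained, , drop = FALSE])
    d <- sqrt(rowSums((.apply_fit(fit, B[retained, , drop = FALSE]) -
                         A[retained, , drop = FALSE])^2))
    over <- d > cutoff
    if (!any(over)) break
    drop_idx <- if (batch) which(over) else which.max(d)
    if (length(retained) - length(drop_idx) < 3L) {
      warning_state <- TRUE
      break
    }
    retained <- retained[-drop_idx]
  }
  d_ret <- sqrt(rowSums((.apply_fit(fit, B[retained, , drop = FALSE]) -
                           A[retained, , drop = FALSE])^2))
  d_all <- sqrt(rowSums((.apply_fit(fit, B) - A)^2))
  out <- fit
  out$rmsd_pruned <- sqrt(mean(d_ret^2))
  out$rmsd_all <- sqrt(mean(d_all^2))
  out$retained_pairs <- length(retained)
  out$n_initial <- n
  out$pruned <- TRUE
  out$warning_state <- warning_state
  out
}

#' Superpose two structures through sequence alignment of their CA traces
#'
#' Extracts the CA atoms of each structure, pairs residues by global
#' BLOSUM-62 alignment of the one-letter sequences, then runs the
#' iterative-pruning superposition on the paired CA coordinates.
#'
#' @param structure_a,structure_b `tyr_structure` objects.
#' @param cutoff pruning cutoff in Angstrom (default 2.0).
#' @param ... further arguments for [prune_superpose].
#' @return a `superposition` (see [prune_superpose]).
#' @export
superpose_structures <- function(structure_a, structure_b, cutoff = 2.0,
                                 ...) {
  ca <- function(s) {
    at <- s$atoms[s$atoms$name == "CA" & s$atoms$element == "C", ,
                  drop = FALSE]
    if (!nrow(at)) stop("no CA atoms in structure ", s$id)
    at
  }
  aa <- ca(structure_a); ab <- ca(structure_b)
  seq1 <- paste(bio3d::aa321(aa$resid), collapse = "")
  seq2 <- paste(bio3d::aa321(ab$resid), collapse = "")
  pairing <- align_sequences(seq1, seq2)
  prune_superpose(as.matrix(aa[, c("x", "y", "z")]),
                  as.matrix(ab[, c("x", "y", "z")]),
                  pairing = pairing, cutoff = cutoff, ...)
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition>\n")
  cat(sprintf("  RMSD (all %d pairs):      %.3f A\n", x$n_initial,
              x$rmsd_all))
  if (!is.na(x$rmsd_pruned))
    cat(sprintf("  RMSD (retained %d pairs): %.3f A\n", x$retained_pairs,
                x$rmsd_pruned))
  if (isTRUE(x$warning_state))
    cat("  warning: fewer than 3 pairs could be retained; last valid fit kept\n")
  invisible(x)
}
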