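test_that("global alignment pairs residues and scores under BLOSUM-62", {
  # identical sequences: one pair per residue, score = diagonal sum
  p <- align_sequences("HISTDYR", "HISTDYR")
  expect_equal(nrow(p$pairs), 7)
  b62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  letters <- strsplit("HISTDYR", "")[[1]]
  expect_equal(p$score, sum(b62[cbind(letters, letters)]))

  expect_equal(nrow(align_sequences("ACD", "ACD")$pairs), 3)

  # one gap column in the longer sequence: 4 aligned pairs
  p2 <- align_sequences("ACDEF", "ACEF")
  expect_equal(nrow(p2$pairs), 4)
  expect_true(all(diff(p2$pairs[, "a"]) > 0))
  expect_true(all(diff(p2$pairs[, "b"]) > 0))

  expect_error(align_sequences("AC1D", "ACD"), "position 3")
  expect_error(align_sequences("", "ACD"), "empty")
  # X tolerated
  expect_equal(nrow(align_sequences("AXC", "AXC")$pairs), 3)
})

test_that("Kabsch recovers rigid motions exactly", {
  set.seed(11)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(A, A)$rmsd_all, 0, tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  B <- A %*% R + matrix(c(10, 0, 0), 10, 3, byrow = TRUE)
  fit <- kabsch(A, B)
  expect_equal(fit$rmsd_all, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)
  # recovered transform maps B back onto A
  back <- sweep(B %*% fit$rotation, 2, fit$translation, `+`)
  expect_equal(back, A, tolerance = 1e-6)

  expect_error(kabsch(A[1:2, ], B[1:2, ]), "3")
})

test_that("Kabsch agrees with an independent least-squares implementation", {
  set.seed(12)
  for (k in 1:5) {
    A <- matrix(rnorm(45), 15, 3)
    B <- A + matrix(rnorm(45, sd = 0.5), 15, 3)
    fit <- kabsch(A, B)
    ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(A)),
                                           mobile = as.numeric(t(B))))
    ref_rmsd <- sqrt(mean(rowSums(
      (matrix(ref, ncol = 3, byrow = TRUE) - A)^2)))
    expect_equal(fit$rmsd_all, ref_rmsd, tolerance = 1e-6)
  }
})

test_that("iterative pruning removes outliers and keeps rmsd_pruned <= rmsd_all", {
  set.seed(13)
  A <- matrix(rnorm(60, sd = 4), 20, 3)
  # rigid copy plus 2 atoms displaced by 5 A
  B <- A
  B[3, ] <- B[3, ] + c(5, 0, 0)
  B[17, ] <- B[17, ] + c(0, 5, 0)
  fit <- prune_superpose(A, B, cutoff = 2.0)
  expect_equal(fit$retained_pairs, 18)
  expect_lt(fit$rmsd_pruned, 1e-6)
  expect_gt(fit$rmsd_all, fit$rmsd_pruned)

  # identical structures: nothing pruned, both RMSDs zero
  fit0 <- prune_superpose(A, A)
  expect_equal(fit0$retained_pairs, 20)
  expect_equal(fit0$rmsd_pruned, 0, tolerance = 1e-9)
  expect_equal(fit0$rmsd_all, 0, tolerance = 1e-9)

  # all pairs within cutoff after the first fit: no pruning happens
  B3 <- A + matrix(rnorm(60, sd = 0.2), 20, 3)
  fit3 <- prune_superpose(A, B3, cutoff = 2.0)
  expect_equal(fit3$retained_pairs, 20)

  # property: rmsd_pruned <= rmsd_all on random perturbed fixtures
  for (k in 1:10) {
    Bk <- A + matrix(rnorm(60, sd = runif(1, 0.1, 3)), 20, 3)
    fk <- prune_superpose(A, Bk)
    expect_lte(fk$rmsd_pruned, fk$rmsd_all + 1e-12)
  }
})

test_that("RMSD is invariant to pre-rotation of either input", {
  set.seed(14)
  A <- matrix(rnorm(36, sd = 3), 12, 3)
  B <- A + matrix(rnorm(36, sd = 1), 12, 3)
  base <- kabsch(A, B)$rmsd_all
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  expect_equal(kabsch(A, B %*% R)$rmsd_all, base, tolerance = 1e-9)
  expect_equal(kabsch(A %*% R, B)$rmsd_all, base, tolerance = 1e-9)
})

test_that("whole structures superpose through their CA traces", {
  n <- 30
  set.seed(15)
  xyz <- matrix(rnorm(3 * n, sd = 6), n, 3)
  aas <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
           "HIS", "ILE")
  mk <- function(xyz) new_structure(data.frame(
    name = "CA", resid = rep(aas, 3), chain = "A", resno = 1:n,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = "C",
    stringsAsFactors = FALSE), id = "ca")
  sa <- mk(xyz)
  sb <- rigid_transform(mk(xyz))
  fit <- superpose_structures(sa, sb)
  expect_equal(fit$rmsd_pruned, 0, tolerance = 1e-6)
  expect_equal(fit$retained_pairs, n)
})
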