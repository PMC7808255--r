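test_that("solid clusters have no interior cavities", {
  expect_length(detect_cavities(make_cluster(n = 60, radius = 3))$cavities,
                0)
  expect_equal(total_cavity_volume(detect_cavities(make_cluster())), 0)
})

test_that("a hollow shell yields one cavity near its analytic volume", {
  sh <- make_hollow_shell(12, 1.5)
  cs <- detect_cavities(sh$structure)
  expect_length(cs$cavities, 1)
  cv <- cs$cavities[[1]]
  expect_lt(abs(cv$volume - sh$analytic_volume) / sh$analytic_volume, 0.10)
  expect_equal(cv$volume, cv$voxel_count * 0.6^3, tolerance = 1e-9)
  expect_gte(cv$depth, 5)
  expect_gt(nrow(cv$lining_residues), 0)
  expect_equal(cv$centroid, c(0, 0, 0), tolerance = 0.5,
               ignore_attr = TRUE)
})

test_that("two disjoint shells give two cavities ordered largest-first", {
  s1 <- make_hollow_shell(11, 1.5, center = c(0, 0, 0), chain = "A")
  s2 <- make_hollow_shell(8, 1.5, center = c(40, 0, 0), chain = "B",
                          resno_offset = 5000)
  both <- s1$structure
  both$atoms <- rbind(s1$structure$atoms, s2$structure$atoms)
  both$atoms$serial <- seq_len(nrow(both$atoms))
  cs <- detect_cavities(both)
  expect_length(cs$cavities, 2)
  vols <- sapply(cs$cavities, `[[`, "volume")
  expect_true(all(diff(vols) <= 0))
  expect_lt(abs(vols[1] - s1$analytic_volume) / s1$analytic_volume, 0.10)
  expect_lt(abs(vols[2] - s2$analytic_volume) / s2$analytic_volume, 0.10)
})

test_that("an opened shell loses its cavity to the exterior", {
  open <- make_hollow_shell(12, 1.5, aperture = 8)
  expect_length(detect_cavities(open$structure)$cavities, 0)
})

test_that("total cavity volume follows the top-n summation rule", {
  fake_set <- function(vols) {
    cavs <- lapply(vols, function(v)
      structure(list(volume = v, voxel_count = 1, depth = 10,
                     centroid = c(0, 0, 0),
                     lining_residues = data.frame(chain = "A", resno = 1)),
                class = "cavity"))
    structure(list(cavities = cavs[order(-vols)],
                   parameters = cavity_params()),
              class = "cavity_set")
  }
  expect_equal(total_cavity_volume(fake_set(c(1000, 400, 200, 50))), 1600)
  expect_equal(total_cavity_volume(fake_set(422)), 422)
  expect_equal(total_cavity_volume(structure(
    list(cavities = list(), parameters = cavity_params()),
    class = "cavity_set")), 0)
  # non-decreasing in n, saturates at the full sum
  s <- fake_set(c(1000, 400, 200, 50))
  v <- sapply(1:6, function(n) total_cavity_volume(s, n))
  expect_true(all(diff(v) >= 0))
  expect_equal(v[4], 1650)
  expect_equal(v[6], 1650)
})

test_that("interface cavity requires lining residues from both domains", {
  fake <- function(vol, resnos) structure(
    list(volume = vol, voxel_count = 1, depth = 10, centroid = c(0, 0, 0),
         lining_residues = data.frame(chain = "A", resno = resnos)),
    class = "cavity")
  set <- structure(list(cavities = list(fake(800, c(5, 105)),
                                        fake(300, c(6, 106)),
                                        fake(900, 1:4)),
                        parameters = cavity_params()),
                   class = "cavity_set")
  hit <- interface_cavity(set, 1:100, 101:200)
  expect_equal(hit$volume, 800) # largest of the two qualifying ones
  expect_null(interface_cavity(set, 1:4, 200:300))
  expect_error(interface_cavity(set, 1:10, 5:20), "disjoint")
})

test_that("a two-domain interface pocket is found with both-domain lining", {
  td <- make_two_domain_trajectory(shell_radius = 10, n_frames = 1,
                                   jitter_sd = 0)
  f <- td$trajectory$frames[[1]]
  cs <- detect_cavities(f)
  ic <- interface_cavity(cs, td$domain_a, td$domain_b)
  expect_false(is.null(ic))
  truth <- td$truth$analytic_interface_volume[1]
  expect_lt(abs(ic$volume - truth) / truth, 0.10)
})

test_that("cavity parameters are validated", {
  expect_error(cavity_params(probe_radius = 1, interior_threshold = 1.25),
               "probe_radius > interior_threshold")
  expect_error(cavity_params(min_depth = -1), "min_depth")
  expect_error(cavity_params(grid_spacing = 0), "grid_spacing")
  expect_error(detect_cavities(make_hollow_shell(12, 1.5)$structure,
                               max_voxels = 100), "spacing")
})
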