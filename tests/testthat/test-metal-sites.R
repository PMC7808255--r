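test_that("metal pair distance is the plain Euclidean separation", {
  two <- make_structure(rbind(c(0, 0, 0), c(0, 0, 2.75)), element = "Cu",
                        name = "CU", resid = "CU")
  expect_equal(metal_pair_distance(two), 2.75)
  same <- make_structure(rbind(c(1, 1, 1), c(1, 1, 1)), element = "Cu",
                         name = "CU", resid = "CU")
  expect_equal(metal_pair_distance(same), 0)
  three <- make_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
                          element = "Cu", name = "CU", resid = "CU")
  expect_error(metal_pair_distance(three), "expected 2.*found 3")
})

test_that("coordination counting honors the cutoff and the ligand selection", {
  site <- make_metal_site(separation = 2.75, n_ligands = 3,
                          ligand_dist = 2.1)
  cu_serials <- site$atoms$serial[site$atoms$element == "Cu"]
  cc1 <- coordination_count(site, cu_serials[1])
  cc2 <- coordination_count(site, cu_serials[2])
  expect_equal(cc1$count, 3)
  expect_equal(cc2$count, 3)
  expect_true(all(diff(cc1$atoms$distance) >= 0))
  # tighter cutoff excludes everything at 2.1 A
  expect_equal(coordination_count(site, cu_serials[1], cutoff = 2.0)$count,
               0)
  # counts are non-decreasing in the cutoff
  cuts <- c(1, 2, 2.2, 3, 5)
  counts <- sapply(cuts, function(ct)
    coordination_count(site, cu_serials[1], cutoff = ct)$count)
  expect_true(all(diff(counts) >= 0))
  expect_error(coordination_count(site, 9999), "serial")
})

test_that("removing a coordinating histidine lowers the count by its atoms", {
  site <- make_metal_site(n_ligands = 3)
  cu <- site$atoms$serial[site$atoms$element == "Cu"][1]
  before <- coordination_count(site, cu)
  victim <- before$atoms$resno[1]
  n_removed <- sum(before$atoms$resno == victim)
  pruned <- site
  pruned$atoms <- site$atoms[site$atoms$resno != victim, ]
  after <- coordination_count(pruned, cu)
  expect_equal(after$count, before$count - n_removed)
})

test_that("distance tracking follows frames and flags coordination loss", {
  # constant series
  td <- make_two_domain_trajectory(n_frames = 3, drift_per_frame = 0.5,
                                   jitter_sd = 0)
  ds <- track_metal_distance(td$trajectory)
  expect_equal(ds$distance, rep(2.75, 3))
  expect_equal(ds$time, td$trajectory$times)

  # engineered linear separation 5.7 -> 8.2 A
  mk <- function(d) make_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                                   element = "Cu", name = "CU",
                                   resid = "CU")
  seps <- seq(5.7, 8.2, length.out = 4)
  traj <- as_trajectory(lapply(seps, mk), times = c(0, 4, 25, 100))
  ds2 <- track_metal_distance(traj)
  expect_equal(ds2$distance, seps, tolerance = 1e-9)
  expect_true(all(diff(ds2$distance) > 0))

  # single-frame trajectory
  ds3 <- track_metal_distance(as_trajectory(list(mk(5.7)), times = 0))
  expect_equal(nrow(ds3), 1)

  # loss flag fires exactly when <= 1 ligand remains in cutoff
  full <- make_metal_site(n_ligands = 3)
  rep_full <- metal_site_report(full)
  expect_false(any(sapply(rep_full$coordination, `[[`, "lost")))
  weak <- make_metal_site(n_ligands = 1)
  rep_weak <- metal_site_report(weak)
  expect_true(all(sapply(rep_weak$coordination, `[[`, "lost")))
})

test_that("metal distances are invariant under rigid motion of a frame", {
  site <- make_metal_site(separation = 3.1)
  moved <- rigid_transform(site, angle = 1.1, axis = c(1, 2, 3))
  expect_equal(metal_pair_distance(moved), 3.1, tolerance = 1e-9)
})
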