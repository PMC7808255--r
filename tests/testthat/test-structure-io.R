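test_that("PDB parsing keeps HETATM metals and applies the alt-loc policy", {
  txt <- c(
    pdb_line("ATOM", 1, "CA", "", "ALA", "A", 1, 1, 2, 3),
    pdb_line("HETATM", 2, "CU", "", "CU", "A", 501, 0, 0, 0,
             element = "CU"),
    pdb_line("HETATM", 3, "CU", "", "CU", "A", 502, 0, 0, 2.75,
             element = "CU"),
    "END")
  s <- parse_pdb(txt)
  expect_s3_class(s, "tyr_structure")
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$element, c("C", "Cu", "Cu"))
  expect_equal(s$atoms$x[1], 1)

  # alt-locs: highest occupancy wins, ties -> first record
  alt <- c(
    pdb_line("ATOM", 1, "CA", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.6),
    pdb_line("ATOM", 2, "CA", "B", "ALA", "A", 1, 9, 9, 9, occ = 0.4),
    "END")
  sa <- parse_pdb(alt)
  expect_equal(nrow(sa$atoms), 1)
  expect_equal(sa$atoms$alt, "A")
  tie <- c(
    pdb_line("ATOM", 1, "CA", "B", "ALA", "A", 1, 7, 7, 7, occ = 0.5),
    pdb_line("ATOM", 2, "CA", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.5),
    "END")
  st <- parse_pdb(tie)
  expect_equal(st$atoms$alt, "B") # file order breaks the tie
})

test_that("malformed coordinates and empty structures are rejected with context", {
  bad <- pdb_line("ATOM", 1, "CA", "", "ALA", "A", 1, 1, 2, 3)
  substr(bad, 31, 38) <- "   xx.yy"
  expect_error(parse_pdb(c(bad, "END")), "line 1")
  expect_error(parse_pdb(c("REMARK nothing here", "END")),
               "no ATOM or HETATM")
})

test_that("parse -> write -> parse round trip preserves atoms and coordinates", {
  sh <- make_hollow_shell(8, 1.5)$structure
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  write_pdb(sh, f)
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(sh$atoms))
  expect_equal(back$atoms$name, sh$atoms$name)
  expect_equal(back$atoms$element, sh$atoms$element)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(sh$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("atom selection filters by attribute and expression, preserving order", {
  site <- make_metal_site()
  cu <- select_atoms(site, element = "CU")
  expect_equal(nrow(cu$atoms), 2)
  his_n <- select_atoms(site,
                        expr = ~ name %in% c("ND1", "NE2") & resid == "HIS")
  expect_equal(nrow(his_n$atoms), 6)
  expect_equal(his_n$atoms$serial, sort(his_n$atoms$serial))
  # residue-range selection
  rng <- select_atoms(site, resno = 10:15)
  expect_true(all(rng$atoms$resno %in% 10:15))
  # empty selection allowed; bad expression rejected
  expect_equal(nrow(select_atoms(site, chain = "Z")$atoms), 0)
  expect_error(select_atoms(site, expr = ~ nonexistent_column > 1),
               "invalid selection")
})

test_that("trajectories reject mismatched atom identity sequences", {
  sh1 <- make_hollow_shell(8, 1.5, id = "a")$structure
  sh2 <- sh1
  expect_s3_class(as_trajectory(list(sh1, sh2), c(0, 100)),
                  "tyr_trajectory")
  sh3 <- sh1
  sh3$atoms$name[1] <- "N"
  expect_error(as_trajectory(list(sh1, sh3), c(0, 100)),
               "identity sequence")
  expect_error(as_trajectory(list(sh1, sh2), c(100, 0)),
               "strictly increasing")
})

test_that("TSV writing round trips records and handles empty tables", {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  tab <- data.frame(mutation = c("W39R", "R77G"), ddg = c(1.2, 5.7),
                    stringsAsFactors = FALSE)
  write_table(tab, f)
  expect_equal(read_table(f), tab)
  empty <- tab[0, ]
  write_table(empty, f)
  expect_equal(nrow(read_table(f)), 0)
  expect_equal(names(read_table(f)), names(tab))
})
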