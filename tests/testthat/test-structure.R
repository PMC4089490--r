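test_that("write/read round-trip preserves identifiers and 3-decimal coordinates", {
  s <- make_closed_bundle(bundle_spec("closed", central = "R", seed = 3))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  r <- read_structure(path)
  expect_equal(nrow(r$atoms), nrow(s$atoms))
  expect_identical(r$atoms$chain, s$atoms$chain)
  expect_identical(r$atoms$resno, s$atoms$resno)
  expect_identical(r$atoms$resid, s$atoms$resid)
  expect_identical(r$atoms$elety, s$atoms$elety)
  for (cc in c("x", "y", "z")) {
    expect_lt(max(abs(r$atoms[[cc]] - s$atoms[[cc]])), 5.01e-4)
  }
})

test_that("a long synthetic chain writes the expected number of residues in order", {
  h <- make_ideal_helix(100)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, path)
  r <- read_structure(path)
  res <- chain_residues(r, "A")
  expect_equal(nrow(res), 100)
  expect_identical(res$resno, 1:100)
})

test_that("altloc policy retains exactly one conformer and drops waters", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(altloc_pdb_lines, path)
  hi <- read_structure(path, altloc_policy = "highest_occupancy")
  expect_equal(nrow(hi$atoms), 4)
  ca <- hi$atoms[hi$atoms$elety == "CA", ]
  expect_equal(ca$occ, 0.6)
  expect_equal(ca$x, 1.4)
  first <- read_structure(path, altloc_policy = "first")
  expect_equal(first$atoms$x[first$atoms$elety == "CA"], 1.4)
  # waters never survive, even with keep_het
  het <- read_structure(path, keep_het = TRUE)
  expect_false(any(toupper(het$atoms$resid) == "HOH"))
})

test_that("atom counts are conserved when no altlocs are present", {
  h <- make_ideal_helix(15)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, path)
  expect_equal(nrow(read_structure(path, altloc_policy = "first")$atoms),
               nrow(read_structure(path, altloc_policy = "highest_occupancy")$atoms))
})

test_that("sequence extraction returns the threaded sequence with a bijective map", {
  seq_in <- "MSEEDFKLWR"
  h <- make_ideal_helix(10, sequence = seq_in, start_res = 5)
  out <- extract_sequence(h, "A")
  expect_identical(out$sequence, seq_in)
  expect_identical(out$map$resno, 5:14)
  expect_identical(out$map$position, 1:10)
  # switching and relay landmarks of the default bundle sequence
  cb <- make_closed_bundle(bundle_spec("closed"))
  sq <- extract_sequence(cb, "A")
  at <- function(no) substr(sq$sequence, match(no, sq$map$resno),
                            match(no, sq$map$resno))
  expect_identical(at(72), "W")
  expect_identical(at(76), "L")
  expect_identical(at(87), "L")
  expect_identical(at(26), "E")
  expect_error(extract_sequence(h, "Z"), "no such chain")
})

test_that("nonstandard residues map to X through the fixed 20-entry table", {
  expect_identical(aa_three_to_one(c("TRP", "MSE", "leu")), c("W", "X", "L"))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  MSE A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_identical(extract_sequence(s, "A")$sequence, "AX")
})

test_that("radius assignment is total and unknown elements raise", {
  expect_equal(vdw_radius(c("C", "N", "O", "S")), c(1.70, 1.55, 1.52, 1.80))
  expect_error(vdw_radius("FE"), "no van der Waals radius")
  expect_error(new_structure(data.frame(
    elety = "FE", resid = "HEM", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, element = "FE")), "FE")
  s <- make_ideal_helix(10)
  expect_true(all(s$atoms$radius > 0))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(read_structure(tempfile()), "not found")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  expect_error(read_structure(path), "empty structure|no protein atoms|zero")
  h <- make_ideal_helix(5)
  h$atoms$resno <- h$atoms$resno + 10000
  expect_error(write_structure(h, tempfile(fileext = ".pdb")), "residue numbers")
  expect_error(new_structure(data.frame(
    elety = character(), resid = character(), chain = character(),
    resno = integer(), x = numeric(), y = numeric(), z = numeric())),
    "empty structure")
})

test_that("atom selection is deterministic and supports empty results", {
  s <- make_closed_bundle(bundle_spec("closed"))
  sel1 <- select_atoms(s, chains = "A", resno = 70:96, part = "sidechain")
  sel2 <- select_atoms(s, chains = "A", resno = 70:96, part = "sidechain")
  expect_identical(sel1, sel2)
  expect_length(select_atoms(s, chains = "Z"), 0)
  bb <- select_atoms(s, part = "backbone")
  sc <- select_atoms(s, part = "sidechain")
  expect_equal(sort(c(bb, sc)), seq_len(nrow(s$atoms)))
  expect_true(all(s$atoms$elety[bb] %in% c("N", "CA", "C", "O", "OXT")))
})
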