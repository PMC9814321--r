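test_that("PDB write/read round trip preserves names, ids and coordinates", {
  dup <- build_duplex(build_spec("GCAGCAGC", c("threoninol_L", "ribose")))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(dup, f)
  st <- read_structure(f)
  expect_named(st$chains, c("A", "B"))
  for (ch in c("A", "B")) {
    expect_length(st$chains[[ch]]$residues, 8)
    for (k in seq_len(8)) {
      r0 <- dup$chains[[ch]]$residues[[k]]
      r1 <- st$chains[[ch]]$residues[[k]]
      expect_identical(r1$seq_id, r0$seq_id)
      expect_identical(r1$base, r0$base)
      expect_setequal(r1$atoms$name, r0$atoms$name)
      m <- merge(r0$atoms, r1$atoms, by = "name")
      expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y),
                    abs(m$z.x - m$z.y)), 1e-3 + 1e-8)
    }
  }
  ## chemistry re-identified from atom names, not component codes
  expect_identical(st$chains$A$residues[[1]]$chemistry, "threoninol_L")
  expect_identical(st$chains$B$residues[[1]]$chemistry, "ribose")
})

test_that("mmCIF atom_site records parse with prime normalization", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(mmcif_fixture_lines("G"), f)
  st <- read_structure(f)
  expect_length(st$chains, 1)
  res <- st$chains$A$residues[[1]]
  expect_identical(res$base, "G")
  expect_true("C1'" %in% res$atoms$name)
  expect_identical(nrow(res$atoms),
                   nrow(standard_base_library()$G))
})

test_that("a file with no nucleic residues warns and yields empty chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 101      10.000  10.000  10.000  1.00 10.00           O",
    "END"), f)
  expect_warning(st <- read_structure(f), "no nucleic residues")
  expect_length(st$chains, 0)
  expect_identical(nrow(st$waters), 1L)
})

test_that("unreadable input raises a parse/file error", {
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("alt-loc policy keeps highest occupancy, ties alphabetical", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ## one G with two N9 conformers (B higher occupancy) and two C8
  ## conformers at equal occupancy (A should win)
  writeLines(c(
    "ATOM      1  N9 AG   A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N9 BG   A   1       1.000   0.000   0.000  0.60 10.00           N",
    "ATOM      3  C8 AG   A   1       2.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  C8 BG   A   1       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      5  N7  G   A   1       2.500   1.000   0.000  1.00 10.00           N",
    "END"), f)
  st <- read_structure(f)
  a <- st$chains$A$residues[[1]]$atoms
  expect_identical(nrow(a), 3L)
  expect_equal(a$x[a$name == "N9"], 1.0)   # occupancy 0.60 conformer
  expect_equal(a$x[a$name == "C8"], 2.0)   # alphabetical tie-break
})

test_that("chain breaks are flagged when the bridging linkage is too long", {
  dup <- build_duplex(build_spec("GCGC", "ribose"))
  f <- withr::local_tempfile(fileext = ".pdb")
  ## displace the second half of chain A far away
  for (k in 3:4) {
    a <- dup$chains$A$residues[[k]]$atoms
    a$z <- a$z + 30
    dup$chains$A$residues[[k]]$atoms <- a
  }
  write_structure(dup, f)
  st <- read_structure(f)
  expect_true(2L %in% st$chains$A$breaks)
})

test_that("chemistry classification follows defining atom sets", {
  dict <- default_chemistry_dictionary()
  rib <- residue_from_matrix(monomer_template("G", "ribose"))
  expect_identical(classify_chemistry(rib, dict), "ribose")
  tna <- residue_from_matrix(monomer_template("A", "threoninol_L"),
                             chemistry = "unknown")
  expect_identical(classify_chemistry(tna, dict), "threoninol_L")
  sna <- residue_from_matrix(monomer_template("C", "serinol"),
                             chemistry = "unknown")
  expect_identical(classify_chemistry(sna, dict), "serinol")
  ## too little information -> unknown
  m <- rbind(P = c(0, 0, 0), OP1 = c(1.5, 0, 0), OP2 = c(0, 1.5, 0))
  expect_identical(classify_chemistry(residue_from_matrix(m), dict),
                   "unknown")
})

test_that("chemistry classification is invariant to atom order", {
  dict <- default_chemistry_dictionary()
  m <- monomer_template("A", "threoninol_L")
  set.seed(7)
  for (k in 1:5) {
    perm <- m[sample(nrow(m)), , drop = FALSE]
    expect_identical(classify_chemistry(residue_from_matrix(perm), dict),
                     "threoninol_L")
  }
})

test_that("select_region restricts residues and records provenance", {
  dup <- build_duplex(build_spec("GCAGCAGC", "ribose"))
  full <- select_region(dup, c("A", "B"), c(1, 8))
  expect_length(full$chains$A$residues, 8)
  sub <- select_region(dup, c("A", "B"), c(1, 6))
  expect_length(sub$chains$A$residues, 6)
  expect_identical(sub$metadata$provenance$windows[[1]], c(1, 6))
  expect_error(select_region(dup, c("A", "Z"), c(1, 6)), "chain")
  expect_error(select_region(dup, c("A", "B"), c(40, 50)), "range")
})

test_that("atom counts sum non-water atoms per chain", {
  dup <- build_duplex(build_spec("GC", "ribose"))
  counts <- atom_counts(dup)
  expect_identical(unname(counts["A"]),
                   sum(vapply(dup$chains$A$residues,
                              function(r) nrow(r$atoms), integer(1))))
})

test_that("chemistry dictionary survives the YAML config round trip", {
  dict <- default_chemistry_dictionary()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_chemistry_dictionary(dict, f)
  back <- read_chemistry_dictionary(f)
  expect_identical(names(back$chemistries), names(dict$chemistries))
  expect_identical(back$chemistries$ribose$torsions$alpha,
                   dict$chemistries$ribose$torsions$alpha)
  expect_identical(back$chemistries$serinol$amide,
                   dict$chemistries$serinol$amide)
  rib <- residue_from_matrix(monomer_template("G", "ribose"))
  expect_identical(classify_chemistry(rib, back), "ribose")
})
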