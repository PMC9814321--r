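test_that("dihedral matches constructions and an independent formula", {
  ## planar trans and cis
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               180)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               0)
  ## independent oracle: project outer bonds onto the plane perpendicular
  ## to the central bond, then take the signed angle
  oracle <- function(p1, p2, p3, p4) {
    b <- (p3 - p2); b <- b / sqrt(sum(b^2))
    u <- (p1 - p2) - sum((p1 - p2) * b) * b
    v <- (p4 - p3) - sum((p4 - p3) * b) * b
    s <- sum(xnahelix:::cross3(u, v) * b)
    xnahelix:::rad2deg(atan2(s, sum(u * v)))
  }
  set.seed(51)
  for (k in 1:50) {
    p <- lapply(1:4, function(i) rnorm(3))
    expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                 oracle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-10)
  }
})

test_that("dihedral symmetry, mirror and rigid-motion properties", {
  set.seed(53)
  for (k in 1:25) {
    p <- lapply(1:4, function(i) rnorm(3))
    d <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    ## order reversal preserves the value
    expect_equal(dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d,
                 tolerance = 1e-10)
    ## mirror reflection flips the sign
    m <- lapply(p, function(v) c(-v[1], v[2], v[3]))
    expect_equal(dihedral(m[[1]], m[[2]], m[[3]], m[[4]]), -d,
                 tolerance = 1e-10)
    ## rigid motion leaves it unchanged
    R <- random_rotation(); t <- rnorm(3, 0, 10)
    q <- lapply(p, function(v) as.numeric(R %*% v + t))
    expect_equal(dihedral(q[[1]], q[[2]], q[[3]], q[[4]]), d,
                 tolerance = 1e-10)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("torsion profile evaluates constructed quadruples", {
  ## ribonucleotide-like fragment with delta built at exactly 80 degrees
  c5 <- c(0, 0, 0); c4 <- c(1.5, 0, 0)
  c3 <- xnahelix:::place_atom(c(0, 1, 0), c5, c4, 1.53, 102, -60)
  o3 <- xnahelix:::place_atom(c5, c4, c3, 1.42, 110, 80)
  m <- rbind(`C5'` = c5, `C4'` = c4, `C3'` = c3, `O3'` = o3)
  res <- residue_from_matrix(m, "A", 1, "G", "ribose")
  chain <- xnahelix:::new_chain("A", list(res))
  prof <- torsion_profile(chain)
  expect_equal(prof$delta, 80, tolerance = 1e-8)
  expect_true(is.na(prof$alpha))   # needs the previous residue
})

test_that("torsions spanning a flagged chain break are undefined", {
  dup <- build_duplex(build_spec("GCGC", "ribose"))
  ch <- dup$chains$B
  prof0 <- torsion_profile(ch)
  expect_true(all(is.finite(prof0$alpha[-1])))
  ch$breaks <- 2L
  prof <- torsion_profile(ch)
  expect_true(is.na(prof$alpha[3]))      # alpha reaches back across break
  expect_true(is.na(prof$epsilon[2]))    # epsilon reaches forward
  expect_true(is.finite(prof$delta[2]))  # intra-residue angles unaffected
})

test_that("pseudorotation inverts exactly over the full wheel", {
  for (P in seq(0, 342, by = 18)) {
    pk <- pucker_from_torsions(torsions_from_pucker(P, 38))
    dphi <- ((pk$phase - P + 180) %% 360) - 180
    expect_lt(abs(dphi), 1e-6)
    expect_equal(pk$amplitude, 38, tolerance = 1e-6)
  }
  ## named bins at the conformer examples
  pk342 <- pucker_from_torsions(torsions_from_pucker(342, 38))
  expect_identical(pk342$conformer, "C2'-exo")
  expect_identical(pk342$hemisphere, "Northern")
  pk18 <- pucker_from_torsions(torsions_from_pucker(18, 38))
  expect_identical(pk18$conformer, "C3'-endo")
  expect_identical(pk18$hemisphere, "Northern")
  pk162 <- pucker_from_torsions(torsions_from_pucker(162, 38))
  expect_identical(pk162$conformer, "C2'-endo")
  expect_identical(pk162$hemisphere, "Southern")
})

test_that("sugar pucker of built ribose templates lands in the target bin", {
  rib <- residue_from_matrix(monomer_template("G", "ribose"))
  pk <- sugar_pucker(rib)
  expect_identical(pk$conformer, "C3'-endo")
  expect_identical(pk$hemisphere, "Northern")
  expect_equal(pk$phase, 18, tolerance = 1)
  ## C2'-exo target: Northern hemisphere but a different bin
  tpl <- xnahelix:::monomer_template("G", "ribose", pucker_phase = 342)
  pk2 <- sugar_pucker(residue_from_matrix(tpl))
  expect_identical(pk2$conformer, "C2'-exo")
  expect_identical(pk2$hemisphere, "Northern")
})

test_that("amide configuration classifies cis and trans", {
  mk <- function(omega) {
    c6 <- c(0, 0, 0); c5 <- c(1.52, 0, 0)
    n4 <- xnahelix:::place_atom(c(0, 1, 0), c6, c5, 1.33, 115, 10)
    c2 <- xnahelix:::place_atom(c6, c5, n4, 1.45, 122, omega)
    residue_from_matrix(rbind(`C6'` = c6, `C5'` = c5, `N4'` = n4,
                              `C2'` = c2),
                        base = "G", chemistry = "serinol")
  }
  expect_identical(amide_configuration(mk(180))$config, "trans")
  expect_equal(amide_configuration(mk(180))$omega, 180, tolerance = 1e-8)
  expect_identical(amide_configuration(mk(0))$config, "cis")
  ## non-XNA residue: not applicable
  rib <- residue_from_matrix(monomer_template("G", "ribose"))
  expect_identical(amide_configuration(rib)$config, "not_applicable")
})

test_that("built acyclic strands are trans at every amide", {
  for (chem in c("serinol", "threoninol_L")) {
    dup <- build_duplex(build_spec("GCAGC", c(chem, "ribose")))
    for (r in dup$chains$A$residues) {
      am <- amide_configuration(r)
      expect_identical(am$config, "trans")
      expect_equal(abs(am$omega), 180, tolerance = 1e-6)
    }
  }
})

test_that("sequential P-P distances and windowed means", {
  m1 <- rbind(P = c(0, 0, 0), `C1'` = c(1, 0, 0))
  m2 <- rbind(P = c(0, 0, 6), `C1'` = c(1, 0, 6))
  ch <- xnahelix:::new_chain("A", list(
    residue_from_matrix(m1, "A", 1), residue_from_matrix(m2, "A", 2)))
  pp <- pp_distances(ch)
  expect_equal(pp$per_step$distance, 6.0)
  expect_equal(pp$mean, 6.0)
  ## windowed on a built duplex: mean over in-window steps only
  dup <- build_duplex(build_spec("GCAGCAGC", "ribose"))
  full <- pp_distances(dup$chains$A)
  win <- pp_distances(dup$chains$A, window = c(2, 5))
  expect_identical(nrow(win$per_step), 3L)
  expect_equal(win$mean, mean(full$per_step$distance[2:4]),
               tolerance = 1e-10)
})

test_that("torsion summaries use circular statistics and report N", {
  prof <- data.frame(seq_id = 1:3, alpha = c(179, -179, NA), beta = NA,
                     gamma = NA, delta = NA, epsilon = NA, zeta = NA,
                     chi = NA, amide_omega = NA,
                     pp_distance = c(5.9, 6.1, NA))
  s <- torsion_summary(prof)
  expect_equal(abs(s$mean[s$quantity == "alpha"]), 180)
  expect_identical(s$n[s$quantity == "alpha"], 2L)
  expect_equal(s$mean[s$quantity == "pp_distance"], 6.0)
})
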