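test_that("superpose recovers exact and constructed transforms", {
  set.seed(11)
  pts <- matrix(rnorm(18), 6, 3)
  id <- superpose(pts, pts)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)

  R <- xnahelix:::rot_z(30); t <- c(1, 2, 3)
  moved <- sweep(pts %*% t(R), 2, t, "+")
  fit <- superpose(pts, moved)
  expect_equal(fit$rotation, R, tolerance = 1e-10)
  expect_equal(fit$translation, t, tolerance = 1e-10)
  expect_lt(fit$rmsd, 1e-10)
})

test_that("superpose rmsd matches direct evaluation and bio3d on noisy data", {
  set.seed(21)
  pts <- matrix(rnorm(18), 6, 3)
  noisy <- sweep(pts %*% t(xnahelix:::rot_z(40)), 2, c(0.5, -1, 2), "+") +
    matrix(rnorm(18, 0, 0.1), 6, 3)
  fit <- superpose(pts, noisy)
  ## independent oracle: apply the returned transform, compute RMS directly
  moved <- sweep(pts %*% t(fit$rotation), 2, fit$translation, "+")
  expect_equal(fit$rmsd, sqrt(mean(rowSums((moved - noisy)^2))),
               tolerance = 1e-12)
  ## independent library cross-check of the attained minimum
  b3d <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(noisy)),
                                         mobile = as.numeric(t(pts))))
  b3d_rmsd <- sqrt(mean(colSums(matrix(b3d - as.numeric(t(noisy)), 3)^2)))
  expect_equal(fit$rmsd, b3d_rmsd, tolerance = 1e-6)
})

test_that("superpose rejects degenerate point sets", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("fit_base_frame recovers identity and constructed transforms", {
  lib <- standard_base_library()
  g <- residue_from_matrix(lib$G)
  fr <- fit_base_frame(g)
  expect_equal(fr$axes, diag(3), tolerance = 1e-8)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-8)
  expect_lt(fr$fit_rmsd, 1e-10)

  R <- xnahelix:::rot_z(36); t <- c(0, 0, 3.4)
  cmat <- sweep(lib$C %*% t(R), 2, t, "+")
  frc <- fit_base_frame(residue_from_matrix(cmat, base = "C"))
  expect_equal(frc$axes, R, tolerance = 1e-8)
  expect_equal(frc$origin, t, tolerance = 1e-8)
})

test_that("fitted frames are orthonormal, right-handed and equivariant", {
  dup <- build_duplex(build_spec("GCAU", "ribose"))
  frames <- fit_frames(dup)
  set.seed(31)
  R <- random_rotation(); t <- rnorm(3, 0, 10)
  moved <- transform_structure(dup, R, t)
  frames2 <- fit_frames(moved)
  for (key in names(frames)) {
    A <- frames[[key]]$axes
    expect_equal(t(A) %*% A, diag(3), tolerance = 1e-8)
    expect_equal(det(A), 1, tolerance = 1e-8)
    ## rigid-motion equivariance
    expect_equal(frames2[[key]]$axes, R %*% A, tolerance = 1e-8)
    expect_equal(frames2[[key]]$origin,
                 as.numeric(R %*% frames[[key]]$origin + t),
                 tolerance = 1e-8)
  }
})

test_that("builder frames are recovered by frame fitting", {
  spec <- build_spec("GCAGCA", "ribose",
                     helical = list(helical_twist = 22.7,
                                    helical_rise = 3.13,
                                    x_displacement = -6.4))
  dup <- build_duplex(spec)
  frames <- fit_frames(dup)
  built <- xnahelix:::helical_frames(6, 22.7, 3.13, x_displacement = -6.4)
  for (k in 2:5) {
    fr <- frames[[paste0("A:", k)]]
    expect_equal(fr$axes, built[[k]]$axes, tolerance = 1e-6)
    expect_equal(fr$origin, built[[k]]$origin, tolerance = 1e-6)
    ## strand II frame equals the pair frame with y/z flipped
    fb <- frames[[paste0("B:", k)]]
    expect_equal(fb$axes %*% diag(c(1, -1, -1)), built[[k]]$axes,
                 tolerance = 1e-6)
  }
})

test_that("detect_pairs finds designed Watson-Crick pairs and no others", {
  spec <- build_spec("GCGCAUGC", "ribose")
  dup <- build_duplex(spec)
  pairs <- detect_pairs(dup)
  expect_identical(nrow(pairs), 8L)
  expect_true(all(pairs$pair_class == "watson_crick"))
  expect_true(all(pairs$orientation == "antiparallel"))
  ## symmetric reporting: each pair appears exactly once
  expect_identical(anyDuplicated(paste(pairs$chain_i, pairs$seq_i)), 0L)
  ## designed partner mapping
  expect_identical(pairs$seq_j, pairs$seq_i)
  ## G:C pairs carry 3 bonds, A:U pairs 2
  expect_identical(pairs$n_hbonds[pairs$base_i %in% c("G", "C")],
                   rep(3L, 6))
  expect_identical(pairs$n_hbonds[pairs$base_i %in% c("A", "U")],
                   rep(2L, 2))
})

test_that("Hoogsteen G*G edge pairing is classified as hoogsteen", {
  st <- hoogsteen_gg_structure()
  pairs <- detect_pairs(st)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$pair_class, "hoogsteen")
  hb <- attr(pairs, "hbonds")
  expect_setequal(hb$acceptor_atom, c("O6", "N7"))
  expect_equal(hb$distance, c(2.9, 2.9), tolerance = 1e-4)
})

test_that("distant bases yield no pairs", {
  G <- standard_base_library()$G
  far <- sweep(G, 2, c(20, 0, 0), "+")
  st <- structure_from_residues(residue_from_matrix(G, "A", 1),
                                residue_from_matrix(far, "B", 1, "C"))
  expect_identical(nrow(detect_pairs(st)), 0L)
})

test_that("orientation classification distinguishes parallel strands", {
  dup <- build_duplex(build_spec("GCGC", "ribose"))
  ## duplicate chain A translated sideways: identical backbone direction
  shifted <- lapply(dup$chains$A$residues, function(r) {
    r$chain_id <- "C"
    r$atoms$x <- r$atoms$x + 30
    r
  })
  st <- dup
  st$chains$C <- xnahelix:::new_chain("C", shifted, "5'->3'")
  pr <- data.frame(chain_i = "A", seq_i = 2L, chain_j = "C", seq_j = 2L)
  expect_identical(classify_orientation(pr, st), "parallel")
  pr2 <- data.frame(chain_i = "A", seq_i = 2L, chain_j = "B", seq_j = 2L)
  expect_identical(classify_orientation(pr2, st), "antiparallel")
})
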