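test_that("pair_frame averages and re-orthonormalizes", {
  R <- xnahelix:::rot_z(25)
  f1 <- xnahelix:::new_base_frame(c(1, 2, 3), R, 0)
  ## a strand-II frame whose flipped axes equal f1's: pair frame = f1
  f2 <- xnahelix:::new_base_frame(c(1, 2, 3), R %*% diag(c(1, -1, -1)), 0)
  pf <- pair_frame(f1, f2)
  expect_equal(pf$axes, R, tolerance = 1e-10)
  expect_equal(pf$origin, c(1, 2, 3), tolerance = 1e-10)

  ## frames symmetric about the xz-plane-in-frame: mid-frame bisects
  fA <- xnahelix:::new_base_frame(c(0, 0, 0), xnahelix:::rot_x(10), 0)
  fB <- xnahelix:::new_base_frame(
    c(0, 0, 0), xnahelix:::rot_x(-10) %*% diag(c(1, -1, -1)), 0)
  mid <- pair_frame(fA, fB)
  expect_equal(mid$axes, diag(3), tolerance = 1e-10)
})

test_that("pure screw about frame z gives clean helical parameters", {
  f1 <- xnahelix:::new_base_frame(c(0, 0, 0), diag(3), 0)
  f2 <- xnahelix:::new_base_frame(c(0, 0, 3.4), xnahelix:::rot_z(36), 0)
  sp <- step_parameters(f1, f2)
  expect_equal(sp$helical_twist, 36, tolerance = 1e-8)
  expect_equal(sp$helical_rise, 3.4, tolerance = 1e-8)
  expect_equal(sp$twist, 36, tolerance = 1e-8)
  expect_equal(sp$rise, 3.4, tolerance = 1e-8)
  expect_equal(sp$inclination, 0, tolerance = 1e-8)
  expect_equal(sp$tip, 0, tolerance = 1e-8)
  expect_equal(sp$x_displacement, 0, tolerance = 1e-8)
  expect_equal(sp$y_displacement, 0, tolerance = 1e-8)
})

test_that("identical frames fall back to the degenerate-screw rule", {
  f <- xnahelix:::new_base_frame(c(1, 1, 1), xnahelix:::rot_y(12), 0)
  sp <- step_parameters(f, f)
  for (p in c("shift", "slide", "rise", "tilt", "roll", "twist",
              "helical_twist", "helical_rise"))
    expect_equal(sp[[p]], 0, tolerance = 1e-10)
})

test_that("step parameters satisfy the reconstruction oracle", {
  ## oracle: rebuild frame_j from frame_i through the independent
  ## builder-side composition of the returned parameters
  set.seed(41)
  worst <- 0
  for (k in 1:1000) {
    R1 <- random_rotation(); o1 <- rnorm(3, 0, 8)
    R2 <- random_rotation(); o2 <- o1 + rnorm(3, 0, 4)
    sp <- step_parameters(xnahelix:::new_base_frame(o1, R1, 0),
                          xnahelix:::new_base_frame(o2, R2, 0))
    re <- xnahelix:::compose_step(R1, o1, sp$shift, sp$slide, sp$rise,
                                  sp$tilt, sp$roll, sp$twist)
    worst <- max(worst, max(abs(re$R - R2)), max(abs(re$o - o2)))
  }
  expect_lt(worst, 1e-8)
})

test_that("step parameters are invariant under a common rigid motion", {
  set.seed(43)
  for (k in 1:25) {
    R1 <- random_rotation(); o1 <- rnorm(3, 0, 5)
    R2 <- random_rotation(); o2 <- o1 + rnorm(3, 0, 3)
    M <- random_rotation(); t <- rnorm(3, 0, 20)
    a <- step_parameters(xnahelix:::new_base_frame(o1, R1, 0),
                         xnahelix:::new_base_frame(o2, R2, 0))
    b <- step_parameters(
      xnahelix:::new_base_frame(as.numeric(M %*% o1 + t), M %*% R1, 0),
      xnahelix:::new_base_frame(as.numeric(M %*% o2 + t), M %*% R2, 0))
    for (p in c("shift", "slide", "rise", "tilt", "roll", "twist",
                "x_displacement", "y_displacement", "inclination", "tip",
                "helical_rise", "helical_twist"))
      expect_equal(b[[p]], a[[p]], tolerance = 1e-8)
  }
})

test_that("helix summary arithmetic and identities", {
  steps <- data.frame(step = 1, shift = 0, slide = 0, rise = 3,
                      tilt = 0, roll = 0, twist = 30,
                      x_displacement = 0, y_displacement = 0,
                      inclination = 0, tip = 0, helical_rise = 3.0,
                      helical_twist = 30)
  s <- summarize_helix(steps)
  expect_equal(s$residues_per_turn, 12.0)
  expect_equal(s$helical_pitch, 36.0)
  ## identity holds exactly before rounding
  expect_equal(s$helical_pitch,
               s$mean[["helical_rise"]] * 360 / s$mean[["helical_twist"]])
  expect_error(summarize_helix(steps[0, ]), "empty")
})

test_that("angle averaging is circular across the +-180 seam", {
  expect_equal(abs(xnahelix:::circular_mean(c(179, -179))), 180)
  expect_lt(xnahelix:::circular_sd(c(179, -179)), 2)
  steps <- data.frame(step = 1:2, shift = 0, slide = 0, rise = 3,
                      tilt = 0, roll = 0, twist = c(179, -179),
                      x_displacement = 0, y_displacement = 0,
                      inclination = 0, tip = 0, helical_rise = 3,
                      helical_twist = c(179, -179))
  s <- summarize_helix(steps)
  expect_equal(abs(s$mean[["helical_twist"]]), 180, tolerance = 1e-10)
})

test_that("minor groove widths follow the closest P-P convention", {
  mkP <- function(chain, seq, x, y = 0, z = 0)
    residue_from_matrix(rbind(P = c(x, y, z), `O5'` = c(x + 1, y, z),
                              `C5'` = c(x + 1, y + 1, z)),
                        chain, seq, "G", "ribose")
  st <- structure_from_residues(mkP("A", 1, 0), mkP("B", 1, 5.8))
  g <- minor_groove_width(st, c("A", "B"))
  expect_equal(g$width, 0, tolerance = 1e-10)

  ## interstrand distances {14.0, 15.3, 16.1}: minimum-based width 8.2
  st2 <- structure_from_residues(
    mkP("A", 1, 0), mkP("A", 2, 0, 40), mkP("A", 3, 0, 80),
    mkP("B", 1, 14.0), mkP("B", 2, 15.3, 40), mkP("B", 3, 16.1, 80))
  g2 <- minor_groove_width(st2, c("A", "B"))
  ## brute-force oracle over all interstrand pairs
  pa <- rbind(c(0, 0, 0), c(0, 40, 0), c(0, 80, 0))
  pb <- rbind(c(14, 0, 0), c(15.3, 40, 0), c(16.1, 80, 0))
  brute <- min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                    outer(pa[, 2], pb[, 2], "-")^2 +
                    outer(pa[, 3], pb[, 3], "-")^2))
  expect_equal(g2$width, brute - 5.8, tolerance = 1e-10)
  expect_equal(g2$width, 8.2, tolerance = 1e-10)
  expect_equal(g2$per_position$width, c(14.0, 15.3, 16.1) - 5.8,
               tolerance = 1e-10)

  ## strand without phosphates: undefined, flagged
  noP <- residue_from_matrix(standard_base_library()$G, "C", 1)
  st3 <- structure_from_residues(mkP("A", 1, 0), noP)
  g3 <- minor_groove_width(st3, c("A", "C"))
  expect_true(g3$undefined)
  expect_true(is.na(g3$width))
})
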