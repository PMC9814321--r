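#' @keywords internal
"_PACKAGE"

## Small geometry kernel shared across modules.  All vectors are length-3
## numerics, all rotation matrices 3x3 with columns = frame axes.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Map an angle in degrees onto (-180, 180].
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

## Rodrigues rotation about unit axis u by theta degrees.
rotation_about <- function(u, theta_deg) {
  u <- unitv(u)
  th <- deg2rad(theta_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rot_x <- function(theta) rotation_about(c(1, 0, 0), theta)
rot_y <- function(theta) rotation_about(c(0, 1, 0), theta)
rot_z <- function(theta) rotation_about(c(0, 0, 1), theta)

## Signed angle (degrees) from a to b about axis u; all in the plane
## perpendicular to u (components along u are projected out).
signed_angle_about <- function(a, b, u) {
  u <- unitv(u)
  a <- a - sum(a * u) * u
  b <- b - sum(b * u) * u
  rad2deg(atan2(sum(cross3(a, b) * u), sum(a * b)))
}

## Rotation angle (degrees) and unit axis of a proper rotation matrix.
## For near-identity rotations the axis is undefined and NA is returned.
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cth <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cth)
  if (theta < 1e-9) {
    return(list(angle = 0, axis = c(NA_real_, NA_real_, NA_real_)))
  }
  if (abs(theta - pi) < 1e-6) {
    ## axis from the dominant column of R + I
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    ax <- unitv(M[, j])
    return(list(angle = 180, axis = ax))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  list(angle = rad2deg(theta), axis = unitv(ax))
}

## Nearest proper rotation to an arbitrary 3x3 matrix (SVD projection).
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

## Circular mean and SD (degrees) of angles in degrees.  The SD is the
## circular standard deviation sqrt(-2 log Rbar) mapped to degrees; this is
## the appropriate spread measure for torsions/twists near the +-180 seam.
circular_mean <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  r <- deg2rad(x)
  wrap180(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

circular_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  r <- deg2rad(x)
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(1, rbar)
  rad2deg(sqrt(-2 * log(max(rbar, 1e-12))))
}

## NeRF-style internal-coordinate placement: position atom D given atoms
## A, B, C, the C-D bond length (Angstrom), the B-C-D angle and the
## A-B-C-D torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang <- deg2rad(180 - angle)
  tor <- deg2rad(torsion)
  d_local <- bond * c(cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  ## frame columns: bc, m, n
  as.numeric(c + cbind(bc, m, n) %*% d_local)
}
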