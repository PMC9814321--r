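## Idealized base geometries in the standard nucleic acid reference frame
## (origin at the pair center, x toward the major groove, y along the
## pseudo-dyad toward the strand-I backbone, z along the helix advance for
## strand I; all base atoms lie in the z = 0 plane).  Coordinates follow
## the published standard reference frame convention used by the common
## helix-analysis programs.

.STD_BASE <- list(
  A = rbind(
    `C1'` = c(-2.479, 5.346, 0.000),
    N9 = c(-1.291, 4.498, 0.000),
    C8 = c(0.024, 4.897, 0.000),
    N7 = c(0.877, 3.902, 0.000),
    C5 = c(0.071, 2.771, 0.000),
    C6 = c(0.369, 1.398, 0.000),
    N6 = c(1.611, 0.909, 0.000),
    N1 = c(-0.668, 0.532, 0.000),
    C2 = c(-1.912, 1.023, 0.000),
    N3 = c(-2.320, 2.290, 0.000),
    C4 = c(-1.267, 3.124, 0.000)
  ),
  G = rbind(
    `C1'` = c(-2.477, 5.399, 0.000),
    N9 = c(-1.289, 4.551, 0.000),
    C8 = c(0.023, 4.962, 0.000),
    N7 = c(0.870, 3.969, 0.000),
    C5 = c(0.071, 2.833, 0.000),
    C6 = c(0.424, 1.460, 0.000),
    O6 = c(1.554, 0.955, 0.000),
    N1 = c(-0.700, 0.641, 0.000),
    C2 = c(-1.999, 1.087, 0.000),
    N2 = c(-2.949, 0.139, -0.001),
    N3 = c(-2.342, 2.364, 0.001),
    C4 = c(-1.265, 3.177, 0.000)
  ),
  C = rbind(
    `C1'` = c(-2.477, 5.402, 0.000),
    N1 = c(-1.285, 4.542, 0.000),
    C2 = c(-1.472, 3.158, 0.000),
    O2 = c(-2.628, 2.709, 0.001),
    N3 = c(-0.391, 2.344, 0.000),
    C4 = c(0.837, 2.868, 0.000),
    N4 = c(1.875, 2.027, 0.001),
    C5 = c(1.056, 4.275, 0.000),
    C6 = c(-0.023, 5.068, 0.000)
  ),
  U = rbind(
    `C1'` = c(-2.481, 5.354, 0.000),
    N1 = c(-1.284, 4.500, 0.000),
    C2 = c(-1.462, 3.131, 0.000),
    O2 = c(-2.563, 2.608, 0.000),
    N3 = c(-0.302, 2.397, 0.000),
    C4 = c(0.989, 2.884, 0.000),
    O4 = c(1.935, 2.094, -0.001),
    C5 = c(1.089, 4.311, 0.000),
    C6 = c(-0.024, 5.053, 0.000)
  ),
  T = rbind(
    `C1'` = c(-2.481, 5.354, 0.000),
    N1 = c(-1.284, 4.500, 0.000),
    C2 = c(-1.462, 3.135, 0.000),
    O2 = c(-2.562, 2.608, 0.000),
    N3 = c(-0.298, 2.407, 0.000),
    C4 = c(0.994, 2.897, 0.000),
    O4 = c(1.944, 2.119, 0.000),
    C5 = c(1.106, 4.338, 0.000),
    C7 = c(2.466, 4.961, 0.001),
    C6 = c(-0.024, 5.057, 0.000)
  )
)

## BrU: uracil geometry with the bromine extending the C5-H direction
## (in-plane, C5-Br 1.89 Angstrom along the C6->C5 exocyclic bisector).
.STD_BASE$BrU <- {
  u <- .STD_BASE$U
  c5 <- u["C5", ]; c4 <- u["C4", ]; c6 <- u["C6", ]
  dir <- c5 - (c4 + c6) / 2
  dir <- dir / sqrt(sum(dir^2))
  rbind(u, BR = c5 + 1.89 * dir)
}

#' Standard base geometry library
#'
#' Idealized planar base-atom coordinates expressed in the standard base
#' reference frame, used both to fit observed base frames
#' ([fit_base_frame()]) and to place bases in the synthetic builder.
#'
#' @return Named list (one matrix per base code, rows = atoms, columns =
#'   x, y, z) of class `standard_base_library`.
#' @export
standard_base_library <- function() {
  structure(.STD_BASE, class = "standard_base_library")
}

## Ring atoms used for frame fitting (exocyclic substituents excluded,
## C1' included to pin the glycosidic direction).
frame_fit_atoms <- function(base) {
  if (is_purine(pairing_base(base))) {
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  } else {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  }
}
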