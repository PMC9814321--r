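## Backbone/glycosidic torsions, sugar pseudorotation, amide configuration
## and sequential P-P distances.

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from p2 towards p3, a clockwise rotation
#' of the far bond relative to the near bond is positive.  Result in
#' degrees on (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b2) < 1e-9) stop("undefined torsion: central atoms coincide")
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: collinear atom triple")
  wrap180(rad2deg(atan2(sum(cross3(n1, n2) * unitv(b2)), sum(n1 * n2))))
}

## Evaluate a torsion quadruple (data.frame name/offset) at residue index i
## of a chain; returns NA when atoms are missing or a chain break is
## spanned.
.quad_torsion <- function(chain, i, quad) {
  n <- length(chain$residues)
  pts <- matrix(NA_real_, 4, 3)
  for (k in 1:4) {
    j <- i + quad$offset[k]
    if (j < 1 || j > n) return(NA_real_)
    if (quad$offset[k] != 0) {
      ## spanning a flagged chain break?
      lo <- min(i, j); hi <- max(i, j)
      if (any(chain$breaks %in% lo:(hi - 1L))) return(NA_real_)
    }
    p <- atom_xyz(chain$residues[[j]], quad$name[k])
    if (anyNA(p)) return(NA_real_)
    pts[k, ] <- p
  }
  tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
           error = function(e) NA_real_)
}

#' Per-residue torsion profile of a chain
#'
#' Computes the chemistry-specific backbone torsions alpha-zeta for every
#' residue, plus chi and sugar pucker for ribose chemistries, the amide
#' omega and cis/trans configuration plus the auxiliary base-attachment
#' dihedral for the acyclic chemistries, and the sequential P-P distance.
#' Torsions spanning a chain break or missing atoms are `NA`.
#'
#' @param chain An `xna_chain`.
#' @param dictionary Chemistry dictionary.
#' @return data.frame, one row per residue.
#' @export
torsion_profile <- function(chain,
                            dictionary = default_chemistry_dictionary()) {
  res <- chain$residues
  rows <- lapply(seq_along(res), function(i) {
    r <- res[[i]]
    entry <- dictionary$chemistries[[r$chemistry]]
    row <- data.frame(chain_id = r$chain_id, seq_id = r$seq_id,
                      base = r$base, chemistry = r$chemistry,
                      alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                      delta = NA_real_, epsilon = NA_real_,
                      zeta = NA_real_, chi = NA_real_,
                      pucker_phase = NA_real_,
                      pucker_amplitude = NA_real_,
                      pucker_conformer = NA_character_,
                      pucker_hemisphere = NA_character_,
                      amide_omega = NA_real_,
                      amide_config = NA_character_,
                      base_attachment = NA_real_,
                      pp_distance = NA_real_,
                      stringsAsFactors = FALSE)
    if (is.null(entry)) return(row)
    for (tor in names(entry$torsions))
      row[[tor]] <- .quad_torsion(chain, i, entry$torsions[[tor]])
    cls <- if (is_purine(pairing_base(r$base))) "purine" else "pyrimidine"
    if (!is.null(entry$chi))
      row$chi <- .quad_torsion(chain, i, entry$chi[[cls]])
    if (!is.null(entry$base_attachment))
      row$base_attachment <- .quad_torsion(chain, i,
                                           entry$base_attachment[[cls]])
    if (!is.null(entry$sugar_ring)) {
      pk <- tryCatch(sugar_pucker(r), error = function(e) NULL)
      if (!is.null(pk) && !is.na(pk$phase)) {
        row$pucker_phase <- pk$phase
        row$pucker_amplitude <- pk$amplitude
        row$pucker_conformer <- pk$conformer
        row$pucker_hemisphere <- pk$hemisphere
      }
    }
    if (!is.null(entry$amide)) {
      am <- tryCatch(amide_configuration(r, dictionary),
                     error = function(e) NULL)
      if (!is.null(am)) {
        row$amide_omega <- am$omega
        row$amide_config <- am$config
      }
    }
    ## sequential P-P distance to the next residue's P
    if (i < length(res)) {
      p1 <- atom_xyz(r, "P"); p2 <- atom_xyz(res[[i + 1L]], "P")
      if (!anyNA(p1) && !anyNA(p2))
        row$pp_distance <- vnorm(as.numeric(p2) - as.numeric(p1))
    }
    row
  })
  do.call(rbind, rows)
}

#' Windowed averages of a torsion profile
#'
#' Circular means/SDs for angles, arithmetic for P-P distances; undefined
#' angles are excluded (not imputed) and the N entering each mean is
#' reported.
#'
#' @param profile data.frame from [torsion_profile()].
#' @param window Optional inclusive `c(lo, hi)` seq-id window.
#' @return data.frame with one row per quantity: mean, sd, n.
#' @export
torsion_summary <- function(profile, window = NULL) {
  if (!is.null(window))
    profile <- profile[profile$seq_id >= window[1] &
                       profile$seq_id <= window[2], , drop = FALSE]
  angles <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi",
              "amide_omega")
  rows <- lapply(angles, function(a) {
    v <- profile[[a]]
    data.frame(quantity = a, mean = circular_mean(v),
               sd = circular_sd(v), n = sum(is.finite(v)),
               stringsAsFactors = FALSE)
  })
  v <- profile$pp_distance
  rows[[length(rows) + 1L]] <- data.frame(
    quantity = "pp_distance", mean = mean(v[is.finite(v)]),
    sd = stats::sd(v[is.finite(v)]), n = sum(is.finite(v)),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

## ---- sugar pseudorotation --------------------------------------------

.CONFORMER_WHEEL <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                      "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                      "C1'-endo", "C2'-exo")

#' Pseudorotation phase and amplitude from five endocyclic torsions
#'
#' Standard tangent formula from the five torsions nu0-nu4 of the furanose
#' ring (nu0: C4'-O4'-C1'-C2', ..., nu2: C1'-C2'-C3'-C4').  The conformer
#' name is the 36-degree envelope bin on the canonical pseudorotation
#' wheel; the hemisphere is the phase quadrant (Northern 315-45, Eastern
#' 45-135, Southern 135-225, Western 225-315 degrees).
#'
#' @param nu Numeric vector of the five torsions nu0..nu4 in degrees.
#' @return List with `phase` (degrees in [0, 360)), `amplitude` (degrees),
#'   `conformer` and `hemisphere`.
#' @export
pucker_from_torsions <- function(nu) {
  stopifnot(length(nu) == 5)
  if (anyNA(nu)) return(list(phase = NA_real_, amplitude = NA_real_,
                             conformer = NA_character_,
                             hemisphere = NA_character_))
  k <- 2 * (sin(deg2rad(36)) + sin(deg2rad(72)))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- k * nu[3]
  phase <- rad2deg(atan2(num, den)) %% 360
  amplitude <- nu[3] / cos(deg2rad(phase))
  if (!is.finite(amplitude) || abs(cos(deg2rad(phase))) < 1e-8) {
    amplitude <- num / (k * sin(deg2rad(phase)))
  }
  conformer <- .CONFORMER_WHEEL[floor((phase %% 360) / 36) + 1L]
  hemisphere <- c("Northern", "Eastern", "Southern",
                  "Western")[floor(((phase + 45) %% 360) / 90) + 1L]
  list(phase = phase, amplitude = abs(amplitude), conformer = conformer,
       hemisphere = hemisphere)
}

#' Inverse pseudorotation: torsions from phase and amplitude
#'
#' @param phase Pseudorotation phase in degrees.
#' @param amplitude Puckering amplitude in degrees.
#' @return Numeric vector nu0..nu4.
#' @export
torsions_from_pucker <- function(phase, amplitude) {
  j <- 0:4
  amplitude * cos(deg2rad(phase + 144 * (j - 2)))
}

#' Sugar pucker of a ribose/deoxyribose residue
#'
#' Computes the five endocyclic torsions from the ring atoms and reports
#' the pseudorotation phase, amplitude, conformer bin and hemisphere.
#'
#' @param residue Residue with furanose ring atoms C1'-C4', O4'.
#' @return As [pucker_from_torsions()].
#' @export
sugar_pucker <- function(residue) {
  ring <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  if (!has_atoms(residue, ring))
    return(list(phase = NA_real_, amplitude = NA_real_,
                conformer = NA_character_, hemisphere = NA_character_))
  xyz <- atom_xyz(residue, ring)
  idx <- function(k) ((k - 1) %% 5) + 1
  nu <- vapply(0:4, function(j) {
    dihedral(xyz[idx(j + 1), ], xyz[idx(j + 2), ], xyz[idx(j + 3), ],
             xyz[idx(j + 4), ])
  }, numeric(1))
  pucker_from_torsions(nu)
}

#' Amide configuration of an acyclic-backbone residue
#'
#' Computes the amide torsion omega over the C5'-N4' bond from the
#' dictionary's quadruple and classifies it as `trans` (|omega| > 90
#' degrees) or `cis`.  The boundary |omega| = 90 is assigned `trans` with
#' a warning.
#'
#' @param residue Residue of serinol or threoninol chemistry.
#' @param dictionary Chemistry dictionary.
#' @return List with `omega` (degrees) and `config` (`"cis"`/`"trans"`),
#'   or `NA` fields with `config = "not_applicable"` for non-XNA
#'   chemistries.
#' @export
amide_configuration <- function(residue,
                                dictionary = default_chemistry_dictionary()) {
  entry <- dictionary$chemistries[[residue$chemistry]]
  if (is.null(entry) || is.null(entry$amide))
    return(list(omega = NA_real_, config = "not_applicable"))
  quad <- entry$amide
  if (!has_atoms(residue, quad$name))
    return(list(omega = NA_real_, config = NA_character_))
  xyz <- atom_xyz(residue, quad$name)
  omega <- dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  if (abs(abs(omega) - 90) < 1e-12)
    warning("amide omega exactly at the 90-degree boundary; assigned trans")
  config <- if (abs(omega) >= 90) "trans" else "cis"
  list(omega = omega, config = config)
}

#' Sequential P-P distances along a chain
#'
#' @param chain An `xna_chain`.
#' @param window Optional inclusive seq-id window.
#' @return List with `per_step` data.frame (`seq_from`, `seq_to`,
#'   `distance`) and `mean`/`sd` over defined steps.
#' @export
pp_distances <- function(chain, window = NULL) {
  res <- chain$residues
  if (!is.null(window))
    res <- Filter(function(r) r$seq_id >= window[1] &&
                    r$seq_id <= window[2], res)
  if (length(res) < 2)
    return(list(per_step = NULL, mean = NA_real_, sd = NA_real_))
  rows <- list()
  for (i in seq_len(length(res) - 1L)) {
    p1 <- atom_xyz(res[[i]], "P"); p2 <- atom_xyz(res[[i + 1L]], "P")
    d <- if (anyNA(p1) || anyNA(p2)) NA_real_
         else vnorm(as.numeric(p2) - as.numeric(p1))
    rows[[i]] <- data.frame(seq_from = res[[i]]$seq_id,
                            seq_to = res[[i + 1L]]$seq_id, distance = d)
  }
  per <- do.call(rbind, rows)
  ok <- is.finite(per$distance)
  list(per_step = per, mean = mean(per$distance[ok]),
       sd = stats::sd(per$distance[ok]))
}
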