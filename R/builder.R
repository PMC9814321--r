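## Synthetic duplex builder: the inverse of the helical analysis.
##
## Pair frames are generated either from uniform local helical parameters
## (closed-form screw placement) or by sequentially composing prescribed
## base-pair step parameters.  The composition code here is written
## independently of step_parameters() so that build -> analyze round trips
## are genuine oracle tests.  Base atoms are placed exactly from the
## standard base library; backbone atoms come from idealized per-chemistry
## template monomers attached rigidly in the base frame (standard bond
## lengths/angles; amide C-N 1.33 A, C=O 1.23 A, trans amide).  Backbone
## atoms are chemically plausible rather than refined: analysis
## correctness is asserted on base-frame-derived quantities and on
## torsions computed from the same templates.

## ---- furanose ring with prescribed pucker ----------------------------

## Closed 5-ring with pseudorotation phase/amplitude targets, atoms
## C1', C2', C3', C4', O4'.  Built from a pentagon with out-of-plane
## displacements z_j = sqrt(2/5) q cos(ph + 4 pi j / 5); the mapping from
## (ph, q) to (phase, amplitude) is linear and calibrated on the fly.
.ring_raw <- function(ph_deg, q, radius = 1.32) {
  j <- 0:4
  ang <- 2 * pi * j / 5
  z <- sqrt(2 / 5) * q * cos(deg2rad(ph_deg) + 4 * pi * j / 5)
  m <- cbind(radius * cos(ang), radius * sin(ang), z)
  rownames(m) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  m
}

.ring_pucker_of <- function(m) {
  ring <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  idx <- function(k) ((k - 1) %% 5) + 1
  xyz <- m[ring, ]
  nu <- vapply(0:4, function(j)
    dihedral(xyz[idx(j + 1), ], xyz[idx(j + 2), ], xyz[idx(j + 3), ],
             xyz[idx(j + 4), ]), numeric(1))
  pucker_from_torsions(nu)
}

ribose_ring <- function(phase = 18, amplitude = 38) {
  q0 <- 0.38
  ref <- .ring_pucker_of(.ring_raw(0, q0))
  offset <- ref$phase          # phase produced by ph_deg = 0
  q <- q0 * amplitude / ref$amplitude
  ## one refinement pass against the measured pucker
  got <- .ring_pucker_of(.ring_raw((phase - offset) %% 360, q))
  offset <- offset + wrap180(got$phase - phase)
  q <- q * amplitude / got$amplitude
  .ring_raw((phase - offset) %% 360, q)
}

## ---- template monomers ------------------------------------------------

## Template coordinates are expressed in the standard base reference
## frame, so a residue is instantiated as  R %*% t(template) + origin.
.template_cache <- new.env(parent = emptyenv())

monomer_template <- function(base, chemistry, pucker_phase = 18,
                             pucker_amplitude = 38, chi = -160) {
  key <- paste(base, chemistry, pucker_phase, pucker_amplitude, chi)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  std <- standard_base_library()[[base]]
  base_atoms <- std[setdiff(rownames(std), "C1'"), , drop = FALSE]
  pur <- is_purine(pairing_base(base))
  N <- if (pur) "N9" else "N1"
  Cnext <- if (pur) "C4" else "C2"
  Cother <- if (pur) "C8" else "C6"
  out <- if (chemistry %in% c("ribose", "deoxyribose")) {
    .ribose_template(base_atoms, std, N, Cnext, pucker_phase,
                     pucker_amplitude, chi, deoxy = chemistry == "deoxyribose")
  } else {
    .xna_template(base_atoms, N, Cnext, Cother, chemistry)
  }
  .template_cache[[key]] <- out
  out
}

.ribose_template <- function(base_atoms, std, N, Cnext, phase, amp, chi,
                             deoxy = FALSE) {
  ring <- ribose_ring(phase, amp)
  ## dummy glycosidic nitrogen and its ring neighbour, in ring-local coords
  nd <- place_atom(ring["C4'", ], ring["O4'", ], ring["C1'", ],
                   1.468, 108.5, -120)
  cd <- place_atom(ring["O4'", ], ring["C1'", ], nd, 1.374, 126.4, chi)
  fit <- superpose(rbind(ring["C1'", ], nd, cd),
                   rbind(std["C1'", ], std[N, ], std[Cnext, ]))
  tf <- function(p) as.numeric(fit$rotation %*% p + fit$translation)
  ringt <- t(apply(ring, 1, tf))
  g <- function(nm) ringt[nm, ]
  atoms <- list()
  atoms[["C5'"]] <- place_atom(g("C2'"), g("C3'"), g("C4'"), 1.51, 115.5,
                               -94)
  atoms[["O3'"]] <- place_atom(atoms[["C5'"]], g("C4'"), g("C3'"),
                               1.42, 110.5, 81)
  if (!deoxy)
    atoms[["O2'"]] <- place_atom(g("C4'"), g("C3'"), g("C2'"), 1.41,
                                 111, -155)
  atoms[["O5'"]] <- place_atom(g("C3'"), g("C4'"), atoms[["C5'"]], 1.42,
                               110.8, 54)
  atoms[["P"]] <- place_atom(g("C4'"), atoms[["C5'"]], atoms[["O5'"]],
                             1.60, 120.5, 180)
  atoms[["OP1"]] <- place_atom(atoms[["C5'"]], atoms[["O5'"]],
                               atoms[["P"]], 1.48, 108, 50)
  atoms[["OP2"]] <- place_atom(atoms[["C5'"]], atoms[["O5'"]],
                               atoms[["P"]], 1.48, 108, 170)
  m <- rbind(base_atoms, ringt, do.call(rbind, atoms))
  rownames(m) <- c(rownames(base_atoms), rownames(ringt), names(atoms))
  m
}

.xna_template <- function(base_atoms, N, Cnext, Cother, chemistry) {
  b <- function(nm) base_atoms[nm, ]
  ## third in-ring reference for in-plane placement of the methylene
  A3 <- if (N == "N9") "N3" else "N3"
  atoms <- list()
  atoms[["C6'"]] <- place_atom(b(A3), b(Cnext), b(N), 1.46, 125.5, 180)
  atoms[["C5'"]] <- place_atom(b(Cnext), b(N), atoms[["C6'"]], 1.52,
                               112.5, -115)
  atoms[["O5'"]] <- place_atom(b(N), atoms[["C6'"]], atoms[["C5'"]],
                               1.23, 121.5, 0)
  atoms[["N4'"]] <- place_atom(b(N), atoms[["C6'"]], atoms[["C5'"]],
                               1.33, 115.0, 180)
  ## trans amide: omega = C6'-C5'-N4'-C2' = 180
  atoms[["C2'"]] <- place_atom(atoms[["C6'"]], atoms[["C5'"]],
                               atoms[["N4'"]], 1.45, 122.0, 180)
  atoms[["C1'"]] <- place_atom(atoms[["C5'"]], atoms[["N4'"]],
                               atoms[["C2'"]], 1.53, 110.5, -130)
  atoms[["C3'"]] <- place_atom(atoms[["C5'"]], atoms[["N4'"]],
                               atoms[["C2'"]], 1.53, 110.5, 107)
  atoms[["O1'"]] <- place_atom(atoms[["N4'"]], atoms[["C2'"]],
                               atoms[["C1'"]], 1.42, 109.5, 180)
  atoms[["O3'"]] <- place_atom(atoms[["N4'"]], atoms[["C2'"]],
                               atoms[["C3'"]], 1.42, 109.5, -65)
  if (chemistry %in% c("threoninol_L", "threoninol_D")) {
    tor <- if (chemistry == "threoninol_L") 55 else 175
    atoms[["C7'"]] <- place_atom(atoms[["N4'"]], atoms[["C2'"]],
                                 atoms[["C3'"]], 1.52, 111, tor)
  }
  atoms[["P"]] <- place_atom(atoms[["C2'"]], atoms[["C1'"]],
                             atoms[["O1'"]], 1.60, 120.5, 180)
  atoms[["OP1"]] <- place_atom(atoms[["C1'"]], atoms[["O1'"]],
                               atoms[["P"]], 1.48, 108, 65)
  atoms[["OP2"]] <- place_atom(atoms[["C1'"]], atoms[["O1'"]],
                               atoms[["P"]], 1.48, 108, -175)
  m <- rbind(base_atoms, do.call(rbind, atoms))
  rownames(m) <- c(rownames(base_atoms), names(atoms))
  m
}

## ---- frame generation --------------------------------------------------

## Independent composition of one base-pair step (builder-side math).
compose_step <- function(R1, o1, shift, slide, rise, tilt, roll, twist) {
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- rad2deg(atan2(tilt, roll))
  if (gamma > 1e-12) {
    h1 <- c(sin(deg2rad(phi - twist / 2)), cos(deg2rad(phi - twist / 2)), 0)
    hg <- as.numeric(R1 %*% h1)
    half <- rotation_about(hg, gamma / 2)
    zm <- as.numeric(half %*% R1[, 3])
    Rm <- rotation_about(zm, twist / 2) %*% half %*% R1
    R2 <- half %*% rotation_about(zm, twist) %*% half %*% R1
  } else {
    zm <- R1[, 3]
    Rm <- rotation_about(zm, twist / 2) %*% R1
    R2 <- rotation_about(zm, twist) %*% R1
  }
  o2 <- o1 + as.numeric(Rm %*% c(shift, slide, rise))
  list(R = R2, o = o2)
}

## Pair frames for uniform local helical parameters: screw about the
## global z-axis.
helical_frames <- function(n, helical_twist, helical_rise,
                           x_displacement = 0, y_displacement = 0,
                           inclination = 0, tip = 0) {
  gamma <- sqrt(inclination^2 + tip^2)
  Tm <- if (gamma > 1e-12) {
    rotation_about(c(inclination / gamma, tip / gamma, 0), gamma)
  } else diag(3)
  M <- rbind((Tm %*% c(1, 0, 0))[1:2], (Tm %*% c(0, 1, 0))[1:2])
  q2 <- solve(M, c(x_displacement, y_displacement))
  q <- c(q2, 0)
  lapply(seq_len(n) - 1L, function(k) {
    Rz <- rot_z(k * helical_twist)
    new_base_frame(k * helical_rise * c(0, 0, 1) + as.numeric(Rz %*% q),
                   Rz %*% Tm, 0)
  })
}

## ---- build specification ----------------------------------------------

.COMPLEMENT <- c(A = "U", G = "C", C = "G", U = "A", T = "A", BrU = "A")

#' Specification for a synthetic duplex
#'
#' @param sequence Strand-1 sequence: a string of base letters, with `BrU`
#'   written in brackets (e.g. `"GCUGC[BrU]GC"`), or a character vector of
#'   base codes.
#' @param chemistry Backbone chemistry per strand (length 1 or 2; one of
#'   `ribose`, `deoxyribose`, `serinol`, `threoninol_L`, `threoninol_D`).
#' @param helical Uniform local helical parameters: list with
#'   `helical_twist`, `helical_rise` and optional `x_displacement`,
#'   `y_displacement`, `inclination`, `tip`.  Ignored when `step_params`
#'   is given.
#' @param step_params Optional data.frame of per-step parameters
#'   (`shift`, `slide`, `rise`, `tilt`, `roll`, `twist`), `length(seq)-1`
#'   rows.
#' @param sigma Gaussian coordinate noise SD in Angstrom (default 0).
#' @param seed Integer seed for the noise generator.
#' @param flip_out Character vector of `"chain:seq_id"` residues to
#'   displace out of the helix (emulating flipped/unresolved terminal
#'   bases).
#' @param chain_ids Chain identifiers for the two strands.
#' @param pucker_phase,pucker_amplitude Furanose pucker targets for ribose
#'   strands (degrees).
#' @return List of class `build_spec`.
#' @export
build_spec <- function(sequence, chemistry = "ribose",
                       helical = list(helical_twist = 36,
                                      helical_rise = 3.38),
                       step_params = NULL, sigma = 0, seed = NULL,
                       flip_out = NULL, chain_ids = c("A", "B"),
                       pucker_phase = 18, pucker_amplitude = 38) {
  bases <- parse_sequence(sequence)
  if (length(bases) < 2) stop("sequence length must be >= 2")
  if (length(chemistry) == 1) chemistry <- rep(chemistry, 2)
  ok <- c("ribose", "deoxyribose", "serinol", "threoninol_L",
          "threoninol_D")
  if (!all(chemistry %in% ok))
    stop("unknown chemistry: ", paste(setdiff(chemistry, ok),
                                      collapse = ", "))
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(step_params) && nrow(step_params) != length(bases) - 1L)
    stop("step_params must have length(sequence) - 1 rows")
  structure(list(bases = bases, chemistry = chemistry, helical = helical,
                 step_params = step_params, sigma = sigma, seed = seed,
                 flip_out = flip_out, chain_ids = chain_ids,
                 pucker_phase = pucker_phase,
                 pucker_amplitude = pucker_amplitude),
            class = "build_spec")
}

#' Parse a sequence string into base codes
#'
#' @param sequence String like `"GCUGC[BrU]GC"` or a character vector of
#'   base codes.
#' @return Character vector of base codes.
#' @export
parse_sequence <- function(sequence) {
  if (length(sequence) > 1) {
    bad <- setdiff(sequence, .BASES)
    if (length(bad)) stop("unknown base code: ", paste(bad, collapse = ", "))
    return(sequence)
  }
  s <- sequence
  out <- character(0)
  while (nchar(s)) {
    if (substr(s, 1, 1) == "[") {
      close <- regexpr("]", s)
      if (close < 0) stop("unbalanced bracket in sequence")
      tok <- substr(s, 2, close - 1)
      s <- substr(s, close + 1, nchar(s))
    } else {
      tok <- substr(s, 1, 1)
      s <- substr(s, 2, nchar(s))
    }
    if (!tok %in% .BASES) stop("unknown base code: ", tok)
    out <- c(out, tok)
  }
  out
}

.complement_base <- function(base, partner_chemistry) {
  comp <- .COMPLEMENT[[base]]
  if (comp == "U" && partner_chemistry != "ribose") comp <- "T"
  comp
}

#' Build a synthetic duplex
#'
#' Places ideal Watson-Crick base pairs on pair frames generated from the
#' spec's helical or per-step parameters, attaches backbone template atoms
#' per strand chemistry, optionally displaces flipped-out residues and adds
#' seeded Gaussian noise.  Deterministic given the spec's seed.
#'
#' @param spec A [build_spec()].
#' @return An `xna_structure` of two chains (strand 2 stored in its own
#'   backbone order, antiparallel to strand 1).
#' @export
build_duplex <- function(spec) {
  stopifnot(inherits(spec, "build_spec"))
  n <- length(spec$bases)
  frames <- if (!is.null(spec$step_params)) {
    fr <- vector("list", n)
    fr[[1]] <- list(R = diag(3), o = c(0, 0, 0))
    for (k in seq_len(n - 1L)) {
      p <- spec$step_params[k, ]
      fr[[k + 1L]] <- compose_step(fr[[k]]$R, fr[[k]]$o, p$shift, p$slide,
                                   p$rise, p$tilt, p$roll, p$twist)
    }
    lapply(fr, function(f) new_base_frame(f$o, f$R, 0))
  } else {
    h <- spec$helical
    helical_frames(n, h$helical_twist, h$helical_rise,
                   h$x_displacement %||% 0, h$y_displacement %||% 0,
                   h$inclination %||% 0, h$tip %||% 0)
  }
  flip <- diag(c(1, -1, -1))
  make_res <- function(base, chemistry, frame, flipped, chain_id, seq_id) {
    tpl <- monomer_template(base, chemistry, spec$pucker_phase,
                            spec$pucker_amplitude)
    m <- tpl
    if (flipped) m <- m %*% flip
    m <- m %*% t(frame$axes)
    m <- sweep(m, 2, frame$origin, "+")
    atoms <- data.frame(
      name = rownames(tpl),
      element = substr(gsub("[0-9']", "", rownames(tpl)), 1,
                       ifelse(grepl("^BR", rownames(tpl)), 2, 1)),
      x = m[, 1], y = m[, 2], z = m[, 3],
      occupancy = 1, b_factor = 0, alt_loc = "",
      stringsAsFactors = FALSE
    )
    new_residue(chain_id, seq_id, base, chemistry, atoms)
  }
  res1 <- lapply(seq_len(n), function(k)
    make_res(spec$bases[k], spec$chemistry[1], frames[[k]], FALSE,
             spec$chain_ids[1], k))
  res2 <- lapply(seq_len(n), function(k)
    make_res(.complement_base(spec$bases[k], spec$chemistry[2]),
             spec$chemistry[2], frames[[k]], TRUE, spec$chain_ids[2], k))
  res2 <- rev(res2)   # strand 2 in its own backbone order (antiparallel)
  ## 5'(or 1')-terminal residues carry no phosphate
  strip_p <- function(res) {
    res$atoms <- res$atoms[!res$atoms$name %in% c("P", "OP1", "OP2"), ,
                           drop = FALSE]
    res
  }
  res1[[1]] <- strip_p(res1[[1]])
  res2[[1]] <- strip_p(res2[[1]])
  dict <- default_chemistry_dictionary()
  pol <- function(chem) dict$chemistries[[chem]]$polarity_label
  chains <- list(
    new_chain(spec$chain_ids[1], res1, pol(spec$chemistry[1])),
    new_chain(spec$chain_ids[2], res2, pol(spec$chemistry[2]))
  )
  names(chains) <- spec$chain_ids
  st <- new_structure(chains, metadata = list(source = "synthetic",
                                              model = 1L,
                                              build_spec = spec))
  if (!is.null(spec$flip_out)) st <- .apply_flip_out(st, spec$flip_out)
  if (spec$sigma > 0) st <- perturb(st, spec$sigma, spec$seed)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Displace named residues by a fixed rigid motion away from the helix:
## 120-degree rotation about the base y-axis through the glycosidic atom,
## then 6 Angstrom outward along the base x-axis.
.apply_flip_out <- function(structure, flip_out) {
  for (tag in flip_out) {
    parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
    ch <- parts[1]; sq <- as.integer(parts[2])
    chain <- structure$chains[[ch]]
    for (i in seq_along(chain$residues)) {
      r <- chain$residues[[i]]
      if (r$seq_id != sq) next
      fr <- tryCatch(fit_base_frame(r), error = function(e) NULL)
      if (is.null(fr)) next
      Rr <- rotation_about(fr$axes[, 2], 120)
      shiftv <- 6 * fr$axes[, 1]
      xyz <- as.matrix(r$atoms[, c("x", "y", "z")])
      xyz <- sweep(xyz, 2, fr$origin)
      xyz <- xyz %*% t(Rr)
      xyz <- sweep(xyz, 2, fr$origin + shiftv, "+")
      r$atoms$x <- xyz[, 1]; r$atoms$y <- xyz[, 2]; r$atoms$z <- xyz[, 3]
      chain$residues[[i]] <- r
    }
    structure$chains[[ch]] <- chain
  }
  structure
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param structure An `xna_structure`.
#' @param sigma Per-coordinate SD in Angstrom; `sigma = 0` returns an
#'   identical copy.
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @return Perturbed structure.
#' @export
perturb <- function(structure, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(structure)
  run <- function() {
    for (ci in seq_along(structure$chains)) {
      ch <- structure$chains[[ci]]
      for (ri in seq_along(ch$residues)) {
        a <- ch$residues[[ri]]$atoms
        k <- nrow(a)
        a$x <- a$x + stats::rnorm(k, 0, sigma)
        a$y <- a$y + stats::rnorm(k, 0, sigma)
        a$z <- a$z + stats::rnorm(k, 0, sigma)
        ch$residues[[ri]]$atoms <- a
      }
      structure$chains[[ci]] <- ch
    }
    if (nrow(structure$waters)) {
      k <- nrow(structure$waters)
      structure$waters$x <- structure$waters$x + stats::rnorm(k, 0, sigma)
      structure$waters$y <- structure$waters$y + stats::rnorm(k, 0, sigma)
      structure$waters$z <- structure$waters$z + stats::rnorm(k, 0, sigma)
    }
    structure
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  run()
}

#' Canonical fiber-model duplex
#'
#' Reference geometries built from conventional fiber-model parameters
#' (embedded defaults, documented as conventions): A-form twist 32.7
#' degrees / rise 2.81 Angstrom, inclination 19 degrees, x-displacement
#' -4.4 Angstrom, C3'-endo sugars; B-form twist 36.0 / rise 3.38,
#' inclination 0, x-displacement -0.7, C2'-endo sugars.
#'
#' @param form `"A"` or `"B"`.
#' @param sequence Strand-1 sequence (string or base-code vector).
#' @param chemistry Backbone chemistry (default ribose for A, deoxyribose
#'   for B).
#' @return An `xna_structure`.
#' @export
fiber_duplex <- function(form = c("A", "B"), sequence,
                         chemistry = NULL) {
  form <- match.arg(form)
  if (is.null(chemistry))
    chemistry <- if (form == "A") "ribose" else "deoxyribose"
  h <- if (form == "A") {
    list(helical_twist = 32.7, helical_rise = 2.81,
         x_displacement = -4.4, inclination = 19.0)
  } else {
    list(helical_twist = 36.0, helical_rise = 3.38,
         x_displacement = -0.7, inclination = 0.0)
  }
  pk <- if (form == "A") 18 else 162
  build_duplex(build_spec(sequence, chemistry, helical = h,
                          pucker_phase = pk))
}
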