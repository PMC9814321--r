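## Least-squares superposition and base reference frame fitting.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t` minimizing
#' the RMSD between `R %*% moving + t` and `fixed`.
#'
#' @param moving,fixed Numeric matrices (n x 3) of corresponding points,
#'   n >= 3, not collinear.
#' @return List with `rotation` (3x3), `translation` (length 3) and `rmsd`
#'   (Angstrom, evaluated after applying the transform).
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed) || ncol(moving) != 3 || ncol(fixed) != 3)
    stop("point sets must be matching n x 3 matrices")
  if (nrow(moving) < 3) stop("need at least 3 point correspondences")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  M <- sweep(moving, 2, cm); F <- sweep(fixed, 2, cf)
  ## collinearity check: rank of the centered moving set
  if (svd(M)$d[2] < 1e-8 * max(1, svd(M)$d[1]))
    stop("point set is (near-)collinear; superposition is degenerate")
  H <- t(M) %*% F
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cf - R %*% cm)
  moved <- sweep(moving %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

new_base_frame <- function(origin, axes, fit_rmsd, residue_ref = NULL) {
  structure(list(origin = as.numeric(origin), axes = axes,
                 fit_rmsd = fit_rmsd, residue_ref = residue_ref),
            class = "base_frame")
}

#' Fit a base reference frame to an observed residue
#'
#' Superposes the idealized base-ring atoms of the standard base geometry
#' onto the observed ring atoms of the residue; the fitted frame is the
#' image of the standard reference frame under that transform.  Purines and
#' pyrimidines use their respective ring-atom lists; missing ring atoms are
#' tolerated down to three.
#'
#' @param residue Residue (from [read_structure()] or the builder).
#' @param library Standard base library.
#' @return A `base_frame`: `origin` (3-vector), `axes` (orthonormal 3x3,
#'   det +1, columns = x, y, z axes), `fit_rmsd` (Angstrom).
#' @export
fit_base_frame <- function(residue, library = standard_base_library()) {
  base <- pairing_base(residue$base)
  ideal <- library[[base]]
  atoms <- intersect(frame_fit_atoms(base), residue$atoms$name)
  atoms <- intersect(atoms, rownames(ideal))
  if (length(atoms) < 3)
    stop("residue ", residue$chain_id, ":", residue$seq_id,
         " has fewer than 3 named ring atoms; cannot fit a frame")
  obs <- atom_xyz(residue, atoms)
  fit <- superpose(ideal[atoms, , drop = FALSE], obs)
  new_base_frame(fit$translation, fit$rotation, fit$rmsd,
                 residue_ref = list(chain_id = residue$chain_id,
                                    seq_id = residue$seq_id,
                                    base = residue$base))
}

#' Fit frames for every residue of a structure
#'
#' @param structure An `xna_structure`.
#' @param library Standard base library.
#' @return Named list of `base_frame` objects keyed `"<chain>:<seq_id>"`;
#'   residues whose frame cannot be fitted are omitted with a message.
#' @export
fit_frames <- function(structure, library = standard_base_library()) {
  frames <- list()
  for (ch in structure$chains) {
    for (res in ch$residues) {
      key <- paste0(res$chain_id, ":", res$seq_id)
      fr <- tryCatch(fit_base_frame(res, library), error = function(e) {
        message("skipping frame for ", key, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(fr)) frames[[key]] <- fr
    }
  }
  frames
}

## Base frame of the complementary (strand II) base, re-expressed in the
## pair convention: y and z axes are negated.
flip_frame <- function(frame) {
  fl <- frame
  fl$axes <- frame$axes %*% diag(c(1, -1, -1))
  fl
}

## --- base-pair detection ----------------------------------------------

.BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4", U = "N3",
                     T = "N3")
.BASE_ACCEPTORS <- list(A = c("N1", "N3", "N7"), G = c("O6", "N7", "N3"),
                        C = c("N3", "O2"), U = c("O2", "O4"),
                        T = c("O2", "O4"))

#' Default base-pairing criteria
#'
#' @param hbond_min,hbond_max Heavy-atom donor-acceptor distance window in
#'   Angstrom (default 2.4-3.5).
#' @param min_hbonds Minimum number of qualifying H-bonds (default 2).
#' @param max_plane_angle Maximum inter-base-plane angle in degrees
#'   (default 65; permissive enough to keep propeller-twisted pairs).
#' @param max_origin_dist Maximum frame-origin distance in Angstrom
#'   (default 15).
#' @return List of criteria for [detect_pairs()].
#' @export
pairing_criteria <- function(hbond_min = 2.4, hbond_max = 3.5,
                             min_hbonds = 2, max_plane_angle = 65,
                             max_origin_dist = 15) {
  list(hbond_min = hbond_min, hbond_max = hbond_max,
       min_hbonds = min_hbonds, max_plane_angle = max_plane_angle,
       max_origin_dist = max_origin_dist)
}

.base_hbonds <- function(res_i, res_j, criteria) {
  bi <- pairing_base(res_i$base); bj <- pairing_base(res_j$base)
  cand <- rbind(
    expand.grid(d = .BASE_DONORS[[bi]], a = .BASE_ACCEPTORS[[bj]],
                donor_res = "i", stringsAsFactors = FALSE),
    expand.grid(d = .BASE_DONORS[[bj]], a = .BASE_ACCEPTORS[[bi]],
                donor_res = "j", stringsAsFactors = FALSE)
  )
  out <- list()
  for (k in seq_len(nrow(cand))) {
    di <- if (cand$donor_res[k] == "i") res_i else res_j
    ai <- if (cand$donor_res[k] == "i") res_j else res_i
    pd <- atom_xyz(di, cand$d[k]); pa <- atom_xyz(ai, cand$a[k])
    if (anyNA(pd) || anyNA(pa)) next
    dist <- vnorm(as.numeric(pd) - as.numeric(pa))
    if (dist >= criteria$hbond_min && dist <= criteria$hbond_max) {
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = di$chain_id, donor_seq = di$seq_id,
        donor_atom = cand$d[k],
        acceptor_chain = ai$chain_id, acceptor_seq = ai$seq_id,
        acceptor_atom = cand$a[k], distance = dist,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## Hoogsteen recognition: any H-bond engaging a purine N7 marks the pair
## as Hoogsteen-edge pairing; otherwise the pattern is Watson-Crick.
.classify_pair <- function(res_i, res_j, hbonds) {
  n7_i <- is_purine(pairing_base(res_i$base)) &&
    any((hbonds$acceptor_seq == res_i$seq_id &
           hbonds$acceptor_chain == res_i$chain_id &
           hbonds$acceptor_atom == "N7"))
  n7_j <- is_purine(pairing_base(res_j$base)) &&
    any((hbonds$acceptor_seq == res_j$seq_id &
           hbonds$acceptor_chain == res_j$chain_id &
           hbonds$acceptor_atom == "N7"))
  if (n7_i || n7_j) "hoogsteen" else "watson_crick"
}

#' Detect base pairs in a structure
#'
#' Enumerates residue pairs that satisfy (i) at least `min_hbonds` base-base
#' N/O donor-acceptor distances inside the H-bond window, (ii) an
#' inter-base-plane angle below threshold and (iii) a frame-origin distance
#' below threshold.  The pair class is assigned from the H-bond atom
#' pattern: bonds on a purine's N7 edge mark a Hoogsteen pair, otherwise
#' Watson-Crick.  Sequential same-chain neighbours are excluded.  When a
#' residue qualifies for several candidates of the same class the candidate
#' with more H-bonds (then smaller mean H-bond distance) is kept; a residue
#' may still belong to one Watson-Crick and one Hoogsteen pair at once, as
#' in a C:G*G triad.
#'
#' @param structure An `xna_structure`.
#' @param frames Frames from [fit_frames()] (computed if missing).
#' @param criteria [pairing_criteria()].
#' @return data.frame, one row per pair: residue refs, `pair_class`,
#'   `orientation`, number of H-bonds and mean bond distance, plus the
#'   H-bond table as the `"hbonds"` attribute.
#' @export
detect_pairs <- function(structure, frames = NULL,
                         criteria = pairing_criteria()) {
  if (is.null(frames)) frames <- fit_frames(structure)
  residues <- list()
  for (ch in structure$chains) for (r in ch$residues)
    residues[[paste0(r$chain_id, ":", r$seq_id)]] <- r
  keys <- intersect(names(residues), names(frames))
  cand <- list()
  if (length(keys) >= 2) {
    for (a in seq_len(length(keys) - 1L)) for (b in (a + 1L):length(keys)) {
      ki <- keys[a]; kj <- keys[b]
      ri <- residues[[ki]]; rj <- residues[[kj]]
      if (ri$chain_id == rj$chain_id && abs(ri$seq_id - rj$seq_id) <= 1)
        next
      fi <- frames[[ki]]; fj <- frames[[kj]]
      if (vnorm(fi$origin - fj$origin) > criteria$max_origin_dist) next
      ang <- rad2deg(acos(min(1, abs(sum(fi$axes[, 3] * fj$axes[, 3])))))
      if (ang > criteria$max_plane_angle) next
      hb <- .base_hbonds(ri, rj, criteria)
      if (is.null(hb) || nrow(hb) < criteria$min_hbonds) next
      cand[[length(cand) + 1L]] <- list(
        i = ki, j = kj, hbonds = hb,
        class = .classify_pair(ri, rj, hb),
        n = nrow(hb), mean_dist = mean(hb$distance)
      )
    }
  }
  ## tie-breaking: per (residue, class) keep the best candidate
  if (length(cand)) {
    ord <- order(-vapply(cand, `[[`, 0, "n"),
                 vapply(cand, `[[`, 0, "mean_dist"))
    cand <- cand[ord]
    taken <- character(0)
    keep <- logical(length(cand))
    for (k in seq_along(cand)) {
      tags <- paste(c(cand[[k]]$i, cand[[k]]$j), cand[[k]]$class)
      if (any(tags %in% taken)) next
      keep[k] <- TRUE
      taken <- c(taken, tags)
    }
    cand <- cand[keep]
  }
  if (!length(cand)) {
    out <- data.frame(chain_i = character(0), seq_i = integer(0),
                      base_i = character(0), chain_j = character(0),
                      seq_j = integer(0), base_j = character(0),
                      pair_class = character(0), orientation = character(0),
                      n_hbonds = integer(0), mean_hbond = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "hbonds") <- NULL
    return(out)
  }
  rows <- lapply(cand, function(p) {
    ri <- residues[[p$i]]; rj <- residues[[p$j]]
    data.frame(chain_i = ri$chain_id, seq_i = ri$seq_id, base_i = ri$base,
               chain_j = rj$chain_id, seq_j = rj$seq_id, base_j = rj$base,
               pair_class = p$class, orientation = NA_character_,
               n_hbonds = p$n, mean_hbond = p$mean_dist,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ## stable report order: by chain then seq of the first residue
  o <- order(out$chain_i, out$seq_i, out$chain_j, out$seq_j)
  out <- out[o, , drop = FALSE]
  cand <- cand[o]
  rownames(out) <- NULL
  out$orientation <- vapply(seq_len(nrow(out)), function(k)
    tryCatch(classify_orientation(out[k, ], structure),
             error = function(e) NA_character_), character(1))
  attr(out, "hbonds") <- do.call(rbind, lapply(cand, `[[`, "hbonds"))
  out
}

## Local backbone direction at a residue: vector between the glycosidic
## attachment atoms of the flanking residues (or the residue itself at a
## terminus), in stored chain order.
.backbone_direction <- function(structure, chain_id, seq_id,
                                dictionary = default_chemistry_dictionary()) {
  ch <- structure$chains[[chain_id]]
  ids <- vapply(ch$residues, `[[`, 0L, "seq_id")
  i <- match(seq_id, ids)
  if (is.na(i)) stop("residue not found: ", chain_id, ":", seq_id)
  if (length(ids) < 2) stop("isolated single-residue chain: orientation undefined")
  ref_atom <- function(res) {
    entry <- dictionary$chemistries[[res$chemistry]]
    nm <- if (!is.null(entry)) entry$glycosidic_atom else "C1'"
    p <- atom_xyz(res, nm)
    if (anyNA(p)) p <- atom_xyz(res, res$atoms$name[1])
    as.numeric(p)
  }
  lo <- max(1L, i - 1L); hi <- min(length(ids), i + 1L)
  ref_atom(ch$residues[[hi]]) - ref_atom(ch$residues[[lo]])
}

#' Classify the relative strand orientation of a base pair
#'
#' Computes local backbone direction vectors at the two paired residues
#' (from the previous to the next glycosidic attachment atom along each
#' chain) and classifies the pair as `parallel` (positive dot product) or
#' `antiparallel` (negative).
#'
#' @param pair One row of the [detect_pairs()] data.frame (or a list with
#'   `chain_i`, `seq_i`, `chain_j`, `seq_j`).
#' @param structure The structure the pair belongs to.
#' @param dictionary Chemistry dictionary.
#' @return `"parallel"` or `"antiparallel"`.
#' @export
classify_orientation <- function(pair, structure,
                                 dictionary = default_chemistry_dictionary()) {
  di <- .backbone_direction(structure, pair$chain_i, pair$seq_i, dictionary)
  dj <- .backbone_direction(structure, pair$chain_j, pair$seq_j, dictionary)
  if (sum(di * dj) > 0) "parallel" else "antiparallel"
}

#' Export a pair list as TSV
#'
#' @param pairs Result of [detect_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
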