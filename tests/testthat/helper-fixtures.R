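## Shared fixture builders (all generated in code; no data files).

## Residue from a coordinate matrix with named rows.
residue_from_matrix <- function(m, chain = "A", seq = 1L, base = "G",
                                chemistry = "ribose") {
  xnahelix:::new_residue(chain, seq, base, chemistry, data.frame(
    name = rownames(m),
    element = substr(gsub("[0-9']", "", rownames(m)), 1, 1),
    x = m[, 1], y = m[, 2], z = m[, 3],
    occupancy = 1, b_factor = 0, alt_loc = "",
    stringsAsFactors = FALSE
  ))
}

structure_from_residues <- function(...) {
  residues <- list(...)
  chains <- list()
  for (r in residues) {
    id <- r$chain_id
    if (is.null(chains[[id]]))
      chains[[id]] <- xnahelix:::new_chain(id, list())
    chains[[id]]$residues <- c(chains[[id]]$residues, list(r))
  }
  xnahelix:::new_structure(chains)
}

## Random proper rotation (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Apply a rigid motion to every atom of a structure.
transform_structure <- function(structure, R, t) {
  for (ci in seq_along(structure$chains)) {
    ch <- structure$chains[[ci]]
    for (ri in seq_along(ch$residues)) {
      a <- ch$residues[[ri]]$atoms
      xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
      xyz <- sweep(xyz, 2, t, "+")
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      ch$residues[[ri]]$atoms <- a
    }
    structure$chains[[ci]] <- ch
  }
  if (nrow(structure$waters)) {
    xyz <- as.matrix(structure$waters[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, t, "+")
    structure$waters$x <- xyz[, 1]
    structure$waters$y <- xyz[, 2]
    structure$waters$z <- xyz[, 3]
  }
  structure
}

## Planar Hoogsteen G*G fixture: the second guanine is the standard-frame
## guanine rotated -31.98 degrees about z and translated so that its
## N1/N2 Watson-Crick edge donates to the first guanine's O6/N7 Hoogsteen
## edge at 2.90 Angstrom (quadruplex-like G*G arrangement).
hoogsteen_gg_structure <- function() {
  G <- standard_base_library()$G
  R <- xnahelix:::rot_z(-31.98037)
  t <- c(4.693383, -0.2528994, 0)
  G2 <- sweep(G %*% t(R), 2, t, "+")
  structure_from_residues(residue_from_matrix(G, "A", 1),
                          residue_from_matrix(G2, "B", 1))
}

## The designed Watson-Crick pair table of a builder duplex.
designed_pairs <- function(spec) {
  n <- length(spec$bases)
  data.frame(
    chain_i = spec$chain_ids[1], seq_i = seq_len(n), base_i = spec$bases,
    chain_j = spec$chain_ids[2], seq_j = seq_len(n),
    base_j = vapply(spec$bases, xnahelix:::.complement_base,
                    character(1), spec$chemistry[2]),
    pair_class = "watson_crick", orientation = "antiparallel",
    n_hbonds = NA_integer_, mean_hbond = NA_real_,
    stringsAsFactors = FALSE
  )
}

## Location for optional user-supplied deposited coordinate files
## (see README: not distributed with the package).
deposited_path <- function(id) {
  testthat::test_path("deposited", paste0(tolower(id), ".pdb"))
}

## Minimal mmCIF text for one standard-frame residue.
mmcif_fixture_lines <- function(base = "G") {
  hdr <- c(
    "data_fixture", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  m <- standard_base_library()[[base]]
  rows <- vapply(seq_len(nrow(m)), function(i) {
    sprintf("ATOM %d %s %s . %s A 1 1 ? %.3f %.3f %.3f 1.00 10.00 ? 1 %s A %s 1",
            i, substr(rownames(m)[i], 1, 1), rownames(m)[i], base,
            m[i, 1], m[i, 2], m[i, 3], base, rownames(m)[i])
  }, character(1))
  c(hdr, rows)
}
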