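## Intrastrand CH-O contact detection and (water-mediated) H-bonds.
##
## The acyclic backbones place the amide carbonyl oxygen (O5') close to
## polarized aromatic carbons (purine C8, cytosine C6/C5) and to the C6'
## methylene of the neighbouring residue; cytosine's O2 carbonyl likewise
## approaches neighbouring C6' atoms.  Contacts are heavy-atom C-O
## distances (crystal models carry no hydrogens); no angular criterion is
## applied by default.

#' Default CH-O contact scheme
#'
#' Each entry names a donor-carbon selector, an acceptor-oxygen selector,
#' the residue offsets allowed between acceptor and donor residues (donor
#' residue index minus acceptor residue index, in stored chain order) and
#' whether the acceptor must belong to an acyclic (amide-carbonyl)
#' chemistry.  The within-van-der-Waals cutoff defaults to 3.7 Angstrom;
#' an extended reporting range (default 5.0) retains longer contacts
#' flagged `within_vdw = FALSE`.
#'
#' @param cutoff Van der Waals cutoff in Angstrom.
#' @param extended_range Extended reporting range in Angstrom.
#' @return List of class `contact_scheme`.
#' @export
default_contact_scheme <- function(cutoff = 3.7, extended_range = 5.0) {
  entry <- function(class, donor_atoms, donor_bases, acceptor_atom,
                    offsets, acceptor_xna = TRUE) {
    list(class = class, donor_atoms = donor_atoms,
         donor_bases = donor_bases, acceptor_atom = acceptor_atom,
         offsets = offsets, acceptor_xna = acceptor_xna)
  }
  structure(list(
    cutoff = cutoff,
    extended_range = extended_range,
    entries = list(
      entry("O5'-C8", "C8", c("A", "G"), "O5'", c(1L)),
      entry("O5'-C6", "C6", "C", "O5'", c(1L)),
      entry("O5'-C5", "C5", "C", "O5'", c(1L)),
      entry("O5'-C6'", "C6'", NULL, "O5'", c(1L)),
      entry("O2-C6'", "C6'", NULL, "O2", c(-1L, 1L), acceptor_xna = FALSE)
    )
  ), class = "contact_scheme")
}

#' Detect CH-O contacts under a scheme
#'
#' For every same-strand residue pair satisfying an entry's offset
#' constraint, every (donor carbon, acceptor oxygen) combination within
#' the extended range yields one record (each atom pair at most once).
#' Acceptor selectors marked chemistry-aware resolve only on acyclic
#' backbones whose O5' is an amide carbonyl - a ribose O5' ester oxygen is
#' never matched, so a pure-RNA structure yields no O5'-class contacts.
#'
#' @param structure An `xna_structure`.
#' @param scheme A [default_contact_scheme()]-style scheme.
#' @param dictionary Chemistry dictionary.
#' @return data.frame of contact records with distances, class labels,
#'   residue offset and `within_vdw` flag.
#' @export
find_ch_o_contacts <- function(structure,
                               scheme = default_contact_scheme(),
                               dictionary = default_chemistry_dictionary()) {
  known <- unique(unlist(lapply(dictionary$chemistries, function(e)
    e$backbone_atoms)))
  known <- c(known, unlist(lapply(.BASES, base_atom_names)))
  for (e in scheme$entries) {
    bad <- setdiff(c(e$donor_atoms, e$acceptor_atom), known)
    if (length(bad))
      stop("contact scheme references unknown atom name(s): ",
           paste(bad, collapse = ", "))
  }
  out <- list()
  for (ch in structure$chains) {
    res <- ch$residues
    n <- length(res)
    for (e in scheme$entries) {
      for (ia in seq_len(n)) {       # acceptor residue
        ra <- res[[ia]]
        if (e$acceptor_xna && !is_xna_chemistry(ra$chemistry)) next
        pa <- atom_xyz(ra, e$acceptor_atom)
        if (anyNA(pa)) next
        for (off in e$offsets) {
          id <- ia + off               # donor residue
          if (id < 1 || id > n) next
          rd <- res[[id]]
          if (!is.null(e$donor_bases) &&
              !(pairing_base(rd$base) %in% e$donor_bases)) next
          for (datom in e$donor_atoms) {
            pd <- atom_xyz(rd, datom)
            if (anyNA(pd)) next
            d <- vnorm(as.numeric(pd) - as.numeric(pa))
            if (d > scheme$extended_range) next
            out[[length(out) + 1L]] <- data.frame(
              chain_id = ch$chain_id,
              donor_seq = rd$seq_id, donor_base = rd$base,
              donor_atom = datom,
              acceptor_seq = ra$seq_id, acceptor_base = ra$base,
              acceptor_atom = e$acceptor_atom,
              class = e$class, offset = off, distance = d,
              within_vdw = d <= scheme$cutoff,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(chain_id = character(0), donor_seq = integer(0),
                      donor_base = character(0), donor_atom = character(0),
                      acceptor_seq = integer(0),
                      acceptor_base = character(0),
                      acceptor_atom = character(0), class = character(0),
                      offset = integer(0), distance = numeric(0),
                      within_vdw = logical(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  ## each atom pair reported once (entries could overlap)
  key <- paste(df$chain_id, df$donor_seq, df$donor_atom, df$acceptor_seq,
               df$acceptor_atom)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$chain_id, df$acceptor_seq, df$class), , drop = FALSE]
}

#' Direct and water-mediated hydrogen bonds
#'
#' Direct bonds are donor-acceptor heavy-atom pairs within `cutoff`.
#' With `include_water`, a bridged record is reported when a water oxygen
#' lies within `cutoff` of both the donor and the acceptor (both legs
#' required).
#'
#' @param structure An `xna_structure`.
#' @param donor_atoms,acceptor_atoms Atom-name selectors.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 3.4).
#' @param include_water Also search water-mediated bridges.
#' @return data.frame of bonds; bridged records carry the water's ids and
#'   both leg distances.
#' @export
find_hbonds <- function(structure, donor_atoms, acceptor_atoms,
                        cutoff = 3.4, include_water = FALSE) {
  donors <- list(); acceptors <- list()
  for (ch in structure$chains) for (r in ch$residues) {
    for (nm in intersect(donor_atoms, r$atoms$name))
      donors[[length(donors) + 1L]] <-
        list(res = r, atom = nm, xyz = as.numeric(atom_xyz(r, nm)))
    for (nm in intersect(acceptor_atoms, r$atoms$name))
      acceptors[[length(acceptors) + 1L]] <-
        list(res = r, atom = nm, xyz = as.numeric(atom_xyz(r, nm)))
  }
  out <- list()
  rec <- function(d, a, type, dist, water = NULL, leg1 = NA, leg2 = NA) {
    data.frame(donor_chain = d$res$chain_id, donor_seq = d$res$seq_id,
               donor_atom = d$atom, acceptor_chain = a$res$chain_id,
               acceptor_seq = a$res$seq_id, acceptor_atom = a$atom,
               type = type, distance = dist,
               water_chain = if (is.null(water)) NA_character_
                             else water$chain_id,
               water_seq = if (is.null(water)) NA_integer_
                           else water$seq_id,
               leg_donor_water = leg1, leg_water_acceptor = leg2,
               stringsAsFactors = FALSE)
  }
  for (d in donors) for (a in acceptors) {
    same <- d$res$chain_id == a$res$chain_id && d$res$seq_id == a$res$seq_id
    if (same && d$atom == a$atom) next
    dist <- vnorm(d$xyz - a$xyz)
    if (dist <= cutoff && !same)
      out[[length(out) + 1L]] <- rec(d, a, "direct", dist)
  }
  if (include_water && nrow(structure$waters)) {
    w <- structure$waters
    for (k in seq_len(nrow(w))) {
      wxyz <- as.numeric(w[k, c("x", "y", "z")])
      for (d in donors) {
        l1 <- vnorm(d$xyz - wxyz)
        if (l1 > cutoff) next
        for (a in acceptors) {
          same <- d$res$chain_id == a$res$chain_id &&
            d$res$seq_id == a$res$seq_id && d$atom == a$atom
          if (same) next
          l2 <- vnorm(a$xyz - wxyz)
          if (l2 > cutoff) next
          out[[length(out) + 1L]] <-
            rec(d, a, "water_mediated", l1 + l2,
                water = list(chain_id = w$chain_id[k],
                             seq_id = w$seq_id[k]),
                leg1 = l1, leg2 = l2)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(donor_chain = character(0), donor_seq = integer(0),
                      donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_seq = integer(0),
                      acceptor_atom = character(0), type = character(0),
                      distance = numeric(0), water_chain = character(0),
                      water_seq = integer(0), leg_donor_water = numeric(0),
                      leg_water_acceptor = numeric(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write contact records as TSV
#'
#' @param contacts data.frame from [find_ch_o_contacts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
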