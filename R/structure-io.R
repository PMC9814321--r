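## Coordinate parsing and the in-memory structure model.
##
## A Structure is a plain list:
##   chains   : named list of chains; each chain is
##              list(chain_id, residues, polarity_label, breaks)
##              where residues is an ordered list of
##              list(chain_id, seq_id, base, chemistry, atoms, is_water)
##              and atoms is a data.frame(name, element, x, y, z,
##              occupancy, b_factor, alt_loc)
##   waters   : data.frame of water oxygen records (same columns + ids)
##   metadata : list(source, model, provenance, ...)
##
## Parsing itself is delegated to bio3d (read.pdb / read.cif); this module
## owns residue assembly, alt-loc policy, base identification by atom set,
## chemistry annotation and chain-break detection.

.WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

.RESID_BASE <- c(
  A = "A", ADE = "A", RA = "A", DA = "A",
  C = "C", CYT = "C", RC = "C", DC = "C",
  G = "G", GUA = "G", RG = "G", DG = "G",
  U = "U", URA = "U", URI = "U", RU = "U",
  T = "T", THY = "T", DT = "T",
  BRU = "BrU", `5BU` = "BrU", UBR = "BrU",
  XA = "A", XC = "C", XG = "G", XT = "T", XU = "U"
)

## Identify the base of a residue from its atom names alone (used when the
## 3-letter component code is not a standard one, e.g. for deposited XNA
## monomers whose codes are not standardized).
.base_from_atoms <- function(atom_names) {
  has <- function(a) a %in% atom_names
  if (has("N9") && has("N7")) {
    if (has("N6")) return("A")
    if (has("O6") || has("N2")) return("G")
    return("A")
  }
  if (has("N1") && has("C6") && has("O2")) {
    if (has("N4")) return("C")
    if (has("BR")) return("BrU")
    if (has("C7")) return("T")
    if (has("O4")) return("U")
    return("C")
  }
  NA_character_
}

new_residue <- function(chain_id, seq_id, base, chemistry, atoms,
                        is_water = FALSE) {
  stopifnot(is.data.frame(atoms))
  structure(list(chain_id = chain_id, seq_id = seq_id, base = base,
                 chemistry = chemistry, atoms = atoms, is_water = is_water),
            class = "xna_residue")
}

new_chain <- function(chain_id, residues, polarity_label = "",
                      breaks = integer(0)) {
  structure(list(chain_id = chain_id, residues = residues,
                 polarity_label = polarity_label, breaks = breaks),
            class = "xna_chain")
}

new_structure <- function(chains, waters = NULL, metadata = list()) {
  if (is.null(waters)) {
    waters <- data.frame(name = character(0), element = character(0),
                         x = numeric(0), y = numeric(0), z = numeric(0),
                         occupancy = numeric(0), b_factor = numeric(0),
                         alt_loc = character(0), chain_id = character(0),
                         seq_id = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(chains = chains, waters = waters, metadata = metadata),
            class = "xna_structure")
}

## Coordinates of named atoms in a residue (rows in requested order);
## rows of NA for missing atoms.
atom_xyz <- function(residue, names) {
  i <- match(names, residue$atoms$name)
  m <- as.matrix(residue$atoms[i, c("x", "y", "z")])
  rownames(m) <- names
  m
}

has_atoms <- function(residue, names) all(names %in% residue$atoms$name)

#' Read a coordinate file into a structure
#'
#' Parses a PDB or mmCIF coordinate file, separates waters, applies the
#' alt-loc policy (highest occupancy conformer kept; ties broken by the
#' alphabetically first identifier), identifies each residue's base (by
#' component code where standard, otherwise by its base atom-name set) and
#' annotates its backbone chemistry via [classify_chemistry()].  Chain
#' breaks (bridging O3'(i)-P(i+1) distance above `break_tol`) are recorded
#' per chain.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param dictionary Chemistry dictionary.
#' @param break_tol Covalent-linkage tolerance in Angstrom (default 2.5).
#' @return An object of class `xna_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           dictionary = default_chemistry_dictionary(),
                           break_tol = 2.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE,
                                         verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  ## normalize prime conventions: C1* / "C1'" -> C1'
  at$elety <- gsub('"', "", gsub("\\*", "'", at$elety))
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  ## element: bio3d stores it in elesy; fall back to first letter of name
  if (is.null(at$elesy) || all(is.na(at$elesy))) {
    at$elesy <- sub("[0-9'].*$", "", at$elety)
  }
  at$elety <- toupper(at$elety)

  ## --- alt-loc policy: one conformer per (chain, resno, atom name),
  ## highest occupancy first, ties by alphabetical alt id; original file
  ## order restored afterwards
  at$.row <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[order(key, -at$o, at$alt), ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ]
  at <- at[order(at$.row), ]

  is_water <- at$resid %in% .WATER_RESID
  waters <- at[is_water, , drop = FALSE]
  at <- at[!is_water, , drop = FALSE]

  waters_df <- data.frame(
    name = waters$elety, element = waters$elesy,
    x = waters$x, y = waters$y, z = waters$z,
    occupancy = waters$o, b_factor = waters$b, alt_loc = waters$alt,
    chain_id = waters$chain, seq_id = waters$resno,
    stringsAsFactors = FALSE
  )

  chains <- list()
  skipped <- 0L
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    residues <- list()
    for (rn in unique(ca$resno)) {
      ra <- ca[ca$resno == rn, , drop = FALSE]
      atoms <- data.frame(
        name = ra$elety, element = ra$elesy,
        x = ra$x, y = ra$y, z = ra$z,
        occupancy = ra$o, b_factor = ra$b, alt_loc = ra$alt,
        stringsAsFactors = FALSE
      )
      resid <- toupper(ra$resid[1])
      base <- unname(.RESID_BASE[resid])
      if (is.na(base)) base <- .base_from_atoms(atoms$name)
      if (is.na(base)) { skipped <- skipped + 1L; next }
      res <- new_residue(ch, rn, base, "unknown", atoms)
      res$chemistry <- classify_chemistry(res, dictionary)
      residues[[length(residues) + 1L]] <- res
    }
    if (!length(residues)) next
    chem_tab <- table(vapply(residues, `[[`, "", "chemistry"))
    major <- names(chem_tab)[which.max(chem_tab)]
    entry <- dictionary$chemistries[[major]]
    polarity <- if (!is.null(entry)) entry$polarity_label else ""
    chain <- new_chain(ch, residues, polarity)
    chain$breaks <- .chain_breaks(chain, dictionary, break_tol)
    chains[[ch]] <- chain
  }
  if (!length(chains)) {
    warning("no nucleic residues found in ", path)
  }
  new_structure(chains, waters_df,
                metadata = list(source = path, model = 1L,
                                format = format,
                                skipped_residues = skipped))
}

## Indices i for which the linkage between residue i and i+1 is broken.
.chain_breaks <- function(chain, dictionary, tol = 2.5) {
  res <- chain$residues
  if (length(res) < 2) return(integer(0))
  breaks <- integer(0)
  for (i in seq_len(length(res) - 1L)) {
    entry <- dictionary$chemistries[[res[[i]]$chemistry]]
    if (is.null(entry)) next
    from <- atom_xyz(res[[i]], entry$bridge$from)
    to <- atom_xyz(res[[i + 1L]], entry$bridge$to)
    if (anyNA(from) || anyNA(to)) next
    if (vnorm(as.numeric(to) - as.numeric(from)) > tol) {
      breaks <- c(breaks, i)
    }
  }
  breaks
}

#' Write a structure as a PDB file
#'
#' Writes all chain atoms (and waters) in PDB format via bio3d.  XNA
#' residues are written with placeholder component codes (`XA`, `XC`, ...);
#' reading relies on atom names, not component codes, so the round trip is
#' faithful.
#'
#' @param structure An `xna_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  rows <- list()
  code_for <- function(base, chemistry) {
    if (base == "BrU") return("BRU")
    if (is_xna_chemistry(chemistry)) return(paste0("X", substr(base, 1, 1)))
    if (chemistry == "deoxyribose") return(paste0("D", base))
    base
  }
  for (ch in structure$chains) {
    for (res in ch$residues) {
      a <- res$atoms
      rows[[length(rows) + 1L]] <- data.frame(
        elety = a$name, resid = code_for(res$base, res$chemistry),
        chain = res$chain_id, resno = res$seq_id,
        x = a$x, y = a$y, z = a$z, o = a$occupancy, b = a$b_factor,
        elesy = a$element, stringsAsFactors = FALSE
      )
    }
  }
  w <- structure$waters
  if (nrow(w)) {
    rows[[length(rows) + 1L]] <- data.frame(
      elety = w$name, resid = "HOH", chain = w$chain_id,
      resno = w$seq_id, x = w$x, y = w$y, z = w$z, o = w$occupancy,
      b = w$b_factor, elesy = w$element, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  xyz <- as.numeric(t(as.matrix(df[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = df$resno,
                   resid = df$resid, eleno = seq_len(nrow(df)),
                   elety = df$elety, chain = df$chain, o = df$o, b = df$b,
                   elesy = df$elesy)
  invisible(path)
}

#' Select a paired duplex region from a structure
#'
#' Restricts a structure to two chains and an inclusive author-numbering
#' window per chain, preserving residue order.  The selection window is
#' recorded in the returned structure's metadata so downstream reports can
#' state the averaging window.
#'
#' @param structure An `xna_structure`.
#' @param chain_pair Character vector of two chain ids.
#' @param residue_range Either a single `c(lo, hi)` applied to both chains
#'   or a list of two `c(lo, hi)` windows (one per chain).
#' @return An `xna_structure` containing only the selected residues.
#' @export
select_region <- function(structure, chain_pair, residue_range) {
  stopifnot(length(chain_pair) == 2)
  if (!is.list(residue_range)) residue_range <- list(residue_range,
                                                     residue_range)
  chains <- list()
  for (k in 1:2) {
    id <- chain_pair[k]
    ch <- structure$chains[[id]]
    if (is.null(ch)) stop("chain not found: ", id)
    rng <- residue_range[[k]]
    keep <- vapply(ch$residues, function(r)
      r$seq_id >= rng[1] && r$seq_id <= rng[2], logical(1))
    if (!any(keep)) stop("no residues of chain ", id, " in range [",
                         rng[1], ", ", rng[2], "]")
    chains[[id]] <- new_chain(id, ch$residues[keep], ch$polarity_label,
                              integer(0))
  }
  md <- structure$metadata
  md$provenance <- list(chains = chain_pair, windows = residue_range)
  new_structure(chains, structure$waters, md)
}

#' @export
print.xna_structure <- function(x, ...) {
  cat("<xna_structure>", if (!is.null(x$metadata$source))
    basename(x$metadata$source), "\n")
  for (ch in x$chains) {
    chems <- table(vapply(ch$residues, `[[`, "", "chemistry"))
    cat(sprintf("  chain %s: %d residues (%s), polarity %s\n",
                ch$chain_id, length(ch$residues),
                paste(names(chems), chems, sep = ":", collapse = ", "),
                ch$polarity_label))
  }
  cat(sprintf("  waters: %d\n", nrow(x$waters)))
  invisible(x)
}

#' Total non-water atom count per chain
#'
#' @param structure An `xna_structure`.
#' @return Named integer vector, one entry per chain.
#' @export
atom_counts <- function(structure) {
  vapply(structure$chains, function(ch)
    sum(vapply(ch$residues, function(r) nrow(r$atoms), integer(1))),
    integer(1))
}

## Look up a residue by chain id and author seq id.
get_residue <- function(structure, chain_id, seq_id) {
  ch <- structure$chains[[chain_id]]
  if (is.null(ch)) stop("chain not found: ", chain_id)
  for (r in ch$residues) if (r$seq_id == seq_id) return(r)
  stop("residue ", seq_id, " not found in chain ", chain_id)
}
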