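## Chemistry dictionary: expected atom sets, backbone linkage topology,
## torsion quadruples and donor/acceptor roles for each backbone chemistry.
##
## Backbone chemistries
##   ribose / deoxyribose : natural nucleotides, 5'->3' polarity,
##                          phosphodiester O3'(i)-P(i+1).
##   serinol              : SNA.  Acyclic three-carbon aminodiol backbone;
##                          the base is carried on an acetyl arm attached to
##                          the backbone nitrogen through an amide bond.
##   threoninol_L/_D      : aTNA.  As serinol with a methyl-bearing
##                          stereocenter (C7' methyl on C3').
##
## XNA atom naming used throughout (primed names, by analogy with ribose):
##   P, OP1, OP2, O1'  phosphate and its ester oxygen on C1'
##   C1'-C2'-C3'       acyclic backbone carbons (C2' carries the nitrogen)
##   O3'               hydroxyl/ester oxygen on C3' (bridges to next P)
##   N4'               backbone amide nitrogen on C2'
##   C5', O5'          amide carbonyl carbon and its carbonyl oxygen
##   C6'               methylene linking the amide to the base N9/N1
##   C7'               threoninol methyl on C3'
## The amide carbonyl oxygen O5' is a genuine carbonyl in SNA/aTNA (a CH-O
## acceptor), unlike the ester O5' of ribose backbones.

.BASES <- c("A", "C", "G", "U", "T", "BrU")
.PURINES <- c("A", "G")

base_atom_names <- function(base) {
  switch(base,
    A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
    C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
    T = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
    BrU = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6", "BR"),
    stop("unknown base: ", base)
  )
}

is_purine <- function(base) base %in% .PURINES

## Base treated as its pairing-relevant parent (BrU pairs as U).
pairing_base <- function(base) ifelse(base == "BrU", "U", base)

.quad <- function(names, offsets = c(0L, 0L, 0L, 0L)) {
  data.frame(name = names, offset = as.integer(offsets),
             stringsAsFactors = FALSE)
}

.ribose_entry <- function(deoxy = FALSE) {
  bb <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
          "C2'", "C1'")
  if (!deoxy) bb <- c(bb, "O2'")
  list(
    backbone_atoms = bb,
    marker_atoms = if (deoxy) c("C1'", "O4'", "C4'", "C2'", "C3'")
                   else c("C1'", "O4'", "C4'", "C2'", "O2'", "C3'"),
    forbidden_atoms = if (deoxy) c("O2'", "N4'") else "N4'",
    glycosidic_atom = "C1'",
    bridge = list(from = "O3'", to = "P"),   # O3'(i) -- P(i+1)
    polarity_label = "5'->3'",
    sugar_ring = c("C1'", "C2'", "C3'", "C4'", "O4'"),
    torsions = list(
      alpha   = .quad(c("O3'", "P", "O5'", "C5'"), c(-1L, 0L, 0L, 0L)),
      beta    = .quad(c("P", "O5'", "C5'", "C4'")),
      gamma   = .quad(c("O5'", "C5'", "C4'", "C3'")),
      delta   = .quad(c("C5'", "C4'", "C3'", "O3'")),
      epsilon = .quad(c("C4'", "C3'", "O3'", "P"), c(0L, 0L, 0L, 1L)),
      zeta    = .quad(c("C3'", "O3'", "P", "O5'"), c(0L, 0L, 1L, 1L))
    ),
    chi = list(
      purine = .quad(c("O4'", "C1'", "N9", "C4")),
      pyrimidine = .quad(c("O4'", "C1'", "N1", "C2"))
    ),
    amide = NULL,
    carbonyl_acceptors = character(0)
  )
}

.xna_entry <- function(chem) {
  bb <- c("P", "OP1", "OP2", "O1'", "C1'", "C2'", "C3'", "O3'",
          "N4'", "C5'", "O5'", "C6'")
  if (chem %in% c("threoninol_L", "threoninol_D")) bb <- c(bb, "C7'")
  list(
    backbone_atoms = bb,
    marker_atoms = c("N4'", "C5'", "O5'", "C6'",
                     if (chem %in% c("threoninol_L", "threoninol_D")) "C7'"),
    forbidden_atoms = c("O4'",
                        if (chem == "serinol") "C7'"),
    glycosidic_atom = "C6'",
    bridge = list(from = "O3'", to = "P"),   # O3'(i) -- P(i+1)
    polarity_label = if (chem == "serinol") "(S)->(R)" else "3'->1'",
    sugar_ring = NULL,
    torsions = list(
      alpha   = .quad(c("O3'", "P", "O1'", "C1'"), c(-1L, 0L, 0L, 0L)),
      beta    = .quad(c("P", "O1'", "C1'", "C2'")),
      gamma   = .quad(c("O1'", "C1'", "C2'", "C3'")),
      delta   = .quad(c("C1'", "C2'", "C3'", "O3'")),
      epsilon = .quad(c("C2'", "C3'", "O3'", "P"), c(0L, 0L, 0L, 1L)),
      zeta    = .quad(c("C3'", "O3'", "P", "O1'"), c(0L, 0L, 1L, 1L))
    ),
    ## no chi in the ribose sense; the base-attachment dihedral is reported
    ## as a named auxiliary angle instead (see torsion_profile)
    chi = NULL,
    base_attachment = list(
      purine = .quad(c("C5'", "C6'", "N9", "C4")),
      pyrimidine = .quad(c("C5'", "C6'", "N1", "C2"))
    ),
    amide = .quad(c("C6'", "C5'", "N4'", "C2'")),
    carbonyl_acceptors = "O5'"
  )
}

#' Default chemistry dictionary
#'
#' Builds the dictionary of expected atom names, backbone-bond topology,
#' torsion quadruples, donor/acceptor roles and glycosidic attachment atoms
#' for every supported (base, backbone chemistry) combination.  The
#' dictionary is plain data: it can be written to and re-read from an
#' editable YAML config with [write_chemistry_dictionary()] /
#' [read_chemistry_dictionary()], so that component naming in deposited
#' files that differs from the defaults can be accommodated without code
#' changes.
#'
#' @return A list of class `chemistry_dictionary` with elements
#'   `chemistries` (per-chemistry entries) and `bases` (supported base
#'   codes).
#' @export
#' @examples
#' dict <- default_chemistry_dictionary()
#' names(dict$chemistries)
default_chemistry_dictionary <- function() {
  out <- list(
    chemistries = list(
      ribose = .ribose_entry(FALSE),
      deoxyribose = .ribose_entry(TRUE),
      serinol = .xna_entry("serinol"),
      threoninol_L = .xna_entry("threoninol_L"),
      threoninol_D = .xna_entry("threoninol_D")
    ),
    bases = .BASES,
    match_threshold = 0.5
  )
  class(out) <- "chemistry_dictionary"
  out
}

is_xna_chemistry <- function(chem) {
  chem %in% c("serinol", "threoninol_L", "threoninol_D")
}

#' Expected atom names for a (base, chemistry) pair
#'
#' @param base Base code (`A`, `C`, `G`, `U`, `T`, `BrU`).
#' @param chemistry Backbone chemistry label.
#' @param dictionary A [default_chemistry_dictionary()]-style dictionary.
#' @return Character vector of atom names.
#' @export
expected_atoms <- function(base, chemistry,
                           dictionary = default_chemistry_dictionary()) {
  entry <- dictionary$chemistries[[chemistry]]
  if (is.null(entry)) stop("unknown chemistry: ", chemistry)
  c(entry$backbone_atoms, base_atom_names(base))
}

#' Classify the backbone chemistry of a residue
#'
#' Scores the residue's observed atom names against every chemistry's
#' expected backbone atom set and returns the best-matching label, or
#' `"unknown"` when no candidate reaches the dictionary's match threshold.
#' Ribose requires the O4'/C4' furanose ring atoms; the acyclic chemistries
#' require the amide triad N4'/C5'/O5'; threoninol additionally requires the
#' C7' methyl, and the L/D assignment is made from the chirality of the C3'
#' stereocenter (signed volume of the C2', O3', C7' substituents) when
#' coordinates permit.  The result is independent of atom order.
#'
#' @param residue A residue as produced by [read_structure()].
#' @param dictionary Chemistry dictionary.
#' @return A single chemistry label string.
#' @export
classify_chemistry <- function(residue,
                               dictionary = default_chemistry_dictionary()) {
  atoms <- residue$atoms
  if (nrow(atoms) < 3) return("unknown")
  observed <- unique(atoms$name)
  ## restrict scoring to backbone-candidate names (anything primed, P, OP*)
  scores <- vapply(names(dictionary$chemistries), function(chem) {
    entry <- dictionary$chemistries[[chem]]
    if (any(entry$forbidden_atoms %in% observed)) return(-1)
    markers <- entry$marker_atoms
    expected <- entry$backbone_atoms
    marker_frac <- mean(markers %in% observed)
    jac <- length(intersect(observed, expected)) /
      length(union(intersect(observed, c(expected, unlist(lapply(.BASES, base_atom_names)))), expected))
    0.7 * marker_frac + 0.3 * jac
  }, numeric(1))
  ## collapse the threoninol enantiomer pair before thresholding
  if (max(scores) < dictionary$match_threshold) return("unknown")
  best <- names(scores)[which.max(scores)]
  if (best %in% c("threoninol_L", "threoninol_D")) {
    best <- .threoninol_handedness(atoms)
  }
  best
}

## L/D assignment at the C3' stereocenter from the signed volume of the
## (C2', O3', C7') substituent triple.  Non-positive volume corresponds to
## the L configuration in the builder's template convention.
.threoninol_handedness <- function(atoms) {
  need <- c("C3'", "C2'", "O3'", "C7'")
  if (!all(need %in% atoms$name)) return("threoninol_L")
  p <- function(nm) {
    i <- match(nm, atoms$name)
    as.numeric(atoms[i, c("x", "y", "z")])
  }
  v <- det(cbind(p("C2'") - p("C3'"), p("O3'") - p("C3'"),
                 p("C7'") - p("C3'")))
  if (v <= 0) "threoninol_L" else "threoninol_D"
}

#' Write / read the chemistry dictionary as an editable config file
#'
#' The dictionary is serialized as YAML, one entry per backbone chemistry,
#' with torsion quadruples stored as (atom name, residue offset) rows.
#'
#' @param dictionary Dictionary to write.
#' @param path File path.
#' @return `read_chemistry_dictionary()` returns the dictionary;
#'   `write_chemistry_dictionary()` returns `path` invisibly.
#' @export
write_chemistry_dictionary <- function(dictionary, path) {
  x <- unclass(dictionary)
  ## flatten torsion data.frames for YAML
  x$chemistries <- lapply(x$chemistries, function(e) {
    e$torsions <- lapply(e$torsions, function(q) as.list(q))
    if (!is.null(e$chi)) e$chi <- lapply(e$chi, as.list)
    if (!is.null(e$base_attachment))
      e$base_attachment <- lapply(e$base_attachment, as.list)
    if (!is.null(e$amide)) e$amide <- as.list(e$amide)
    e
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_chemistry_dictionary
#' @export
read_chemistry_dictionary <- function(path) {
  x <- yaml::read_yaml(path)
  undf <- function(q) data.frame(name = unlist(q$name),
                                 offset = as.integer(unlist(q$offset)),
                                 stringsAsFactors = FALSE)
  x$chemistries <- lapply(x$chemistries, function(e) {
    e$torsions <- lapply(e$torsions, undf)
    if (!is.null(e$chi)) e$chi <- lapply(e$chi, undf)
    if (!is.null(e$base_attachment))
      e$base_attachment <- lapply(e$base_attachment, undf)
    if (!is.null(e$amide)) e$amide <- undf(e$amide)
    if (is.null(e$sugar_ring)) e$sugar_ring <- NULL
    e$marker_atoms <- unlist(e$marker_atoms)
    e$backbone_atoms <- unlist(e$backbone_atoms)
    e$forbidden_atoms <- as.character(unlist(e$forbidden_atoms))
    e$carbonyl_acceptors <- as.character(unlist(e$carbonyl_acceptors))
    e
  })
  class(x) <- "chemistry_dictionary"
  x
}
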