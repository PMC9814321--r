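## Oligomer molecular formulas and masses for RNA, SNA and L-aTNA strands
## and their non-covalent assemblies.
##
## Formula model: an oligomer with free hydroxyl termini is the sum of its
## nucleoside formulas plus (n - 1) phosphodiester bridges, each bridge
## contributing H3PO4 minus two condensation waters.  Nucleosides:
##   ribose        base + ribofuranose (C5H10O5) - H2O
##   deoxyribose   as ribose minus one oxygen
##   serinol       serinol (C3H9NO2) + base-acetic acid - H2O
##   threoninol    threoninol (C4H11NO2) + base-acetic acid - H2O
## where base-acetic acid is the nucleobase N-alkylated with CH2COOH
## (base + C2H2O2); 5-bromouridine substitutes Br for the uracil C5
## hydrogen (+Br, -H).
##
## The default mass convention is monoisotopic: the reported "calculated
## masses (singly charged states)" of the oligomers studied here are
## monoisotopic neutral masses (their strand values sum to the printed
## duplex and dimer values, confirming plain additivity).  Average masses
## and the [M-H]- convention are available via arguments.

.MONO_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                O = 15.9949146196, P = 30.97376163, Br = 78.9183371)
.AVG_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
               P = 30.973762, Br = 79.904)
.PROTON <- 1.007276466

.ELEMENTS <- names(.MONO_MASS)

formula_zero <- function() stats::setNames(rep(0, length(.ELEMENTS)),
                                           .ELEMENTS)

as_formula <- function(...) {
  v <- c(...)
  f <- formula_zero()
  f[names(v)] <- f[names(v)] + v
  f
}

formula_add <- function(a, b) a + b
formula_scale <- function(a, k) a * k

formula_string <- function(f) {
  f <- round(f)
  parts <- vapply(.ELEMENTS[f != 0], function(e)
    paste0(e, if (f[[e]] != 1) f[[e]] else ""), character(1))
  paste(parts, collapse = "")
}

.BASE_FORMULA <- list(
  A = as_formula(C = 5, H = 5, N = 5),
  G = as_formula(C = 5, H = 5, N = 5, O = 1),
  C = as_formula(C = 4, H = 5, N = 3, O = 1),
  U = as_formula(C = 4, H = 4, N = 2, O = 2),
  T = as_formula(C = 5, H = 6, N = 2, O = 2)
)
.BASE_FORMULA$BrU <- .BASE_FORMULA$U + as_formula(Br = 1, H = -1)

.H2O <- as_formula(H = 2, O = 1)
.H3PO4 <- as_formula(H = 3, P = 1, O = 4)
.RIBOSE <- as_formula(C = 5, H = 10, O = 5)
.SERINOL <- as_formula(C = 3, H = 9, N = 1, O = 2)
.THREONINOL <- as_formula(C = 4, H = 11, N = 1, O = 2)
.ACETIC_ARM <- as_formula(C = 2, H = 2, O = 2)

nucleoside_formula <- function(base, chemistry) {
  bf <- .BASE_FORMULA[[base]]
  if (is.null(bf)) stop("unknown base: ", base)
  switch(chemistry,
    rna = ,
    ribose = bf + .RIBOSE - .H2O,
    dna = ,
    deoxyribose = bf + .RIBOSE - .H2O - as_formula(O = 1),
    sna = ,
    serinol = bf + .ACETIC_ARM + .SERINOL - .H2O,
    latna = ,
    threoninol_L = ,
    threoninol_D = bf + .ACETIC_ARM + .THREONINOL - .H2O,
    stop("unsupported chemistry: ", chemistry)
  )
}

#' Monomer formula table
#'
#' Elemental formulas of internal residues (nucleoside plus one
#' phosphodiester bridge share, condensation losses folded in) for every
#' supported (base, chemistry) pair, with the terminal correction used for
#' free-hydroxyl termini.  Ships as plain data so modified entries can be
#' supplied to [oligomer_mass()].
#'
#' @return List with `residues` (data.frame of formulas) and
#'   `terminal_correction` (formula applied once per strand).
#' @export
monomer_mass_table <- function() {
  bridge <- .H3PO4 - 2 * .H2O
  combos <- expand.grid(base = names(.BASE_FORMULA),
                        chemistry = c("ribose", "deoxyribose", "serinol",
                                      "threoninol_L", "threoninol_D"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    f <- nucleoside_formula(combos$base[i], combos$chemistry[i]) + bridge
    cbind(combos[i, ], as.data.frame(as.list(f)))
  })
  list(residues = do.call(rbind, rows),
       terminal_correction = -bridge)
}

.mass_of <- function(formula, convention = c("monoisotopic", "average")) {
  convention <- match.arg(convention)
  w <- if (convention == "monoisotopic") .MONO_MASS else .AVG_MASS
  sum(w[names(formula)] * formula)
}

.CHEM_ALIAS <- c(rna = "ribose", dna = "deoxyribose", sna = "serinol",
                 latna = "threoninol_L", ribose = "ribose",
                 deoxyribose = "deoxyribose", serinol = "serinol",
                 threoninol_L = "threoninol_L",
                 threoninol_D = "threoninol_D")

#' Molecular formula and mass of an oligomer strand
#'
#' @param sequence Base sequence: string with `[BrU]` bracket tokens
#'   allowed, or a character vector of base codes.
#' @param chemistry Backbone chemistry: `"rna"`, `"dna"`, `"sna"`,
#'   `"latna"` or an explicit chemistry label.
#' @param termini Terminal state; only `"hydroxyl"` (free hydroxyls both
#'   ends, no terminal phosphate) is currently provided.
#' @param convention `"monoisotopic"` (default) or `"average"` atomic
#'   masses.
#' @param charge_state `"neutral"` (default) or `"deprotonated"`
#'   ([M-H]-).
#' @return List of class `mass_result` with `formula` (element counts),
#'   `formula_string`, `mass` (Da), `assembly = "single_strand"` and the
#'   call conventions.
#' @export
oligomer_mass <- function(sequence, chemistry = "rna",
                          termini = "hydroxyl",
                          convention = c("monoisotopic", "average"),
                          charge_state = c("neutral", "deprotonated")) {
  convention <- match.arg(convention)
  charge_state <- match.arg(charge_state)
  termini <- match.arg(termini, "hydroxyl")
  chem <- unname(.CHEM_ALIAS[chemistry])
  if (is.na(chem)) stop("unsupported chemistry: ", chemistry)
  bases <- parse_sequence(sequence)
  if (!length(bases)) stop("empty sequence")
  if (length(bases) < 1) stop("empty sequence")
  f <- formula_zero()
  for (b in bases) f <- f + nucleoside_formula(b, chem)
  f <- f + (length(bases) - 1) * (.H3PO4 - 2 * .H2O)
  mass <- .mass_of(f, convention)
  if (charge_state == "deprotonated") mass <- mass - .PROTON
  structure(list(formula = f, formula_string = formula_string(f),
                 mass = mass, assembly = "single_strand",
                 n_residues = length(bases), convention = convention,
                 charge_state = charge_state),
            class = "mass_result")
}

#' Mass of a non-covalent assembly of strands
#'
#' Sums component strand masses (and formulas) without condensation loss,
#' as appropriate for duplexes and dimers of duplexes held together by
#' base pairing.
#'
#' @param strands List of `mass_result` objects (or a single one).
#' @param stoichiometry Integer multiplier per strand (recycled).
#' @return A `mass_result` with `assembly` set to `"duplex"`,
#'   `"dimer_of_duplex"` or `"assembly"` according to the total strand
#'   count.
#' @export
assembly_mass <- function(strands, stoichiometry = 1L) {
  if (inherits(strands, "mass_result")) strands <- list(strands)
  if (!length(strands)) stop("need at least one strand")
  stoich <- rep_len(as.integer(stoichiometry), length(strands))
  f <- formula_zero()
  mass <- 0
  for (i in seq_along(strands)) {
    f <- f + stoich[i] * strands[[i]]$formula
    mass <- mass + stoich[i] * strands[[i]]$mass
  }
  total <- sum(stoich)
  assembly <- if (total == 1) "single_strand"
              else if (total == 2) "duplex"
              else if (total == 4) "dimer_of_duplex" else "assembly"
  structure(list(formula = f, formula_string = formula_string(f),
                 mass = mass, assembly = assembly,
                 n_strands = total,
                 convention = strands[[1]]$convention,
                 charge_state = strands[[1]]$charge_state),
            class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("<mass_result> %s  %s  %.1f Da (%s, %s)\n", x$assembly,
              x$formula_string, x$mass, x$convention, x$charge_state))
  invisible(x)
}
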