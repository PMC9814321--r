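## The central fitting interface: fit base reference frames to a duplex
## and derive its step/helical parameter profile, in the classic
## model-object idiom.

#' Fit the helical geometry of a nucleic acid duplex
#'
#' Fits least-squares base reference frames to every residue, detects (or
#' accepts) Watson-Crick base pairs between the two strands, forms pair
#' frames and computes the twelve local step/helical parameters per
#' dinucleotide step together with a duplex summary (residues per turn,
#' helical pitch, minor-groove width).
#'
#' @param structure An `xna_structure` (from [read_structure()] or
#'   [build_duplex()]).
#' @param chains Two chain ids forming the duplex; defaults to the first
#'   two chains.
#' @param window Optional inclusive seq-id window (one `c(lo, hi)` or a
#'   list of two, per chain) restricting the analysis, recorded as the
#'   averaging-window provenance.
#' @param pairs Optional precomputed pair table (as [detect_pairs()]);
#'   when omitted, Watson-Crick pairs are detected.
#' @param criteria [pairing_criteria()] used when detecting pairs.
#' @return Object of class `helix_fit` with components `frames`, `pairs`,
#'   `pair_frames`, `steps` (data.frame), `summary` (a `helix_summary`),
#'   `groove`, `chains`, `window` and `call`.  Methods: `print`,
#'   `summary`, `coef` (mean helical parameters), `residuals` (per-residue
#'   frame fit RMSDs), `plot`, `simulate` (synthetic duplex rebuilt from
#'   the fitted means).
#' @export
#' @examples
#' dup <- build_duplex(build_spec("GCGCGC", "ribose",
#'   helical = list(helical_twist = 32, helical_rise = 2.9)))
#' fit <- helix_fit(dup)
#' coef(fit)["helical_twist"]
helix_fit <- function(structure, chains = NULL, window = NULL,
                      pairs = NULL, criteria = pairing_criteria()) {
  cl <- match.call()
  if (is.null(chains)) chains <- names(structure$chains)[1:2]
  if (any(is.na(chains)) || length(chains) < 2)
    stop("helix_fit needs a two-chain duplex")
  sel <- structure
  if (!is.null(window)) sel <- select_region(structure, chains, window)
  frames <- fit_frames(sel)
  if (is.null(pairs)) {
    pairs <- detect_pairs(sel, frames, criteria)
    pairs <- pairs[pairs$pair_class == "watson_crick" &
                     ((pairs$chain_i == chains[1] &
                         pairs$chain_j == chains[2]) |
                      (pairs$chain_i == chains[2] &
                         pairs$chain_j == chains[1])), , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no Watson-Crick pairs found between chains ",
                         chains[1], " and ", chains[2])
  ## orient every pair as (chain1, chain2) and order along chain 1
  flip_rows <- pairs$chain_i != chains[1]
  if (any(flip_rows)) {
    tmp <- pairs[flip_rows, c("chain_j", "seq_j", "base_j")]
    pairs[flip_rows, c("chain_j", "seq_j", "base_j")] <-
      pairs[flip_rows, c("chain_i", "seq_i", "base_i")]
    pairs[flip_rows, c("chain_i", "seq_i", "base_i")] <- tmp
  }
  ord <- order(match(paste0(pairs$chain_i, ":", pairs$seq_i),
                     vapply(sel$chains[[chains[1]]]$residues,
                            function(r) paste0(r$chain_id, ":", r$seq_id),
                            character(1))))
  pairs <- pairs[ord, , drop = FALSE]
  pfr <- lapply(seq_len(nrow(pairs)), function(k) {
    fi <- frames[[paste0(pairs$chain_i[k], ":", pairs$seq_i[k])]]
    fj <- frames[[paste0(pairs$chain_j[k], ":", pairs$seq_j[k])]]
    if (is.null(fi) || is.null(fj)) return(NULL)
    pair_frame(fi, fj)
  })
  keep <- !vapply(pfr, is.null, logical(1))
  pairs <- pairs[keep, , drop = FALSE]
  pfr <- pfr[keep]
  steps <- if (length(pfr) >= 2) step_series(pfr) else NULL
  groove <- minor_groove_width(structure, chains, window)
  summ <- if (!is.null(steps))
    summarize_helix(steps, window = window,
                    minor_groove = groove$width) else NULL
  structure(list(structure = sel, frames = frames, pairs = pairs,
                 pair_frames = pfr, steps = steps, summary = summ,
                 groove = groove, chains = chains, window = window,
                 call = cl),
            class = "helix_fit")
}

#' @export
print.helix_fit <- function(x, ...) {
  cat("Duplex helical geometry fit\n")
  cat("  chains:", paste(x$chains, collapse = " / "),
      if (!is.null(x$window))
        paste0("  window: ", paste(unlist(x$window), collapse = "-")),
      "\n")
  cat("  base pairs:", nrow(x$pairs), "  steps:",
      if (is.null(x$steps)) 0 else nrow(x$steps), "\n")
  if (!is.null(x$summary)) {
    cat(sprintf("  mean helical twist %.1f deg, rise %.2f A, %.1f nt/turn\n",
                x$summary$mean[["helical_twist"]],
                x$summary$mean[["helical_rise"]],
                x$summary$residues_per_turn))
  }
  invisible(x)
}

#' @export
summary.helix_fit <- function(object, ...) {
  if (is.null(object$summary)) stop("fit has fewer than two steps")
  object$summary
}

#' @export
coef.helix_fit <- function(object, ...) {
  if (is.null(object$summary)) stop("fit has fewer than two steps")
  c(object$summary$mean,
    residues_per_turn = object$summary$residues_per_turn,
    helical_pitch = object$summary$helical_pitch,
    minor_groove = if (is.null(object$summary$minor_groove)) NA_real_
                   else object$summary$minor_groove)
}

#' @export
residuals.helix_fit <- function(object, ...) {
  vapply(object$frames, `[[`, numeric(1), "fit_rmsd")
}

#' @export
plot.helix_fit <- function(x, which = c("helical_twist", "helical_rise",
                                        "x_displacement"), ...) {
  if (is.null(x$steps)) stop("nothing to plot: fewer than two steps")
  which <- intersect(which, names(x$steps))
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in which) {
    graphics::plot(x$steps$step, x$steps[[p]], type = "b", xlab = "step",
                   ylab = p, ...)
    graphics::abline(h = x$summary$mean[[p]], lty = 2)
  }
  invisible(x)
}

#' Simulate a synthetic duplex from a fitted geometry
#'
#' Rebuilds an ideal duplex with the fit's mean helical parameters (same
#' length and strand-1 sequence) through the synthetic builder, optionally
#' with coordinate noise — the generative counterpart of the fit.
#'
#' @param object A `helix_fit`.
#' @param nsim Number of structures.
#' @param seed Integer seed.
#' @param sigma Gaussian noise SD in Angstrom (default 0).
#' @param ... Unused.
#' @return A list of `xna_structure`s (length `nsim`).
#' @export
simulate.helix_fit <- function(object, nsim = 1, seed = NULL, sigma = 0,
                               ...) {
  if (is.null(object$summary)) stop("fit has fewer than two steps")
  m <- object$summary$mean
  seq1 <- object$pairs$base_i
  ch <- object$structure$chains[[object$chains[1]]]
  chem <- ch$residues[[1]]$chemistry
  chem2 <- object$structure$chains[[object$chains[2]]]$residues[[1]]$chemistry
  lapply(seq_len(nsim), function(k) {
    build_duplex(build_spec(
      seq1, c(chem, chem2),
      helical = list(helical_twist = m[["helical_twist"]],
                     helical_rise = m[["helical_rise"]],
                     x_displacement = m[["x_displacement"]],
                     y_displacement = m[["y_displacement"]],
                     inclination = m[["inclination"]],
                     tip = m[["tip"]]),
      sigma = sigma,
      seed = if (is.null(seed)) NULL else seed + k - 1L))
  })
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Reads (or accepts) a structure, runs frame fitting, pair detection,
#' step/helical summary, per-chain torsion profiles with sugar pucker and
#' amide configuration, P-P distances, minor-groove width and CH-O
#' contacts, and optionally writes TSV tables plus a JSON report with
#' provenance (windows, parameters, package version).
#'
#' @param input Path to a coordinate file or an `xna_structure`.
#' @param chains Two chain ids (default: first two).
#' @param window Optional averaging window (see [helix_fit()]).
#' @param out_dir Optional output directory for the report bundle.
#' @param contact_scheme Scheme for [find_ch_o_contacts()].
#' @param criteria Pairing criteria.
#' @return List of class `duplex_report` with `fit`, `pairs`, `torsions`
#'   (per chain), `torsion_summaries`, `contacts`, `groove` and
#'   `provenance`.
#' @export
analyze_duplex <- function(input, chains = NULL, window = NULL,
                           out_dir = NULL,
                           contact_scheme = default_contact_scheme(),
                           criteria = pairing_criteria()) {
  st <- if (inherits(input, "xna_structure")) input
        else read_structure(input)
  if (is.null(chains)) chains <- names(st$chains)[1:2]
  fit <- helix_fit(st, chains, window, criteria = criteria)
  all_pairs <- detect_pairs(st, fit$frames, criteria)
  torsions <- lapply(st$chains[chains], torsion_profile)
  tsumm <- lapply(torsions, torsion_summary,
                  window = if (is.list(window)) NULL else window)
  contacts <- find_ch_o_contacts(st, contact_scheme)
  prov <- list(
    source = st$metadata$source, chains = chains,
    window = window,
    package_version = as.character(utils::packageVersion("xnahelix")),
    parameters = list(pairing = criteria,
                      contact_cutoff = contact_scheme$cutoff,
                      contact_extended = contact_scheme$extended_range)
  )
  report <- structure(list(fit = fit, pairs = all_pairs,
                           torsions = torsions,
                           torsion_summaries = tsumm,
                           contacts = contacts, groove = fit$groove,
                           provenance = prov),
                      class = "duplex_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.duplex_report <- function(x, ...) {
  print(x$fit)
  cat("  all pairs:", nrow(x$pairs),
      sprintf("(%d WC, %d Hoogsteen)\n",
              sum(x$pairs$pair_class == "watson_crick"),
              sum(x$pairs$pair_class == "hoogsteen")))
  cat("  CH-O contacts:", nrow(x$contacts), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits pair, step, torsion and contact TSV tables plus a JSON summary
#' with provenance.  Deterministic for identical inputs (no timestamps).
#'
#' @param report A `duplex_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs_tsv(report$pairs, file.path(out_dir, "pairs.tsv"))
  if (!is.null(report$fit$steps))
    utils::write.table(report$fit$steps, file.path(out_dir, "steps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (ch in names(report$torsions))
    utils::write.table(report$torsions[[ch]],
                       file.path(out_dir, paste0("torsions_", ch, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_contacts_tsv(report$contacts, file.path(out_dir, "contacts.tsv"))
  summ <- report$fit$summary
  json <- list(
    provenance = report$provenance,
    helix = if (!is.null(summ)) list(
      mean = as.list(summ$mean), sd = as.list(summ$sd),
      n_steps = summ$n_steps,
      residues_per_turn = summ$residues_per_turn,
      helical_pitch = summ$helical_pitch,
      minor_groove = summ$minor_groove
    ),
    torsion_summaries = report$torsion_summaries,
    n_pairs = nrow(report$pairs),
    n_contacts = nrow(report$contacts)
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
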