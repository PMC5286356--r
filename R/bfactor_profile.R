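# B-factor "fulcrum" profiling: displacement parameters versus distance
# from the interface anchor residues.

#' B-factor of a single atom
#'
#' @param model A `structure_model` or atom tibble.
#' @param selector Atom selector string (`"chain/resseq/name"`).
#' @return The stored isotropic B (Angstrom^2).
#' @export
atom_bfactor <- function(model, selector) {
  atoms <- if (inherits(model, "structure_model")) model$atoms else model
  hit <- resolve_selector(atoms, selector)
  if (nrow(hit) == 0) stop("no atom matches selector: ", selector)
  if (nrow(hit) > 1) {
    hit <- dplyr::filter(hit, .data$altloc %in% c("", "A"))
    if (nrow(hit) != 1) stop("ambiguous selector: ", selector)
  }
  hit$bfactor
}

#' Mean B-factor of a selection
#'
#' Arithmetic, occupancy-unweighted mean over the atoms.
#'
#' @param selection Atom tibble (non-empty).
#' @return Mean B in Angstrom^2.
#' @export
mean_b <- function(selection) {
  if (nrow(selection) == 0) stop("mean_b: empty selection")
  mean(selection$bfactor)
}

#' Fulcrum profile: B-factor versus distance from anchors
#'
#' For every atom of a selection, the distance to the nearest anchor atom is
#' paired with its B-factor. A rising trend indicates rigid-body-like
#' rocking about the anchoring contacts. The trend is summarized by the
#' Spearman rank correlation (monotonicity, not linearity, is the claim) and
#' by mean B in distance bins, with a least-squares slope over the binned
#' means as a gradient estimate.
#'
#' @param atoms Protein atom tibble.
#' @param anchors Anchor atom tibble (e.g. the interface-forming side-chain
#'   atoms); non-empty.
#' @param bin_width Distance bin width in Angstrom (default 5).
#' @return A `fulcrum_profile`: list with `per_atom` tibble (`atom`,
#'   `distance`, `bfactor`), `spearman`, `bins` (binned mean B),
#'   `slope` (Angstrom^2 per Angstrom from the binned means), `n` and
#'   `unreliable` flag (fewer than 10 atoms).
#' @export
fulcrum_profile <- function(atoms, anchors, bin_width = 5) {
  if (nrow(anchors) == 0) stop("fulcrum_profile: empty anchor selection")
  if (nrow(atoms) == 0) stop("fulcrum_profile: empty atom selection")
  # round to 1e-6 A so exact ties keep identical ranks under rigid motion
  dist <- round(min_dist_to(atoms, anchors), 6)
  per_atom <- tibble::tibble(atom = atom_id(atoms), distance = dist,
                             bfactor = atoms$bfactor)
  rho <- if (stats::sd(per_atom$bfactor) == 0 ||
             stats::sd(per_atom$distance) == 0) 0 else
    suppressWarnings(stats::cor(per_atom$distance, per_atom$bfactor,
                                method = "spearman"))
  breaks <- seq(0, max(dist) + bin_width, by = bin_width)
  bins <- per_atom |>
    dplyr::mutate(bin = cut(.data$distance, breaks, right = FALSE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mid = mean(.data$distance), n = dplyr::n(),
                     mean_b = mean(.data$bfactor), .groups = "drop")
  slope <- if (nrow(bins) >= 2) {
    unname(stats::coef(stats::lm(mean_b ~ mid, data = bins))[2])
  } else NA_real_
  structure(list(per_atom = per_atom, spearman = rho, bins = bins,
                 slope = slope, n = nrow(per_atom),
                 anchors = atom_id(anchors),
                 unreliable = nrow(per_atom) < 10),
            class = "fulcrum_profile")
}

#' @export
print.fulcrum_profile <- function(x, ...) {
  cat(sprintf(
    "<fulcrum_profile> %d atoms, %d anchors; Spearman rho = %.3f%s\n",
    x$n, length(x$anchors), x$spearman,
    if (x$unreliable) " (unreliable: < 10 atoms)" else ""))
  if (!is.na(x$slope)) {
    cat(sprintf("  binned-mean B gradient: %.3f A^2/A\n", x$slope))
  }
  invisible(x)
}
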