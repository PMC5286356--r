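# Declaring and extracting one biological complex from a structure.

#' Declare the members of a two-protein complex
#'
#' Names which chains form the donor-side protein (A), which form the
#' acceptor-side protein (B), how waters are picked up, and where the
#' redox cofactors and the donor/acceptor atoms of an electron-transfer
#' pair live.
#'
#' @param chains_A,chains_B Character vectors of chain identifiers; must be
#'   disjoint.
#' @param water_chains Optional chain restriction for waters. By default all
#'   waters in the file (resname HOH/WAT/DOD) are pooled, whatever their
#'   chain, and interface membership is decided geometrically.
#' @param cofactors_A,cofactors_B Character vectors of hetero residue names
#'   that belong with each protein (e.g. `"HEC"` for covalently bound heme c).
#' @param donor_atom,acceptor_atom Atom selector strings
#'   (`"chain/resseq/name"`) for the tunneling endpoints; optional.
#' @param keep_altloc Alternate-location codes retained for geometry
#'   (default: blank and `"A"`).
#' @return A `complex_spec` object.
#' @export
complex_spec <- function(chains_A, chains_B, water_chains = NULL,
                         cofactors_A = character(0),
                         cofactors_B = character(0),
                         donor_atom = NULL, acceptor_atom = NULL,
                         keep_altloc = c("", "A")) {
  if (length(intersect(chains_A, chains_B)) > 0) {
    stop("chains_A and chains_B must be disjoint")
  }
  structure(list(chains_A = chains_A, chains_B = chains_B,
                 water_chains = water_chains,
                 cofactors_A = cofactors_A, cofactors_B = cofactors_B,
                 donor_atom = donor_atom, acceptor_atom = acceptor_atom,
                 keep_altloc = keep_altloc),
            class = "complex_spec")
}

#' Read a complex declaration from a YAML file
#'
#' Schema: keys `chains_A`, `chains_B` (required, lists of chain ids) and
#' optional `water_chains`, `cofactors_A`, `cofactors_B`, `donor_atom`,
#' `acceptor_atom`, `keep_altloc`.
#'
#' @param path YAML file path.
#' @return A `complex_spec`.
#' @export
read_complex_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chains_A) || is.null(cfg$chains_B)) {
    stop("complex spec must define chains_A and chains_B")
  }
  complex_spec(
    chains_A = as.character(cfg$chains_A),
    chains_B = as.character(cfg$chains_B),
    water_chains = if (!is.null(cfg$water_chains))
      as.character(cfg$water_chains),
    cofactors_A = as.character(cfg$cofactors_A %||% character(0)),
    cofactors_B = as.character(cfg$cofactors_B %||% character(0)),
    donor_atom = cfg$donor_atom, acceptor_atom = cfg$acceptor_atom,
    keep_altloc = as.character(cfg$keep_altloc %||% c("", "A")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the members of a complex
#'
#' Splits a structure into the two protein selections, the pooled waters and
#' the cofactor groups named by the spec. Alternate conformers other than
#' those in `spec$keep_altloc` are dropped from every selection, so each
#' physical atom appears once.
#'
#' Cofactor atoms whose residue name is listed in `cofactors_A`/`cofactors_B`
#' are part of the corresponding protein selection (they travel with it in
#' surface and distance work) and are additionally returned separately.
#'
#' @param model A `structure_model`.
#' @param spec A [complex_spec()].
#' @return A `complex_selection`: list with atom tibbles `A`, `B`, `waters`,
#'   `cofactors` (`$A`, `$B`) and resolved `donor` / `acceptor` atom rows
#'   (or `NULL`).
#' @export
select_complex <- function(model, spec) {
  stopifnot(inherits(model, "structure_model"), inherits(spec, "complex_spec"))
  atoms <- model$atoms
  have <- unique(atoms$chain)
  absent <- setdiff(c(spec$chains_A, spec$chains_B), have)
  if (length(absent) > 0) {
    stop("chains not present in model: ", paste(absent, collapse = ", "))
  }
  atoms <- dplyr::filter(atoms, .data$altloc %in% spec$keep_altloc)
  waters <- dplyr::filter(atoms, .data$is_water)
  if (!is.null(spec$water_chains)) {
    waters <- dplyr::filter(waters, .data$chain %in% spec$water_chains)
  }
  side <- function(chains, cof) {
    dplyr::filter(atoms, !.data$is_water, .data$chain %in% chains,
                  !.data$is_hetero | .data$resname %in% cof)
  }
  A <- side(spec$chains_A, spec$cofactors_A)
  B <- side(spec$chains_B, spec$cofactors_B)
  if (nrow(A) == 0) stop("empty selection for protein A")
  if (nrow(B) == 0) stop("empty selection for protein B")
  resolve_one <- function(sel, pool, what) {
    if (is.null(sel)) return(NULL)
    hit <- resolve_selector(pool, sel)
    if (nrow(hit) == 0) stop(what, " atom not found: ", sel)
    if (nrow(hit) > 1) stop(what, " selector ambiguous: ", sel)
    hit
  }
  structure(list(
    A = A, B = B, waters = waters,
    cofactors = list(
      A = dplyr::filter(A, .data$resname %in% spec$cofactors_A),
      B = dplyr::filter(B, .data$resname %in% spec$cofactors_B)),
    donor = resolve_one(spec$donor_atom, A, "donor"),
    acceptor = resolve_one(spec$acceptor_atom, B, "acceptor"),
    spec = spec), class = "complex_selection")
}

#' Pick the lower-B copy of a duplicated complex
#'
#' Crystals often carry more than one copy of the same complex in the
#' asymmetric unit; descriptive analyses conventionally use the copy with
#' the lower mean B-factor. Given candidate chain-set pairs, returns the
#' index of the copy whose combined protein atoms have the lowest mean B.
#'
#' @param model A `structure_model`.
#' @param copies List of lists, each with elements `chains_A`, `chains_B`.
#' @return Integer index into `copies`.
#' @export
pick_lower_b_copy <- function(model, copies) {
  stopifnot(length(copies) >= 1)
  means <- vapply(copies, function(cp) {
    sel <- dplyr::filter(model$atoms, !.data$is_water,
                         .data$chain %in% c(cp$chains_A, cp$chains_B))
    if (nrow(sel) == 0) return(Inf)
    mean(sel$bfactor)
  }, numeric(1))
  which.min(means)
}
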