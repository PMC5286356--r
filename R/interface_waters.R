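# Interfacial-water triage and the water hydrogen-bond network.
#
# A water "interacts" with a protein when its oxygen lies strictly within
# `cutoff` (default 3.5 A) of any protein atom; interface membership asks for
# the oxygen to be within `shell` (default 7 A) of BOTH proteins. The three
# resulting classes -- bridging, non-bridging (one side) and non-interacting
# (neither side, but inside the shell) -- partition the interface waters.

water_oxygens <- function(waters) {
  w <- dplyr::filter(waters, .data$element == "O")
  w$water_id <- atom_id(w)
  w
}

min_dist_to <- function(points, target) {
  if (nrow(target) == 0) return(rep(Inf, nrow(points)))
  sqrt(apply(cross_dist2(xyz_matrix(points), xyz_matrix(target)), 1, min))
}

#' Select waters inside the two-sided interface shell
#'
#' Keeps waters whose oxygen is within `shell` of at least one atom of A
#' *and* at least one atom of B.
#'
#' @param waters Water atom tibble (the oxygen rows are used).
#' @param atoms_A,atoms_B Protein atom tibbles.
#' @param shell Shell radius in Angstrom (default 7).
#' @return Tibble of interface water oxygens with `water_id`, `d_min_A`,
#'   `d_min_B` columns added.
#' @export
select_interface_waters <- function(waters, atoms_A, atoms_B, shell = 7) {
  if (nrow(atoms_A) == 0 || nrow(atoms_B) == 0) {
    stop("select_interface_waters: empty protein selection")
  }
  w <- water_oxygens(waters)
  if (nrow(w) == 0) return(dplyr::mutate(w, d_min_A = numeric(0),
                                         d_min_B = numeric(0)))
  w$d_min_A <- min_dist_to(w, atoms_A)
  w$d_min_B <- min_dist_to(w, atoms_B)
  dplyr::filter(w, .data$d_min_A <= shell, .data$d_min_B <= shell)
}

WATER_CATEGORIES <- c("bridging", "nonbridging_A", "nonbridging_B",
                      "noninteracting")

#' Classify interface waters
#'
#' Assigns each interface water to one of four exclusive categories using the
#' strict `< cutoff` interaction rule on its nearest-atom distances to each
#' protein: `bridging` (both sides), `nonbridging_A` / `nonbridging_B` (one
#' side) or `noninteracting` (neither; boundary equality counts as
#' non-interacting).
#'
#' @param interface_waters Output of [select_interface_waters()].
#' @param atoms_A,atoms_B Protein atom tibbles (used to refresh distances if
#'   the input lacks them).
#' @param cutoff Interaction cutoff in Angstrom (default 3.5).
#' @return A `water_census` tibble: one row per water with `water_id`,
#'   coordinates, `bfactor`, `d_min_A`, `d_min_B` and `category` (factor).
#' @export
classify_waters <- function(interface_waters, atoms_A, atoms_B, cutoff = 3.5) {
  w <- interface_waters
  if (!all(c("d_min_A", "d_min_B") %in% names(w))) {
    w <- water_oxygens(w)
    w$d_min_A <- min_dist_to(w, atoms_A)
    w$d_min_B <- min_dist_to(w, atoms_B)
  }
  inA <- w$d_min_A < cutoff
  inB <- w$d_min_B < cutoff
  w$category <- factor(
    dplyr::case_when(inA & inB ~ "bridging",
                     inA & !inB ~ "nonbridging_A",
                     !inA & inB ~ "nonbridging_B",
                     TRUE ~ "noninteracting"),
    levels = WATER_CATEGORIES)
  out <- tibble::new_tibble(w, class = "water_census")
  attr(out, "cutoff") <- cutoff
  out
}

#' Per-water contact profile
#'
#' For each classified water, counts protein polar atoms (N/O), protein
#' non-polar atoms (C/S) and other water oxygens strictly within `cutoff`,
#' and tallies which residue types the waters touch on each protein.
#'
#' @param census A `water_census`.
#' @param atoms_A,atoms_B Protein atom tibbles.
#' @param waters Full water tibble (for water-water contacts; the census
#'   waters themselves are used if omitted).
#' @param cutoff Contact cutoff in Angstrom (default 3.5, same as the
#'   interaction rule).
#' @return List with `per_water` (census plus `n_polar_contacts`,
#'   `n_nonpolar_contacts`, `n_water_contacts`), `by_category` (mean
#'   polar-or-water and non-polar contacts per category) and `residue_tally`
#'   (side, resname, n).
#' @export
water_contact_profile <- function(census, atoms_A, atoms_B, waters = NULL,
                                  cutoff = 3.5) {
  w <- census
  wat <- if (is.null(waters)) w else water_oxygens(waters)
  prot <- dplyr::bind_rows(dplyr::mutate(atoms_A, .side = "A"),
                           dplyr::mutate(atoms_B, .side = "B"))
  polar <- dplyr::filter(prot, .data$element %in% c("N", "O"))
  nonpolar <- dplyr::filter(prot, .data$element %in% c("C", "S"))
  count_within <- function(target) {
    if (nrow(target) == 0 || nrow(w) == 0) return(integer(nrow(w)))
    d <- sqrt(cross_dist2(xyz_matrix(w), xyz_matrix(target)))
    as.integer(rowSums(d < cutoff))
  }
  n_polar <- count_within(polar)
  n_nonpolar <- count_within(nonpolar)
  # water-water: exclude self-distance (0)
  n_water <- if (nrow(wat) == 0 || nrow(w) == 0) integer(nrow(w)) else {
    d <- sqrt(cross_dist2(xyz_matrix(w), xyz_matrix(wat)))
    as.integer(rowSums(d < cutoff & d > 1e-6))
  }
  per_water <- dplyr::mutate(tibble::as_tibble(w),
                             n_polar_contacts = n_polar,
                             n_nonpolar_contacts = n_nonpolar,
                             n_water_contacts = n_water)
  by_category <- per_water |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_polar_or_water = mean(.data$n_polar_contacts +
                                   .data$n_water_contacts),
      mean_nonpolar = mean(.data$n_nonpolar_contacts),
      .groups = "drop")
  tally <- if (nrow(polar) == 0 || nrow(w) == 0) {
    tibble::tibble(side = character(0), resname = character(0),
                   n = integer(0))
  } else {
    d <- sqrt(cross_dist2(xyz_matrix(w), xyz_matrix(prot)))
    hits <- which(d < cutoff, arr.ind = TRUE)
    if (nrow(hits) == 0) {
      tibble::tibble(side = character(0), resname = character(0),
                     n = integer(0))
    } else {
      tibble::tibble(side = prot$.side[hits[, 2]],
                     resname = prot$resname[hits[, 2]]) |>
        dplyr::count(.data$side, .data$resname, sort = TRUE)
    }
  }
  list(per_water = per_water, by_category = by_category,
       residue_tally = tally)
}

#' Build the interface hydrogen-bond network
#'
#' Heavy-atom network: nodes are the census water oxygens plus every protein
#' N/O atom within `hb_cutoff` of a census water; edges join water-water and
#' water-protein pairs at distance `<= hb_cutoff`. No angle term is applied
#' (deposited waters carry no hydrogens). Reports whether a path of edges
#' links a protein-A node to a protein-B node.
#'
#' @param census A `water_census`.
#' @param atoms_A,atoms_B Protein atom tibbles.
#' @param hb_cutoff Hydrogen-bond heavy-atom cutoff (default 3.5 A).
#' @return An `hbond_network`: list with `nodes`, `edges` tibbles, the
#'   `igraph` object, `components` membership and `connects_AB` flag.
#' @export
build_hbond_network <- function(census, atoms_A, atoms_B, hb_cutoff = 3.5) {
  w <- tibble::as_tibble(census)
  polar <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(atoms_A, .data$element %in% c("N", "O")),
                  node_kind = "protein_A"),
    dplyr::mutate(dplyr::filter(atoms_B, .data$element %in% c("N", "O")),
                  node_kind = "protein_B"))
  polar$node_id <- paste0(polar$node_kind, ":", atom_id(polar))
  w$node_id <- paste0("water:", w$water_id)
  edges <- list()
  if (nrow(w) > 1) {
    d <- sqrt(cross_dist2(xyz_matrix(w), xyz_matrix(w)))
    hits <- which(d <= hb_cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hits) > 0) {
      edges[["ww"]] <- tibble::tibble(from = w$node_id[hits[, 1]],
                                      to = w$node_id[hits[, 2]],
                                      distance = d[hits],
                                      kind = "water_water")
    }
  }
  keep_polar <- polar[0, ]
  if (nrow(polar) > 0 && nrow(w) > 0) {
    d <- sqrt(cross_dist2(xyz_matrix(w), xyz_matrix(polar)))
    hits <- which(d <= hb_cutoff, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      edges[["wp"]] <- tibble::tibble(from = w$node_id[hits[, 1]],
                                      to = polar$node_id[hits[, 2]],
                                      distance = d[hits],
                                      kind = "water_protein")
      keep_polar <- polar[sort(unique(hits[, 2])), ]
    }
  }
  edges <- dplyr::bind_rows(edges)
  nodes <- dplyr::bind_rows(
    tibble::tibble(node_id = w$node_id, node_kind = "water",
                   x = w$x, y = w$y, z = w$z),
    tibble::tibble(node_id = keep_polar$node_id,
                   node_kind = keep_polar$node_kind,
                   x = keep_polar$x, y = keep_polar$y, z = keep_polar$z))
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0) edges else
      tibble::tibble(from = character(0), to = character(0)),
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)$membership
  a_comp <- unique(comp[nodes$node_kind == "protein_A"])
  b_comp <- unique(comp[nodes$node_kind == "protein_B"])
  structure(list(nodes = nodes, edges = edges, graph = g,
                 components = comp,
                 connects_AB = length(intersect(a_comp, b_comp)) > 0,
                 hb_cutoff = hb_cutoff),
            class = "hbond_network")
}

#' @export
print.hbond_network <- function(x, ...) {
  cat("<hbond_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (cutoff ", x$hb_cutoff, " A)\n", sep = "")
  cat("  links protein A to protein B: ", x$connects_AB, "\n", sep = "")
  invisible(x)
}

#' B-factor statistics of classified waters
#'
#' Arithmetic mean B per category plus the overall mean. Categories with no
#' members are absent from the table (not reported as zero).
#'
#' @param census A `water_census`.
#' @return Tibble with `category`, `n`, `mean_b`; the final row (`"all"`)
#'   covers every interface water.
#' @export
water_bfactor_stats <- function(census) {
  w <- tibble::as_tibble(census)
  per_cat <- w |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::left_join(
      w |> dplyr::group_by(.data$category) |>
        dplyr::summarise(mean_b = mean(.data$bfactor), .groups = "drop"),
      by = "category") |>
    dplyr::mutate(category = as.character(.data$category))
  dplyr::bind_rows(per_cat,
                   tibble::tibble(category = "all", n = nrow(w),
                                  mean_b = if (nrow(w) > 0)
                                    mean(w$bfactor) else NA_real_))
}
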