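# Empirical Pathways-model search for electron tunneling routes.
#
# Per-step decay factors: a covalent bond contributes a constant factor; a
# hydrogen bond and a through-space jump decay exponentially with distance
# beyond a calibrated equilibrium separation. The coupling of a route is the
# product of its factors; the best route maximizes it, found as a shortest
# path under edge weight -ln(eps).

#' Pathways decay parameters
#'
#' The classic parameterization: covalent factor 0.6 per bond; hydrogen bond
#' `0.36 * exp(-1.7 (R - 2.8))` on the heavy-atom distance R; through-space
#' `0.6 * exp(-1.7 (R - 1.4))`. Each law is clamped at its prefactor below
#' the equilibrium distance so factors stay in (0, 1] and decay
#' monotonically.
#'
#' @param eps_covalent Covalent per-bond factor.
#' @param hb_prefactor,hb_decay,hb_equilibrium Hydrogen-bond law parameters.
#' @param space_prefactor,space_decay,space_equilibrium Through-space law
#'   parameters.
#' @return An `et_params` list.
#' @export
et_params <- function(eps_covalent = 0.6,
                      hb_prefactor = 0.36, hb_decay = 1.7,
                      hb_equilibrium = 2.8,
                      space_prefactor = 0.6, space_decay = 1.7,
                      space_equilibrium = 1.4) {
  structure(list(eps_covalent = eps_covalent,
                 hb_prefactor = hb_prefactor, hb_decay = hb_decay,
                 hb_equilibrium = hb_equilibrium,
                 space_prefactor = space_prefactor,
                 space_decay = space_decay,
                 space_equilibrium = space_equilibrium),
            class = "et_params")
}

#' Per-step decay factor
#'
#' @param R Distance in Angstrom (ignored for covalent steps).
#' @param kind `"covalent"`, `"hbond"` or `"space"`.
#' @param params An [et_params()] list.
#' @return Decay factor in (0, 1].
#' @export
et_decay <- function(R, kind, params = et_params()) {
  switch(kind,
         covalent = rep_len(params$eps_covalent, length(R)),
         hbond = pmin(params$hb_prefactor,
                      params$hb_prefactor *
                        exp(-params$hb_decay * (R - params$hb_equilibrium))),
         space = pmin(params$space_prefactor,
                      params$space_prefactor *
                        exp(-params$space_decay *
                              (R - params$space_equilibrium))),
         stop("unknown edge kind: ", kind))
}

# Covalent-bond detection cutoff for an element pair. Distance-based
# detection with explicit patches covers standard topologies including
# metal-ligand coordination.
covalent_cutoff <- function(el1, el2) {
  metals <- c("FE", "CU", "ZN", "MG", "MN", "NA")
  ifelse(el1 %in% metals | el2 %in% metals, 2.6,
         ifelse(el1 == "S" | el2 == "S", 2.1, 1.9))
}

#' Build the tunneling coupling graph
#'
#' Heavy-atom graph over a selection: covalent edges from distance-based
#' bond detection (element-pair cutoffs; metal coordination up to 2.6 A)
#' plus any explicit `extra_bonds`; hydrogen-bond edges between N/O pairs
#' within `hb_cutoff`; through-space edges between any remaining pair within
#' `space_cutoff`. Hydrogens, if present, are dropped: the hydrogen-bond law
#' is heavy-atom calibrated.
#'
#' @param atoms Atom tibble covering donor, acceptor and the medium.
#' @param hb_cutoff Hydrogen-bond cutoff (default 3.5 A).
#' @param space_cutoff Through-space cutoff (default 5.0 A).
#' @param extra_bonds Optional tibble of forced covalent bonds with columns
#'   `atom1`, `atom2` holding selector strings (`"chain/resseq/name"`), e.g.
#'   heme thioether links or metal-site ligations.
#' @param params Decay parameters ([et_params()]).
#' @param covalent_max Optional single override for the covalent detection
#'   cutoff (Angstrom); `NULL` uses the element-pair rule.
#' @return A `coupling_graph`: list with `nodes`, `edges` tibbles and the
#'   underlying `igraph` (edge weight `-log(eps)`).
#' @export
build_coupling_graph <- function(atoms, hb_cutoff = 3.5, space_cutoff = 5.0,
                                 extra_bonds = NULL, params = et_params(),
                                 covalent_max = NULL) {
  atoms <- dplyr::filter(atoms, .data$element != "H")
  if (nrow(atoms) < 2) stop("need at least two heavy atoms")
  atoms$node_id <- atom_id(atoms)
  if (anyDuplicated(atoms$node_id)) {
    atoms$node_id <- paste0(atoms$node_id, "#", atoms$serial)
  }
  xyz <- xyz_matrix(atoms)
  reach <- max(hb_cutoff, space_cutoff)
  d <- sqrt(cross_dist2(xyz, xyz))
  hits <- which(d <= reach & d > 1e-6 & upper.tri(d), arr.ind = TRUE)
  i <- hits[, 1]; j <- hits[, 2]
  R <- d[hits]
  el_i <- atoms$element[i]; el_j <- atoms$element[j]
  cov_cut <- if (is.null(covalent_max)) covalent_cutoff(el_i, el_j)
             else rep_len(covalent_max, length(R))
  covalent <- R <= cov_cut
  if (!is.null(extra_bonds) && nrow(extra_bonds) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    forced <- vapply(seq_len(nrow(extra_bonds)), function(k) {
      a1 <- resolve_selector(atoms, extra_bonds$atom1[k])
      a2 <- resolve_selector(atoms, extra_bonds$atom2[k])
      if (nrow(a1) != 1 || nrow(a2) != 1) {
        stop("bond patch does not resolve uniquely: ",
             extra_bonds$atom1[k], " - ", extra_bonds$atom2[k])
      }
      key(a1$node_id, a2$node_id)
    }, character(1))
    covalent <- covalent |
      key(atoms$node_id[i], atoms$node_id[j]) %in% forced
  }
  polar_pair <- el_i %in% c("N", "O") & el_j %in% c("N", "O")
  kind <- dplyr::case_when(
    covalent ~ "covalent",
    polar_pair & R <= hb_cutoff ~ "hbond",
    R <= space_cutoff ~ "space",
    TRUE ~ NA_character_)
  keep <- !is.na(kind)
  edges <- tibble::tibble(
    from = atoms$node_id[i[keep]], to = atoms$node_id[j[keep]],
    kind = kind[keep], R = R[keep])
  edges$eps <- vapply(seq_len(nrow(edges)), function(k)
    et_decay(edges$R[k], edges$kind[k], params), numeric(1))
  edges$weight <- -log(edges$eps)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble::tibble(name = atoms$node_id))
  structure(list(nodes = atoms, edges = edges, graph = g, params = params,
                 hb_cutoff = hb_cutoff, space_cutoff = space_cutoff),
            class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat("<coupling_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  print(dplyr::count(x$edges, .data$kind))
  invisible(x)
}

resolve_node <- function(g, sel) {
  if (sel %in% g$nodes$node_id) return(sel)
  hit <- resolve_selector(g$nodes, sel)
  if (nrow(hit) != 1) stop("cannot resolve node: ", sel)
  hit$node_id
}

path_from_nodes <- function(g, node_seq) {
  if (length(node_seq) < 2) {
    edges <- g$edges[0, ]
  } else {
    key <- paste(pmin(node_seq[-length(node_seq)], node_seq[-1]),
                 pmax(node_seq[-length(node_seq)], node_seq[-1]))
    ekey <- paste(pmin(g$edges$from, g$edges$to),
                  pmax(g$edges$from, g$edges$to))
    edges <- g$edges[match(key, ekey), ]
  }
  structure(list(nodes = node_seq, edges = edges,
                 T_DA = prod(edges$eps),
                 running_distance = sum(edges$R),
                 jumps = dplyr::filter(edges, .data$kind != "covalent"),
                 no_path = FALSE),
            class = "et_path")
}

no_path_result <- function() {
  structure(list(nodes = character(0), edges = NULL, T_DA = NA_real_,
                 running_distance = NA_real_, jumps = NULL, no_path = TRUE),
            class = "et_path")
}

#' @export
print.et_path <- function(x, ...) {
  if (x$no_path) {
    cat("<et_path> no path\n")
    return(invisible(x))
  }
  cat(sprintf("<et_path> %d steps, T_DA = %.3g, running distance = %.1f A\n",
              nrow(x$edges), x$T_DA, x$running_distance))
  cat("  ", paste(x$nodes, collapse = " -> "), "\n", sep = "")
  if (nrow(x$jumps) > 0) {
    cat("  non-covalent jumps: ",
        paste(sprintf("%s (%.1f A)", x$jumps$kind, x$jumps$R),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Best-coupled tunneling path
#'
#' Maximizes the product of per-step decay factors between two atoms, via a
#' shortest path on `-ln(eps)` weights. Ties are broken by the
#' lexicographically smallest node-id sequence.
#'
#' @param g A `coupling_graph`.
#' @param donor,acceptor Node ids or atom selector strings.
#' @return An `et_path` (with `no_path = TRUE` when donor and acceptor are
#'   disconnected).
#' @export
best_path <- function(g, donor, acceptor) {
  from <- resolve_node(g, donor); to <- resolve_node(g, acceptor)
  dist <- suppressWarnings(
    igraph::distances(g$graph, v = from, to = to,
                      weights = igraph::E(g$graph)$weight))[1, 1]
  if (!is.finite(dist)) return(no_path_result())
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g$graph, from = from, to = to,
                               weights = igraph::E(g$graph)$weight))
  seqs <- lapply(sp$vpaths %||% sp$res, function(v)
    igraph::as_ids(v))
  seqs <- seqs[order(vapply(seqs, paste, character(1), collapse = "\r"))]
  path_from_nodes(g, seqs[[1]])
}

#' k best tunneling paths (Yen enumeration)
#'
#' Enumerates up to `k` distinct loopless paths in non-increasing coupling
#' order, by Yen's algorithm on the `-ln(eps)` weights. May return fewer
#' paths when fewer exist.
#'
#' @inheritParams best_path
#' @param k Number of candidate routes (default 200).
#' @return List of `et_path` objects sorted by decreasing `T_DA`.
#' @export
k_best_paths <- function(g, donor, acceptor, k = 200) {
  from <- resolve_node(g, donor); to <- resolve_node(g, acceptor)
  first <- best_path(g, from, to)
  if (first$no_path) return(list())
  ew <- igraph::E(g$graph)$weight
  path_weight <- function(nodes) {
    eids <- igraph::get_edge_ids(
      g$graph, rbind(nodes[-length(nodes)], nodes[-1]))
    sum(ew[eids])
  }
  A <- list(first$nodes)
  A_w <- path_weight(first$nodes)
  B <- list(); B_w <- numeric(0)
  while (length(A) < k) {
    prev <- A[[length(A)]]
    for (s in seq_len(length(prev) - 1)) {
      spur <- prev[s]
      root <- prev[1:s]
      gg <- g$graph
      # remove edges that would reproduce an already-accepted path
      drop_edges <- integer(0)
      for (p in A) {
        if (length(p) > s && identical(p[1:s], root)) {
          eid <- igraph::get_edge_ids(gg, c(p[s], p[s + 1]))
          if (eid > 0) drop_edges <- c(drop_edges, eid)
        }
      }
      if (length(drop_edges) > 0) {
        gg <- igraph::delete_edges(gg, unique(drop_edges))
      }
      if (s > 1) gg <- igraph::delete_vertices(gg, root[1:(s - 1)])
      sp <- suppressWarnings(igraph::shortest_paths(
        gg, from = spur, to = to, weights = igraph::E(gg)$weight,
        output = "vpath"))
      spur_nodes <- igraph::as_ids(sp$vpath[[1]])
      if (length(spur_nodes) < 2 && !(length(spur_nodes) == 1 &&
                                      spur_nodes[1] == to)) next
      cand <- c(root[-length(root)], spur_nodes)
      if (cand[length(cand)] != to) next
      sig <- paste(cand, collapse = "\r")
      known <- c(vapply(A, paste, character(1), collapse = "\r"),
                 vapply(B, paste, character(1), collapse = "\r"))
      if (sig %in% known) next
      B[[length(B) + 1]] <- cand
      B_w <- c(B_w, path_weight(cand))
    }
    if (length(B) == 0) break
    sigs <- vapply(B, paste, character(1), collapse = "\r")
    pick <- order(B_w, sigs)[1]
    A[[length(A) + 1]] <- B[[pick]]
    A_w <- c(A_w, B_w[pick])
    B <- B[-pick]; B_w <- B_w[-pick]
  }
  lapply(A, function(nodes) path_from_nodes(g, nodes))
}

#' Path metrics
#'
#' Running distance (sum of step lengths) and the list of non-covalent
#' jumps with their distances.
#'
#' @param p An `et_path`.
#' @return List with `running_distance` and `jumps` tibble.
#' @export
path_metrics <- function(p) {
  stopifnot(inherits(p, "et_path"))
  if (p$no_path) return(list(running_distance = NA_real_, jumps = NULL))
  list(running_distance = p$running_distance, jumps = p$jumps)
}
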