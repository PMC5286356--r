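# Distance queries, superposition, symmetry expansion, polar contacts.

xyz_matrix <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  storage.mode(m) <- "double"
  m
}

# Full cross squared-distance matrix, computed in row blocks so memory stays
# bounded for large selections. Exact (no neighbor pruning).
cross_dist2 <- function(m1, m2, block = 2000L) {
  n1 <- nrow(m1)
  out <- matrix(0, n1, nrow(m2))
  s2 <- rowSums(m2^2)
  for (i0 in seq(1, n1, by = block)) {
    idx <- i0:min(i0 + block - 1L, n1)
    d2 <- outer(rowSums(m1[idx, , drop = FALSE]^2), s2, "+") -
      2 * m1[idx, , drop = FALSE] %*% t(m2)
    out[idx, ] <- d2
  }
  pmax(out, 0)
}

#' Minimum distance between two atom selections
#'
#' Exact minimum over all cross pairs; ties are broken by the lowest serial
#' number of the first atom, then the second.
#'
#' @param sel1,sel2 Atom tibbles (non-empty).
#' @return List with `distance` (Angstrom) and `pair`, a two-row tibble of
#'   the closest atoms.
#' @export
min_atom_distance <- function(sel1, sel2) {
  if (nrow(sel1) == 0 || nrow(sel2) == 0) {
    stop("min_atom_distance: empty atom selection")
  }
  d2 <- cross_dist2(xyz_matrix(sel1), xyz_matrix(sel2))
  m <- min(d2)
  hits <- which(d2 <= m + 1e-12, arr.ind = TRUE)
  ord <- order(sel1$serial[hits[, 1]], sel2$serial[hits[, 2]])
  i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
  list(distance = sqrt(d2[i, j]),
       pair = dplyr::bind_rows(sel1[i, ], sel2[j, ]))
}

#' Shortest inter-chain C-alpha distance
#'
#' The minimum over all C-alpha / C-alpha pairs between two protein
#' selections: the span metric that separates "soft" interfaces (long span)
#' from conventional tight ones.
#'
#' @param atoms_A,atoms_B Atom tibbles; each must contain CA atoms.
#' @return List with `distance` and `pair` (the two CA rows).
#' @export
min_interchain_ca_distance <- function(atoms_A, atoms_B) {
  ca_A <- dplyr::filter(atoms_A, .data$name == "CA", .data$element == "C")
  ca_B <- dplyr::filter(atoms_B, .data$name == "CA", .data$element == "C")
  if (nrow(ca_A) == 0 || nrow(ca_B) == 0) {
    stop("no C-alpha atoms in one of the selections")
  }
  min_atom_distance(ca_A, ca_B)
}

# Side-chain atoms of charged groups, for salt-bridge labelling.
POSITIVE_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
NEGATIVE_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

is_charged <- function(atoms, table) {
  mapply(function(rn, nm) rn %in% names(table) && nm %in% table[[rn]],
         atoms$resname, atoms$name, USE.NAMES = FALSE)
}

#' Inventory of inter-protein polar contacts
#'
#' All nitrogen/oxygen atom pairs across the interface within `max_dist`,
#' labelled `salt_bridge` when the two atoms belong to oppositely charged
#' side-chain groups (Lys NZ / Arg NE,NH / His ring N versus Asp OD / Glu OE)
#' and `hydrogen_bond` otherwise. The label never changes the distance.
#'
#' @param atoms_A,atoms_B Atom tibbles.
#' @param max_dist Distance cutoff in Angstrom (default 3.5).
#' @return Tibble with one row per contact, sorted by distance: atom ids,
#'   residue info on both sides, `distance`, `kind`.
#' @export
polar_contact_inventory <- function(atoms_A, atoms_B, max_dist = 3.5) {
  if (nrow(atoms_A) == 0 || nrow(atoms_B) == 0) {
    stop("polar_contact_inventory: empty atom selection")
  }
  pA <- dplyr::filter(atoms_A, .data$element %in% c("N", "O"))
  pB <- dplyr::filter(atoms_B, .data$element %in% c("N", "O"))
  if (nrow(pA) == 0 || nrow(pB) == 0) {
    return(tibble::tibble(atom_A = character(0), resname_A = character(0),
                          atom_B = character(0), resname_B = character(0),
                          distance = numeric(0), kind = character(0)))
  }
  d <- sqrt(cross_dist2(xyz_matrix(pA), xyz_matrix(pB)))
  hits <- which(d <= max_dist, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble::tibble(atom_A = character(0), resname_A = character(0),
                          atom_B = character(0), resname_B = character(0),
                          distance = numeric(0), kind = character(0)))
  }
  a <- pA[hits[, 1], ]; b <- pB[hits[, 2], ]
  salt <- (is_charged(a, POSITIVE_ATOMS) & is_charged(b, NEGATIVE_ATOMS)) |
    (is_charged(a, NEGATIVE_ATOMS) & is_charged(b, POSITIVE_ATOMS))
  out <- tibble::tibble(
    atom_A = atom_id(a), resname_A = a$resname,
    atom_B = atom_id(b), resname_B = b$resname,
    distance = d[hits],
    kind = ifelse(salt, "salt_bridge", "hydrogen_bond"))
  dplyr::arrange(out, .data$distance)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' matched coordinate sets. `Q ~ P %*% rotation + translation` (row vectors).
#'
#' @param coords_P,coords_Q Numeric n x 3 matrices with matched rows (n >= 3).
#' @return A `kabsch_fit`: list with `rotation` (3x3, det +1), `translation`
#'   (length 3), `rmsd` (Angstrom) and `n`.
#' @export
kabsch_superpose <- function(coords_P, coords_Q) {
  P <- as.matrix(coords_P); Q <- as.matrix(coords_Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3) {
    stop("coordinate sets must be matched n x 3 matrices")
  }
  if (nrow(P) < 3) stop("need at least 3 matched points")
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  if (sum(svd(P0)$d > 1e-8) < 2 || sum(svd(Q0)$d > 1e-8) < 2) {
    stop("degenerate (collinear) coordinates: superposition is not unique")
  }
  s <- svd(t(P0) %*% Q0)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((P0 %*% R - Q0)^2)))
  structure(list(rotation = R, translation = as.numeric(cQ - cP %*% R),
                 rmsd = rmsd, n = nrow(P)),
            class = "kabsch_fit")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("<kabsch_fit> n = %d, rmsd = %.4f A, det(R) = %+.0f\n",
              x$n, x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Match C-alpha atoms of two chains by residue number
#'
#' Pairs CA atoms over the common residue-number range; residues missing on
#' either side are dropped pairwise.
#'
#' @param atoms_A,atoms_B Atom tibbles.
#' @return List of two matched coordinate matrices `P`, `Q` and the shared
#'   residue numbers.
#' @export
match_ca_pairs <- function(atoms_A, atoms_B) {
  ca <- function(a) dplyr::filter(a, .data$name == "CA") |>
    dplyr::distinct(.data$resseq, .keep_all = TRUE)
  a <- ca(atoms_A); b <- ca(atoms_B)
  shared <- intersect(a$resseq, b$resseq)
  if (length(shared) < 3) stop("fewer than 3 shared residues")
  a <- dplyr::arrange(dplyr::filter(a, .data$resseq %in% shared), .data$resseq)
  b <- dplyr::arrange(dplyr::filter(b, .data$resseq %in% shared), .data$resseq)
  list(P = xyz_matrix(a), Q = xyz_matrix(b), resseq = shared)
}

#' Expand a structure by crystal symmetry
#'
#' Applies every symmetry operator combined with lattice translations in the
#' -1..1 cell neighbourhood, keeping images with any atom within `shell` of
#' the asymmetric unit's bounding box. The identity image (identity operator,
#' zero translation) is excluded. Suitable for shells up to one cell edge.
#'
#' @param model A `structure_model` with a cell.
#' @param shell Distance shell in Angstrom (use `Inf` to keep all images).
#' @return Tibble of image atoms: original columns plus `image_id`, `symop`
#'   (operator index) and `tx`, `ty`, `tz` (lattice translation).
#' @export
symmetry_expand <- function(model, shell = 10) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$cell)) {
    stop("no cell: structure carries no crystal symmetry information")
  }
  cc <- model$cell
  atoms <- model$atoms
  M <- cc$ortho
  Minv <- solve(M)
  frac <- xyz_matrix(atoms) %*% t(Minv)
  lo <- apply(xyz_matrix(atoms), 2, min) - shell
  hi <- apply(xyz_matrix(atoms), 2, max) + shell
  shifts <- as.matrix(expand.grid(tx = -1:1, ty = -1:1, tz = -1:1))
  out <- list()
  img <- 0L
  for (k in seq_along(cc$symops)) {
    op <- cc$symops[[k]]
    base <- frac %*% t(op$R)
    for (s in seq_len(nrow(shifts))) {
      if (k == 1L && all(shifts[s, ] == 0)) next
      f <- sweep(base, 2, op$t + shifts[s, ], "+")
      cart <- f %*% t(M)
      if (is.finite(shell)) {
        inside <- cart[, 1] >= lo[1] & cart[, 1] <= hi[1] &
          cart[, 2] >= lo[2] & cart[, 2] <= hi[2] &
          cart[, 3] >= lo[3] & cart[, 3] <= hi[3]
        if (!any(inside)) next
      }
      img <- img + 1L
      im <- atoms
      im$x <- cart[, 1]; im$y <- cart[, 2]; im$z <- cart[, 3]
      im$image_id <- img
      im$symop <- k
      im$tx <- shifts[s, 1]; im$ty <- shifts[s, 2]; im$tz <- shifts[s, 3]
      out[[img]] <- im
    }
  }
  if (length(out) == 0) {
    return(dplyr::mutate(atoms[0, ], image_id = integer(0), symop = integer(0),
                         tx = integer(0), ty = integer(0), tz = integer(0)))
  }
  dplyr::bind_rows(out)
}

#' Closest contact to any crystal symmetry mate
#'
#' Minimum distance from a selection to any atom of any symmetry image of
#' the whole model (operators x lattice translations in the -1..1
#' neighbourhood, identity excluded). Quantifies whether crystal packing
#' approaches a molecule of interest.
#'
#' @param model A `structure_model` with a cell.
#' @param sel Atom tibble (subset of the model's atoms).
#' @return List with `distance` and `pair` (selection atom, image atom with
#'   its `symop` and lattice shift).
#' @export
closest_symmetry_contact <- function(model, sel) {
  if (nrow(sel) == 0) stop("empty selection")
  images <- symmetry_expand(model, shell = Inf)
  if (nrow(images) == 0) stop("symmetry expansion produced no images")
  res <- min_atom_distance(sel, images)
  res
}
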