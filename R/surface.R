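# Shrake-Rupley solvent-accessible surface area and contact surface area.
#
# Numerical SASA: each atom's sphere (van der Waals radius + probe) is
# sampled with a deterministic golden-section spiral point set; a point is
# accessible iff it lies outside every neighbouring atom's probe-expanded
# sphere. Deterministic for fixed n_points, so results are bit-stable.

#' Default van der Waals radii (Angstrom)
#'
#' The radius table used by [sasa()]; configurable per call. Unknown
#' elements are an error, never silently defaulted.
#' @export
default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                       P = 1.80, FE = 1.40, CU = 1.40, ZN = 1.40, MG = 1.73,
                       SE = 1.90)

# Quasi-uniform points on the unit sphere (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

atom_radii <- function(atoms, radii) {
  r <- unname(radii[atoms$element])
  bad <- which(is.na(r))
  if (length(bad) > 0) {
    a <- atoms[bad[1], ]
    stop(sprintf(
      "no van der Waals radius for element '%s' (atom %s %s %s/%d)",
      a$element, a$name, a$resname, a$chain, a$resseq))
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param atoms Atom tibble.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sphere sampling density per atom (default 960).
#' @param radii Named element -> radius vector (default
#'   [default_vdw_radii]).
#' @return A `sasa_result`: list with `per_atom` tibble (`serial`, ids,
#'   `area`), `total` (Angstrom^2), `probe`, `n_points`.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960,
                 radii = default_vdw_radii) {
  if (nrow(atoms) == 0) stop("sasa: empty atom selection")
  r <- atom_radii(atoms, radii) + probe
  xyz <- xyz_matrix(atoms)
  pts <- sphere_points(n_points)
  n <- nrow(atoms)
  # neighbour lists from the exact cross-distance matrix (chunked)
  d2 <- cross_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    touch <- (r[i] + r)^2
    nb <- which(d2[i, ] < touch & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        buried <- buried | dj2 < r[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * r[i]^2 * acc / n_points
  }
  per_atom <- tibble::tibble(serial = atoms$serial, atom = atom_id(atoms),
                             element = atoms$element, area = area)
  structure(list(per_atom = per_atom, total = sum(area), probe = probe,
                 n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.2f, %d pts)\n",
              nrow(x$per_atom), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Contact surface area between two selections
#'
#' Area buried on complex formation, from three SASA evaluations:
#' `(SASA(A) + SASA(B) - SASA(A+B)) / 2` under the default half-buried-area
#' convention, or the full difference with `convention = "full"`. Waters are
#' removed from both selections before the calculation (the metric concerns
#' direct protein burial); hetero cofactors are retained with their protein.
#'
#' @param atoms_A,atoms_B Atom tibbles with disjoint serial numbers.
#' @param probe Probe radius (default 1.4 A).
#' @param n_points Sampling density (default 960).
#' @param convention `"half"` (default) or `"full"`.
#' @param radii Element radius table.
#' @return Contact surface area in Angstrom^2.
#' @export
contact_surface_area <- function(atoms_A, atoms_B, probe = 1.4,
                                 n_points = 960,
                                 convention = c("half", "full"),
                                 radii = default_vdw_radii) {
  convention <- match.arg(convention)
  atoms_A <- dplyr::filter(atoms_A, !.data$is_water)
  atoms_B <- dplyr::filter(atoms_B, !.data$is_water)
  if (nrow(atoms_A) == 0 || nrow(atoms_B) == 0) {
    stop("contact_surface_area: empty selection after removing waters")
  }
  if (length(intersect(atoms_A$serial, atoms_B$serial)) > 0) {
    stop("selections share atom serial numbers; they must be disjoint")
  }
  sA <- sasa(atoms_A, probe, n_points, radii)$total
  sB <- sasa(atoms_B, probe, n_points, radii)$total
  sAB <- sasa(dplyr::bind_rows(atoms_A, atoms_B), probe, n_points,
              radii)$total
  delta <- sA + sB - sAB
  if (convention == "half") delta / 2 else delta
}
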