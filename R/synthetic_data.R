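# Seeded toy two-chain complexes with ground-truth water categories, plus
# small hand-computable tunneling cases. Pseudo-protein chains carry only
# N, CA, C, O, CB atoms: enough for C-alpha metrics, SASA, polar contacts
# and water classification, with no claim to real protein geometry.

toy_atoms <- function(name, element, resname, chain, resseq, xyz,
                      bfactor = 0, is_water = FALSE, is_hetero = FALSE) {
  tibble::tibble(serial = 0L, name = name, element = element,
                 altloc = "", resname = resname, chain = chain,
                 resseq = as.integer(resseq), icode = "",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 occupancy = 1, bfactor = bfactor,
                 is_water = is_water, is_hetero = is_hetero)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# One pseudo chain: residues every 3.8 A along x; CB faces the interface.
# The mid-chain residue extends a charged "arm" atom (a lysine-like NZ or an
# aspartate-like OD2) to arm_z, emulating the long side-chain reach that
# lets two well-separated proteins form a specific polar contact.
toy_chain <- function(n_res, chain, z0, flip = FALSE, arm_z = NULL,
                      arm_name = "NZ", arm_element = "N",
                      arm_resname = "LYS", arm_res = ceiling(n_res / 2)) {
  rows <- list()
  m <- arm_res
  sgn <- if (flip) -1 else 1
  for (i in seq_len(n_res)) {
    x <- 3.8 * (i - 1)
    pos <- rbind(
      N  = c(x - 1.0, 0.8, z0 + sgn * 0.4),
      CA = c(x, 0, z0),
      C  = c(x + 1.2, -0.7, z0 + sgn * 0.3),
      O  = c(x + 1.3, -1.9, z0 + sgn * 0.3),
      CB = c(x, 1.0, z0 + sgn * 1.2))
    nm <- rownames(pos)
    el <- c("N", "C", "C", "O", "C")
    resname <- "ALA"
    if (i == m && !is.null(arm_z)) {
      pos <- rbind(pos, arm = c(x, 0, arm_z))
      nm <- c(nm, arm_name)
      el <- c(el, arm_element)
      resname <- arm_resname
    }
    rows[[i]] <- toy_atoms(nm, el, resname, chain, i, pos)
  }
  dplyr::bind_rows(rows)
}

# Water category placement bands relative to the 3.5 A interaction rule and
# 7 A shell: strict margins so PDB coordinate rounding (1e-3 A) cannot flip
# a category.
CATEGORY_BANDS <- list(
  bridging       = list(A = c(2.3, 3.40), B = c(2.3, 3.40)),
  nonbridging_A  = list(A = c(2.3, 3.40), B = c(3.70, 6.90)),
  nonbridging_B  = list(A = c(3.70, 6.90), B = c(2.3, 3.40)),
  noninteracting = list(A = c(3.70, 6.90), B = c(3.70, 6.90)))

#' Generate a toy two-chain complex with known water categories
#'
#' Builds two pseudo-protein chains separated by `gap` (surface to surface),
#' each with one side-chain "arm" protruding into the gap so that bridging
#' positions exist, then places waters by rejection sampling against exact
#' per-category distance bands (verified before emission). B-factors of
#' chain A rise linearly with distance from the arm anchor at the planted
#' slope plus seeded Gaussian noise. A valid P 1 21 1 cell is attached.
#'
#' @param n_res_A,n_res_B Residues per chain (>= 1).
#' @param n_waters Named or positional integer vector of length 4:
#'   waters per category in the order bridging, nonbridging_A,
#'   nonbridging_B, noninteracting.
#' @param gap Surface-to-surface separation in Angstrom; must exceed 7.4
#'   when non-interacting waters are requested.
#' @param b_slope Planted B gradient (Angstrom^2 per Angstrom).
#' @param b_base Baseline B (Angstrom^2).
#' @param b_noise_sd Gaussian noise on B (Angstrom^2).
#' @param seed Integer seed; same seed, same structure, byte for byte.
#' @param max_attempts Rejection-sampling cap per water before an
#'   infeasibility error.
#' @return A `toy_complex`: list with `model` (a `structure_model`),
#'   `truth` (water_id, category, exact distances), `anchors` (atom tibble),
#'   `b_slope`, `b_base`, `gap`, `seed`.
#' @export
make_toy_complex <- function(n_res_A = 8, n_res_B = 8,
                             n_waters = c(bridging = 3, nonbridging_A = 3,
                                          nonbridging_B = 3,
                                          noninteracting = 2),
                             gap = 10, b_slope = 1.5, b_base = 20,
                             b_noise_sd = 2, seed = 1,
                             max_attempts = 10000) {
  stopifnot(n_res_A >= 1, n_res_B >= 1, length(n_waters) == 4,
            all(n_waters >= 0))
  n_waters <- as.integer(n_waters)
  names(n_waters) <- names(CATEGORY_BANDS)
  z_top <- 1.2
  if (n_waters["noninteracting"] > 0 && gap < 7.4) {
    stop("infeasible: non-interacting waters need a gap of at least 7.4 A")
  }
  if (sum(n_waters[c("bridging", "nonbridging_A", "nonbridging_B")]) > 0 &&
      gap < 7) {
    stop("infeasible: gap must be at least 7 A")
  }
  with_seed(seed, {
    mid_z <- z_top + gap / 2
    # both arms sit at the same x so bridging positions exist between them
    arm_res <- ceiling(min(n_res_A, n_res_B) / 2)
    A <- toy_chain(n_res_A, "A", 0, flip = FALSE, arm_z = mid_z - 1.5,
                   arm_name = "NZ", arm_element = "N", arm_resname = "LYS",
                   arm_res = arm_res)
    B <- toy_chain(n_res_B, "B", 2 * z_top + gap, flip = TRUE,
                   arm_z = mid_z + 1.5,
                   arm_name = "OD2", arm_element = "O", arm_resname = "ASP",
                   arm_res = arm_res)
    arm_A <- dplyr::filter(A, .data$name == "NZ")
    arm_B <- dplyr::filter(B, .data$name == "OD2")
    xyz_A <- xyz_matrix(A); xyz_B <- xyz_matrix(B)
    x_range <- range(c(A$x, B$x))
    arm_mid <- (as.numeric(arm_A[1, c("x", "y", "z")]) +
                  as.numeric(arm_B[1, c("x", "y", "z")])) / 2
    sample_point <- function(category) {
      if (category == "bridging") {
        arm_mid + c(stats::runif(2, -3.3, 3.3), stats::runif(1, -1.2, 1.2))
      } else if (category == "nonbridging_A") {
        c(stats::runif(1, arm_A$x - 5, arm_A$x + 5), stats::runif(1, -3, 3),
          stats::runif(1, z_top + 2.3, mid_z))
      } else if (category == "nonbridging_B") {
        c(stats::runif(1, arm_B$x - 5, arm_B$x + 5), stats::runif(1, -3, 3),
          stats::runif(1, mid_z, z_top + gap - 2.3))
      } else {
        c(stats::runif(1, x_range[1], x_range[2]), stats::runif(1, -2, 2),
          stats::runif(1, mid_z - 1.2, mid_z + 1.2))
      }
    }
    placed <- matrix(numeric(0), ncol = 3)
    truth <- list()
    for (category in names(CATEGORY_BANDS)) {
      band <- CATEGORY_BANDS[[category]]
      for (k in seq_len(n_waters[category])) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          p <- sample_point(category)
          dA <- sqrt(min(colSums((t(xyz_A) - p)^2)))
          dB <- sqrt(min(colSums((t(xyz_B) - p)^2)))
          sep_ok <- nrow(placed) == 0 ||
            min(colSums((t(placed) - p)^2)) >= 2.4^2
          if (dA >= band$A[1] && dA <= band$A[2] &&
              dB >= band$B[1] && dB <= band$B[2] && sep_ok) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("infeasible: could not place a ", category,
               " water within ", max_attempts, " attempts (gap = ", gap, ")")
        }
        placed <- rbind(placed, p)
        truth[[length(truth) + 1]] <- tibble::tibble(
          category = category, d_min_A = dA, d_min_B = dB)
      }
    }
    waters <- if (nrow(placed) > 0) {
      toy_atoms("O", "O", "HOH", "W", seq_len(nrow(placed)),
                round(placed, 3), is_water = TRUE, is_hetero = TRUE)
    } else toy_atoms(character(0), character(0), character(0), character(0),
                     integer(0), matrix(numeric(0), ncol = 3),
                     is_water = logical(0), is_hetero = logical(0))
    anchor_xyz <- xyz_matrix(arm_A)
    b_for <- function(atoms) {
      d <- sqrt(apply(cross_dist2(xyz_matrix(atoms), anchor_xyz), 1, min))
      pmax(1, b_base + b_slope * d + stats::rnorm(nrow(atoms), 0, b_noise_sd))
    }
    A$bfactor <- round(b_for(A), 2)
    B$bfactor <- round(pmax(1, b_base +
                              stats::rnorm(nrow(B), 0, b_noise_sd)), 2)
    if (nrow(waters) > 0) {
      waters$bfactor <- round(pmax(1, b_base + 30 +
                                     stats::rnorm(nrow(waters), 0, 10)), 2)
    }
    atoms <- dplyr::bind_rows(A, B, waters)
    atoms$serial <- seq_len(nrow(atoms))
    atoms$x <- round(atoms$x, 3)
    atoms$y <- round(atoms$y, 3)
    atoms$z <- round(atoms$z, 3)
    span <- function(v) diff(range(v))
    cell <- crystal_cell(span(atoms$x) + 20, span(atoms$y) + 20,
                         span(atoms$z) + 20, 90, 102.1, 90,
                         spacegroup = "P 1 21 1")
    model <- structure_model(atoms, cell = cell,
                             source_id = paste0("toy-", seed))
    truth_tbl <- if (length(truth) > 0) {
      tt <- dplyr::bind_rows(truth)
      w <- dplyr::filter(atoms, .data$is_water)
      tt$water_id <- atom_id(w)
      dplyr::select(tt, "water_id", "category", "d_min_A", "d_min_B")
    } else tibble::tibble(water_id = character(0), category = character(0),
                          d_min_A = numeric(0), d_min_B = numeric(0))
    anchors <- dplyr::filter(atoms, .data$chain == "A", .data$name == "NZ")
    structure(list(model = model, truth = truth_tbl, anchors = anchors,
                   b_slope = b_slope, b_base = b_base,
                   b_noise_sd = b_noise_sd, gap = gap, seed = seed,
                   n_waters = n_waters),
              class = "toy_complex")
  })
}

#' @export
print.toy_complex <- function(x, ...) {
  cat("<toy_complex> seed ", x$seed, ", gap ", x$gap, " A\n", sep = "")
  print(x$n_waters)
  invisible(x)
}

#' Small tunneling cases with hand-computable best paths
#'
#' Lays out a handful of atoms so the coupling graph's best route and its
#' total coupling follow in closed form.
#'
#' Topologies: `"chain4"` (four atoms in a covalent line; T_DA = 0.6^3),
#' `"shortcut"` (a five-atom covalent arc whose ends are 1.95 A apart, so a
#' through-space jump beats two covalent steps), `"space_eq"` (two atoms at
#' the through-space equilibrium distance with covalent detection narrowed,
#' so the single edge's factor equals the law's prefactor).
#'
#' @param topology One of `"chain4"`, `"shortcut"`, `"space_eq"`.
#' @param seed Unused for the fixed layouts; kept for interface symmetry.
#' @return List with `model`, `donor`, `acceptor` selectors,
#'   `expected_nodes`, `expected_T_DA` and `graph_args` to pass to
#'   [build_coupling_graph()].
#' @export
make_toy_coupling_case <- function(topology = c("chain4", "shortcut",
                                                "space_eq"), seed = 1) {
  topology <- match.arg(topology)
  mk <- function(xyz) {
    n <- nrow(xyz)
    atoms <- toy_atoms("C", "C", "UNK", "X", seq_len(n), xyz,
                       is_hetero = TRUE)
    atoms$serial <- seq_len(n)
    structure_model(atoms, source_id = paste0("toy-et-", topology))
  }
  id <- function(i) paste0("X/", i, "/C")
  if (topology == "chain4") {
    model <- mk(cbind(1.5 * (0:3), 0, 0))
    list(model = model, donor = id(1), acceptor = id(4),
         expected_nodes = id(1:4), expected_T_DA = 0.6^3,
         graph_args = list())
  } else if (topology == "shortcut") {
    # B..E chord 1.95 A; BC = CD = DE = 1.5 A (trapezoid), AB = 1.5 A.
    dx <- 0.225; h <- sqrt(2.25 - dx^2)
    xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5 + dx, h, 0),
                 c(3.45 - dx, h, 0), c(3.45, 0, 0))
    model <- mk(xyz)
    list(model = model, donor = id(1), acceptor = id(5),
         expected_nodes = id(c(1, 2, 5)),
         expected_T_DA = 0.6 * et_decay(1.95, "space"),
         graph_args = list())
  } else {
    model <- mk(rbind(c(0, 0, 0), c(1.4, 0, 0)))
    list(model = model, donor = id(1), acceptor = id(2),
         expected_nodes = id(1:2), expected_T_DA = 0.6,
         graph_args = list(covalent_max = 0.5))
  }
}
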