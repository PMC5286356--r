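# Shared fixtures and independent brute-force oracles.

# Quick atom tibble from coordinates.
make_atoms <- function(xyz, element = "C", name = element, resname = "UNK",
                       chain = "X", resseq = seq_len(nrow(xyz)),
                       bfactor = 0, is_water = FALSE, is_hetero = FALSE,
                       serial = seq_len(nrow(xyz))) {
  xyz <- matrix(xyz, ncol = 3)
  tibble::tibble(
    serial = as.integer(serial),
    name = rep_len(name, nrow(xyz)),
    element = rep_len(element, nrow(xyz)),
    altloc = "", resname = rep_len(resname, nrow(xyz)),
    chain = rep_len(chain, nrow(xyz)),
    resseq = as.integer(rep_len(resseq, nrow(xyz))), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, bfactor = rep_len(bfactor, nrow(xyz)),
    is_water = rep_len(is_water, nrow(xyz)),
    is_hetero = rep_len(is_hetero, nrow(xyz)))
}

# O(n*m) double-loop minimum distance: the oracle for accelerated queries.
brute_min_dist <- function(xyz1, xyz2) {
  best <- Inf
  for (i in seq_len(nrow(xyz1))) {
    for (j in seq_len(nrow(xyz2))) {
      d <- sqrt(sum((xyz1[i, ] - xyz2[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Exhaustive enumeration of all simple paths between two nodes of a small
# undirected weighted graph given as an edge tibble (from, to, eps).
# Returns paths sorted by decreasing product of eps (ties: lexicographic).
enumerate_simple_paths <- function(edges, from, to) {
  adj <- list()
  add <- function(a, b, eps) {
    adj[[a]] <<- rbind(adj[[a]], data.frame(to = b, eps = eps))
  }
  for (k in seq_len(nrow(edges))) {
    add(edges$from[k], edges$to[k], edges$eps[k])
    add(edges$to[k], edges$from[k], edges$eps[k])
  }
  out <- list()
  walk <- function(node, visited, prod) {
    if (node == to) {
      out[[length(out) + 1]] <<- list(nodes = visited, T_DA = prod)
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      if (!(nb$to[k] %in% visited)) {
        walk(nb$to[k], c(visited, nb$to[k]), prod * nb$eps[k])
      }
    }
  }
  walk(from, from, 1)
  if (length(out) == 0) return(out)
  tda <- vapply(out, function(p) p$T_DA, numeric(1))
  sig <- vapply(out, function(p) paste(p$nodes, collapse = "\r"),
                character(1))
  out[order(-tda, sig)]
}

# Random connected coupling graph on n nodes as an atom cloud dense enough
# that the through-space cutoff connects it.
random_atom_cloud <- function(n, seed) {
  set.seed(seed)
  side <- 4.8 * n^(1 / 3)  # mean degree ~4-5 at the 5 A space cutoff
  make_atoms(matrix(runif(3 * n, 0, side), ncol = 3),
             element = sample(c("C", "N", "O"), n, replace = TRUE),
             name = "C")
}

# Closed-form SASA of two identical spheres of radius R (centre separation
# d): each sphere loses a cap of height h = R - d/2.
two_sphere_sasa <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), nrow = 3, byrow = TRUE)
}
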