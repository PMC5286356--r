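test_that("minimum atom distance is exact and matches the brute-force oracle", {
  a <- make_atoms(rbind(c(0, 0, 0)))
  b <- make_atoms(rbind(c(5, 0, 0)))
  expect_equal(min_atom_distance(a, b)$distance, 5)
  set.seed(41)
  for (rep in 1:5) {
    p <- matrix(runif(150, 0, 20), ncol = 3)
    q <- matrix(runif(150, 0, 20), ncol = 3)
    got <- min_atom_distance(make_atoms(p), make_atoms(q))$distance
    expect_equal(got, brute_min_dist(p, q), tolerance = 1e-12)
  }
  expect_error(min_atom_distance(a[0, ], b), "empty")
})

test_that("shortest inter-chain CA distance uses C-alpha pairs only", {
  a <- make_atoms(rbind(c(0, 0, 0), c(1, 0, 0)), name = c("CA", "CB"),
                  chain = "A", resseq = 1)
  b <- make_atoms(rbind(c(7, 0, 0), c(3, 0, 0)), name = c("CA", "CB"),
                  chain = "B", resseq = 1)
  res <- min_interchain_ca_distance(a, b)
  expect_equal(res$distance, 7)  # the 2 A CB pair must be ignored
  expect_error(min_interchain_ca_distance(a[2, ], b), "C-alpha")
})

test_that("polar contacts are N/O pairs, labelled and distance-sorted", {
  lys <- make_atoms(rbind(c(0, 0, 0)), element = "N", name = "NZ",
                    resname = "LYS", chain = "A")
  asp <- make_atoms(rbind(c(2.7, 0, 0), c(3.2, 0, 0), c(10, 0, 0)),
                    element = "O", name = c("OD2", "O", "OD1"),
                    resname = c("ASP", "GLY", "ASP"), chain = "B")
  inv <- polar_contact_inventory(lys, asp, max_dist = 3.5)
  expect_equal(nrow(inv), 2)
  expect_equal(inv$distance, c(2.7, 3.2))
  expect_equal(inv$kind, c("salt_bridge", "hydrogen_bond"))
  # carbon atoms never enter the inventory
  cb <- make_atoms(rbind(c(1, 0, 0)), element = "C", name = "CB", chain = "B")
  expect_equal(nrow(polar_contact_inventory(lys, cb)), 0)
})

test_that("Kabsch recovers planted rigid motions with rmsd 0 and det +1", {
  set.seed(7)
  for (rep in 1:10) {
    P <- matrix(rnorm(36), ncol = 3)
    R <- random_rotation()
    t <- rnorm(3)
    Q <- P %*% R + matrix(t, nrow(P), 3, byrow = TRUE)
    fit <- kabsch_superpose(P, Q)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
    expect_equal(fit$rotation, R, tolerance = 1e-8)
  }
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
})

test_that("Kabsch rmsd is invariant under rigid motion of either input", {
  set.seed(8)
  P <- matrix(rnorm(30), ncol = 3)
  Q <- P + matrix(rnorm(30, sd = 0.3), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (rep in 1:5) {
    R <- random_rotation()
    moved <- Q %*% R + matrix(rnorm(3), nrow(Q), 3, byrow = TRUE)
    expect_equal(kabsch_superpose(P, moved)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("Kabsch rejects mismatched and collinear input", {
  P <- matrix(rnorm(12), ncol = 3)
  expect_error(kabsch_superpose(P, P[1:3, ]), "matched")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch agrees with the bio3d superposition on noisy pairs", {
  set.seed(9)
  P <- matrix(rnorm(60), ncol = 3)
  Q <- P %*% random_rotation() + matrix(rnorm(60, sd = 0.5), ncol = 3)
  ours <- kabsch_superpose(P, Q)$rmsd
  ref <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("a lone atom in P1 yields the 26 neighbour-cell images", {
  m <- structure_model(make_atoms(rbind(c(5, 5, 5))),
                       cell = crystal_cell(10, 10, 10))
  img <- symmetry_expand(m, shell = Inf)
  expect_equal(length(unique(img$image_id)), 26)
  # nearest image in a 10 A cubic cell is one edge away
  expect_equal(closest_symmetry_contact(m, m$atoms)$distance, 10)
})

test_that("screw-axis images match the hand-computed fractional transform", {
  # P 1 21 1, orthogonal axes for hand checking: (-x, y+1/2, -z)
  cell <- crystal_cell(20, 30, 40, 90, 90, 90, spacegroup = "P 1 21 1")
  m <- structure_model(make_atoms(rbind(c(2, 3, 4))), cell = cell)
  img <- symmetry_expand(m, shell = Inf)
  scr <- dplyr::filter(img, .data$symop == 2, .data$tx == 0, .data$ty == 0,
                       .data$tz == 0)
  # frac (0.1, 0.1, 0.1) -> (-0.1, 0.6, -0.1) -> cart (-2, 18, -4)
  expect_equal(c(scr$x, scr$y, scr$z), c(-2, 18, -4), tolerance = 1e-9)
})

test_that("symmetry images are isometries of the original", {
  tc <- make_toy_complex(seed = 13, n_res_A = 4, n_res_B = 4)
  m <- tc$model
  img <- symmetry_expand(m, shell = Inf)
  one <- dplyr::filter(img, .data$image_id == min(img$image_id))
  d_orig <- dist(cbind(m$atoms$x, m$atoms$y, m$atoms$z))
  d_img <- dist(cbind(one$x, one$y, one$z))
  expect_equal(as.vector(d_img), as.vector(d_orig), tolerance = 1e-9)
})

test_that("closest symmetry contact equals brute force over all images", {
  tc <- make_toy_complex(seed = 17, n_res_A = 3, n_res_B = 3,
                         n_waters = c(1, 1, 1, 1))
  m <- tc$model
  sel <- dplyr::filter(m$atoms, .data$chain == "A")
  img <- symmetry_expand(m, shell = Inf)
  want <- brute_min_dist(cbind(sel$x, sel$y, sel$z),
                         cbind(img$x, img$y, img$z))
  expect_equal(closest_symmetry_contact(m, sel)$distance, want,
               tolerance = 1e-9)
})

test_that("requesting symmetry without a cell is an explicit error", {
  m <- structure_model(make_atoms(rbind(c(0, 0, 0))))
  expect_error(symmetry_expand(m), "no cell")
  expect_error(closest_symmetry_contact(m, m$atoms), "no cell")
})
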