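chain_at <- function(x0, chain) {
  make_atoms(rbind(c(x0, 0, 0), c(x0, 2, 0)), name = c("O", "CA"),
             element = c("O", "C"), chain = chain)
}

water_at <- function(xyz, bfactor = 30) {
  make_atoms(matrix(xyz, ncol = 3), element = "O", name = "O",
             resname = "HOH", chain = "W", bfactor = bfactor,
             is_water = TRUE, is_hetero = TRUE)
}

test_that("interface shell requires closeness to both proteins", {
  A <- chain_at(0, "A"); B <- chain_at(12, "B")
  w <- water_at(rbind(c(6, 0, 10),   # 10+ A from both -> out
                      c(6, 0, 0),    # 6 from both -> in
                      c(4, 0, 0)))   # 4 from A, 8 from B -> out
  iw <- select_interface_waters(w, A, B, shell = 7)
  expect_equal(nrow(iw), 1)
  expect_equal(iw$x, 6)
})

test_that("water categories follow the strict 3.5 A rule on both sides", {
  A <- chain_at(0, "A"); B <- chain_at(6, "B")
  w <- water_at(rbind(c(3.0, 0, 0),    # 3.0 / 3.0 -> bridging
                      c(2.0, 0, 0),    # 2.0 / 4.0 -> nonbridging_A
                      c(4.0, 0, 0)))   # 4.0 / 2.0 -> nonbridging_B
  cen <- classify_waters(select_interface_waters(w, A, B), A, B)
  expect_equal(as.character(cen$category),
               c("bridging", "nonbridging_A", "nonbridging_B"))
  # boundary equality at exactly 3.5 counts as non-interacting
  B2 <- chain_at(7, "B")
  w2 <- water_at(rbind(c(3.5, 0, 0)))
  cen2 <- classify_waters(select_interface_waters(w2, A, B2), A, B2)
  expect_equal(as.character(cen2$category), "noninteracting")
})

test_that("contact profile counts planted polar, non-polar and water neighbours", {
  # protein A: two polar + one non-polar atom within 3.5 of the water
  A <- make_atoms(rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(0, 0, 20)),
                  element = c("N", "O", "C", "C"),
                  name = c("N", "O", "CB", "CA"), chain = "A")
  B <- chain_at(30, "B")
  w <- water_at(rbind(c(0, 0, 0), c(3.0, 0, 0), c(25, 0, 20)))
  cen <- classify_waters(w, A, B, cutoff = 3.5)
  prof <- water_contact_profile(cen, A, B, waters = w)
  first <- prof$per_water[1, ]
  expect_equal(first$n_polar_contacts, 2L)
  expect_equal(first$n_nonpolar_contacts, 1L)
  expect_equal(first$n_water_contacts, 1L)
  # isolated water: all zero
  iso <- prof$per_water[3, ]
  expect_equal(iso$n_polar_contacts + iso$n_nonpolar_contacts +
                 iso$n_water_contacts, 0L)
  expect_true(all(c("side", "resname", "n") %in% names(prof$residue_tally)))
})

test_that("hydrogen-bond network links waters and reports A-B connectivity", {
  A <- chain_at(0, "A"); B <- chain_at(12, "B")
  # water chain spanning the gap: A ... w1 - w2 - w3 ... B
  w <- water_at(rbind(c(3, 0, 0), c(6, 0, 0), c(9, 0, 0)))
  cen <- classify_waters(w, A, B)
  net <- build_hbond_network(cen, A, B)
  expect_true(net$connects_AB)
  expect_equal(sum(net$edges$kind == "water_water"), 2)
  deg <- igraph::degree(net$graph)
  expect_true(all(deg[grep("^water", names(deg))] >= 1))
  # two waters alone: one edge, one component, no protein link
  lone <- water_at(rbind(c(100, 0, 0), c(103, 0, 0)))
  cen2 <- classify_waters(lone, A, B, cutoff = 3.5)
  net2 <- build_hbond_network(cen2, A[0, ], B[0, ])
  expect_equal(nrow(net2$edges), 1)
  expect_false(net2$connects_AB)
})

test_that("water B statistics average per category and skip empty ones", {
  A <- chain_at(0, "A"); B <- chain_at(6, "B")
  w <- water_at(rbind(c(3, 0, 0), c(3, 0.5, 0)), bfactor = c(10, 20))
  cen <- classify_waters(select_interface_waters(w, A, B), A, B)
  st <- water_bfactor_stats(cen)
  expect_equal(st$mean_b[st$category == "all"], 15)
  expect_false("noninteracting" %in% st$category)
  expect_equal(sum(st$n[st$category != "all"]), 2)
})

test_that("census on synthetic waters matches direct averages", {
  tc <- make_toy_complex(seed = 23)
  sel <- select_complex(tc$model, complex_spec("A", "B"))
  cen <- classify_waters(
    select_interface_waters(sel$waters, sel$A, sel$B), sel$A, sel$B)
  st <- water_bfactor_stats(cen)
  expect_equal(st$mean_b[st$category == "all"],
               mean(sel$waters$bfactor[sel$waters$element == "O"]))
})

test_that("category partition and cutoff monotonicity hold on toy complexes", {
  for (seed in c(31, 32, 33)) {
    tc <- make_toy_complex(seed = seed)
    sel <- select_complex(tc$model, complex_spec("A", "B"))
    iw <- select_interface_waters(sel$waters, sel$A, sel$B, shell = 7)
    cen <- classify_waters(iw, sel$A, sel$B, cutoff = 3.5)
    counts <- table(cen$category)
    expect_equal(sum(counts), nrow(iw))
    wider <- classify_waters(iw, sel$A, sel$B, cutoff = 4.5)
    expect_gte(sum(wider$category == "bridging"), counts[["bridging"]])
    iw_wide <- select_interface_waters(sel$waters, sel$A, sel$B, shell = 9)
    expect_gte(nrow(iw_wide), nrow(iw))
  }
})
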