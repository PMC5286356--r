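test_that("decay laws: covalent constant, exponential clamped at equilibrium", {
  p <- et_params()
  expect_equal(et_decay(NA, "covalent", p), 0.6)
  expect_equal(et_decay(2.8, "hbond", p), 0.36)
  expect_equal(et_decay(1.4, "space", p), 0.6)
  # monotone decay beyond equilibrium, clamped below it
  expect_equal(et_decay(1.0, "space", p), 0.6)
  r <- seq(1.4, 5, by = 0.1)
  eps <- et_decay(r, "space", p)
  expect_true(all(diff(eps) <= 0))
  expect_true(all(eps <= 0.6 & eps > 0))
  expect_equal(et_decay(3.8, "hbond", p), 0.36 * exp(-1.7 * 1.0))
})

test_that("a covalent 3-bond chain gives the closed-form coupling", {
  cs <- make_toy_coupling_case("chain4")
  g <- build_coupling_graph(cs$model$atoms)
  expect_equal(sum(g$edges$kind == "covalent"), 3)
  expect_true(all(g$edges$eps[g$edges$kind == "covalent"] == 0.6))
  p <- best_path(g, cs$donor, cs$acceptor)
  expect_equal(p$nodes, cs$expected_nodes)
  expect_equal(p$T_DA, 0.6^3)
  expect_equal(path_metrics(p)$running_distance, 4.5)
  expect_equal(nrow(path_metrics(p)$jumps), 0)
})

test_that("a through-space shortcut at favourable distance wins the route", {
  cs <- make_toy_coupling_case("shortcut")
  g <- build_coupling_graph(cs$model$atoms)
  p <- best_path(g, cs$donor, cs$acceptor)
  expect_equal(p$nodes, cs$expected_nodes)
  expect_equal(p$T_DA, cs$expected_T_DA, tolerance = 1e-12)
  expect_equal(nrow(p$jumps), 1)
  expect_equal(p$jumps$R, 1.95, tolerance = 1e-9)
})

test_that("a pair at the space-equilibrium distance couples at the prefactor", {
  cs <- make_toy_coupling_case("space_eq")
  g <- do.call(build_coupling_graph, c(list(cs$model$atoms), cs$graph_args))
  p <- best_path(g, cs$donor, cs$acceptor)
  expect_equal(p$T_DA, 0.6)
  expect_equal(p$edges$kind, "space")
})

test_that("parallel routes: the higher eps-product route is selected", {
  # nodes 1-2-3 with eps 0.6 each (covalent) vs direct 1-3 space jump with
  # lower eps: product 0.36 beats the single weak jump
  atoms <- make_atoms(rbind(c(0, 0, 0), c(1.5, 0.9, 0), c(3.0, 0, 0)))
  g <- build_coupling_graph(atoms)
  direct <- g$edges[g$edges$kind == "space", ]
  expect_equal(nrow(direct), 1)
  expect_lt(direct$eps, 0.36)
  p <- best_path(g, "X/1/C", "X/3/C")
  expect_equal(length(p$nodes), 3)
  expect_equal(p$T_DA, 0.36, tolerance = 1e-12)
})

test_that("disconnected endpoints return a no-path result, not an error", {
  atoms <- make_atoms(rbind(c(0, 0, 0), c(100, 0, 0)))
  g <- build_coupling_graph(atoms)
  p <- best_path(g, "X/1/C", "X/2/C")
  expect_true(p$no_path)
  expect_true(is.na(p$T_DA))
  expect_equal(k_best_paths(g, "X/1/C", "X/2/C"), list())
})

test_that("best path equals exhaustive enumeration on random graphs", {
  for (seed in 1:30) {
    atoms <- random_atom_cloud(sample(5:12, 1), seed = seed)
    g <- build_coupling_graph(atoms)
    from <- g$nodes$node_id[1]
    to <- g$nodes$node_id[nrow(g$nodes)]
    oracle <- enumerate_simple_paths(g$edges, from, to)
    got <- best_path(g, from, to)
    if (length(oracle) == 0) {
      expect_true(got$no_path)
    } else {
      expect_equal(got$T_DA, oracle[[1]]$T_DA, tolerance = 1e-9)
      expect_equal(got$nodes, oracle[[1]]$nodes)
    }
  }
})

test_that("k best paths match the brute-force top-k, sorted by coupling", {
  for (seed in 101:110) {
    atoms <- random_atom_cloud(sample(5:9, 1), seed = seed)
    g <- build_coupling_graph(atoms)
    from <- g$nodes$node_id[1]
    to <- g$nodes$node_id[nrow(g$nodes)]
    oracle <- enumerate_simple_paths(g$edges, from, to)
    k <- 5
    got <- k_best_paths(g, from, to, k = k)
    expect_equal(length(got), min(k, length(oracle)))
    tda <- vapply(got, function(p) p$T_DA, numeric(1))
    expect_true(all(diff(tda) <= 1e-12))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$T_DA, oracle[[i]]$T_DA, tolerance = 1e-9)
    }
  }
})

test_that("a graph with exactly three simple routes returns all three", {
  # triangle plus pendant: 1-2, 2-3, 1-3 all covalent; routes 1->3:
  # (1,3), (1,2,3) and that is all
  atoms <- make_atoms(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0)))
  g <- build_coupling_graph(atoms)
  ps <- k_best_paths(g, "X/1/C", "X/3/C", k = 200)
  expect_equal(length(ps), 2)
  expect_equal(ps[[1]]$T_DA, 0.6)
  expect_equal(ps[[2]]$T_DA, 0.36)
})

test_that("removing an edge of the best path never improves the coupling", {
  for (seed in c(7, 8, 9)) {
    atoms <- random_atom_cloud(10, seed = seed)
    g <- build_coupling_graph(atoms)
    from <- g$nodes$node_id[1]; to <- g$nodes$node_id[10]
    p <- best_path(g, from, to)
    if (p$no_path) next
    for (e in seq_len(nrow(p$edges))) {
      g2 <- g
      eid <- igraph::get_edge_ids(g$graph,
                                  c(p$nodes[e], p$nodes[e + 1]))
      g2$graph <- igraph::delete_edges(g$graph, eid)
      p2 <- best_path(g2, from, to)
      if (!p2$no_path) expect_lte(p2$T_DA, p$T_DA + 1e-12)
    }
  }
})

test_that("bond patches force covalent edges between named atoms", {
  atoms <- make_atoms(rbind(c(0, 0, 0), c(2.4, 0, 0)))
  g0 <- build_coupling_graph(atoms)
  expect_equal(g0$edges$kind, "space")
  patch <- tibble::tibble(atom1 = "X/1/C", atom2 = "X/2/C")
  g1 <- build_coupling_graph(atoms, extra_bonds = patch)
  expect_equal(g1$edges$kind, "covalent")
  expect_equal(g1$edges$eps, 0.6)
})

test_that("metal coordination bonds are detected at metal-ligand range", {
  atoms <- make_atoms(rbind(c(0, 0, 0), c(2.3, 0, 0)),
                      element = c("FE", "N"), name = c("FE", "ND1"))
  g <- build_coupling_graph(atoms)
  expect_equal(g$edges$kind, "covalent")
})
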