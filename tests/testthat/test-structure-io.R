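test_that("a minimal one-atom PDB parses into a one-row atom table", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104  13.207   2.100  1.00 20.50           C",
    "END"), path)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 1)
  a <- m$atoms
  expect_equal(a$name, "CA")
  expect_equal(a$chain, "A")
  expect_equal(a$resseq, 1L)
  expect_equal(c(a$x, a$y, a$z), c(11.104, 13.207, 2.100))
  expect_equal(a$bfactor, 20.5)
  expect_false(a$is_water)
  expect_null(m$cell)
})

test_that("write-then-read round-trips coordinates, B, cell and symops", {
  tc <- make_toy_complex(seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tc$model, path)
  m2 <- read_structure(path)
  a1 <- tc$model$atoms; a2 <- m2$atoms
  expect_equal(nrow(a2), nrow(a1))
  expect_lt(max(abs(a2$x - a1$x), abs(a2$y - a1$y), abs(a2$z - a1$z)), 1e-3)
  expect_equal(a2$bfactor, a1$bfactor, tolerance = 1e-6)
  expect_equal(a2$name, a1$name)
  expect_equal(a2$is_water, a1$is_water)
  expect_equal(m2$cell$a, tc$model$cell$a, tolerance = 1e-3)
  expect_equal(m2$cell$beta, 102.1)
  expect_equal(length(m2$cell$symops), 2)
  # symops survive via REMARK 290 (a two-fold screw along b)
  expect_equal(m2$cell$symops[[2]]$R, diag(c(-1, 1, -1)))
  expect_equal(m2$cell$symops[[2]]$t, c(0, 0.5, 0))
})

test_that("mmCIF input yields the same atom model with cell and symops", {
  m <- read_structure(test_path("fixtures", "minimal.cif"))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$name, c("CA", "O"))
  expect_equal(m$atoms$is_water, c(FALSE, TRUE))
  expect_equal(m$atoms$bfactor, c(20.5, 30))
  expect_equal(m$cell$a, 20)
  expect_equal(m$cell$spacegroup, "P 1 21 1")
  expect_equal(length(m$cell$symops), 2)
})

test_that("unreadable input and unknown space groups raise clear errors", {
  expect_error(read_structure("does-not-exist.pdb"), "not found")
  expect_error(spacegroup_symops("P 63"), "no built-in symmetry")
})

test_that("complex selection partitions atoms and validates chains", {
  tc <- make_toy_complex(seed = 5)
  spec <- complex_spec("A", "B")
  sel <- select_complex(tc$model, spec)
  expect_equal(nrow(sel$waters), sum(tc$n_waters))
  # partition: A, B and waters are disjoint and cover all kept atoms
  ids <- c(sel$A$serial, sel$B$serial, sel$waters$serial)
  expect_equal(anyDuplicated(ids), 0L)
  expect_setequal(ids, tc$model$atoms$serial)
  expect_error(select_complex(tc$model, complex_spec("A", "Q")),
               "chains not present")
  expect_error(select_complex(tc$model, complex_spec("A", "A")),
               "disjoint")
})

test_that("alternate conformers beyond the kept codes are dropped", {
  atoms <- make_atoms(rbind(c(0, 0, 0), c(0.3, 0, 0), c(5, 0, 0)),
                      chain = c("A", "A", "B"), resseq = c(1, 1, 1),
                      name = "CA")
  atoms$altloc <- c("A", "B", "")
  m <- structure_model(atoms)
  sel <- select_complex(m, complex_spec("A", "B"))
  expect_equal(nrow(sel$A), 1)
  expect_equal(sel$A$altloc, "A")
})

test_that("donor/acceptor selectors resolve within their protein", {
  tc <- make_toy_complex(seed = 2, n_res_A = 5, n_res_B = 5)
  spec <- complex_spec("A", "B", donor_atom = "A/3/NZ",
                       acceptor_atom = "B/3/OD2")
  sel <- select_complex(tc$model, spec)
  expect_equal(sel$donor$name, "NZ")
  expect_equal(sel$acceptor$name, "OD2")
  expect_error(
    select_complex(tc$model, complex_spec("A", "B", donor_atom = "A/99/NZ")),
    "donor atom not found")
})

test_that("YAML complex specs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("chains_A: [A]", "chains_B: [B]",
               "cofactors_A: [HEC]", "donor_atom: A/3/NZ"), path)
  spec <- read_complex_spec(path)
  expect_equal(spec$chains_A, "A")
  expect_equal(spec$cofactors_A, "HEC")
  expect_equal(spec$donor_atom, "A/3/NZ")
})
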