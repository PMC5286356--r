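# Structure input/output: uniform atom table + crystal metadata.

#' Construct a structure model
#'
#' A structure model bundles a per-atom tibble with optional crystal metadata.
#' The atom table is the package's working currency: every analysis function
#' takes atom tibbles (or selections of them) and returns tibbles.
#'
#' @param atoms Tibble with one row per atom. Required columns: `serial`,
#'   `name`, `element`, `altloc`, `resname`, `chain`, `resseq`, `icode`,
#'   `x`, `y`, `z`, `occupancy`, `bfactor`, `is_water`, `is_hetero`.
#' @param cell Optional crystal cell, as returned by [crystal_cell()].
#' @param source_id Label for provenance (accession or file name).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, source_id = "") {
  atoms <- tibble::as_tibble(atoms)
  req <- c("serial", "name", "element", "altloc", "resname", "chain",
           "resseq", "icode", "x", "y", "z", "occupancy", "bfactor",
           "is_water", "is_hetero")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
    stop("occupancies must lie in [0, 1]")
  }
  if (any(!nzchar(atoms$element))) {
    stop("every atom needs a non-empty element symbol")
  }
  structure(list(atoms = atoms, cell = cell, source_id = source_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$source_id, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms),
      " (waters: ", sum(x$atoms$is_water),
      ", hetero: ", sum(x$atoms$is_hetero), ")\n", sep = "")
  cat("  chains: ", paste(sort(unique(x$atoms$chain)), collapse = " "), "\n",
      sep = "")
  if (!is.null(x$cell)) {
    cat(sprintf("  cell: %.1f %.1f %.1f / %.1f %.1f %.1f  %s (%d symops)\n",
                x$cell$a, x$cell$b, x$cell$c, x$cell$alpha, x$cell$beta,
                x$cell$gamma, x$cell$spacegroup, length(x$cell$symops)))
  }
  invisible(x)
}

#' Construct a crystal cell
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @param spacegroup Hermann-Mauguin symbol (e.g. `"P 1 21 1"`).
#' @param symops Optional list of symmetry operators, each a list with a 3x3
#'   rotation `R` and translation `t` in fractional coordinates. When `NULL`
#'   the operators are looked up from a built-in table for common space
#'   groups (P 1, P 1 21 1, P 21 21 21, C 1 2 1).
#' @return A `crystal_cell` list, including the orthogonalization matrix
#'   `ortho` (fractional -> cartesian).
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                         spacegroup = "P 1", symops = NULL) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  if (is.null(symops)) symops <- spacegroup_symops(spacegroup)
  if (length(symops) == 0) stop("symmetry operator list must be non-empty")
  has_identity <- any(vapply(symops, function(op) {
    isTRUE(all.equal(op$R, diag(3))) && isTRUE(all.equal(op$t, c(0, 0, 0)))
  }, logical(1)))
  if (!has_identity) stop("symmetry operators must include the identity")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  ortho <- matrix(c(a, b * cg, c * cb,
                    0, b * sg, c * (ca - cb * cg) / sg,
                    0, 0,      c * v / sg),
                  nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, spacegroup = spacegroup, symops = symops,
                 ortho = ortho),
            class = "crystal_cell")
}

sym_op <- function(R, t) list(R = R, t = t)

#' Symmetry operators for common space groups
#'
#' Built-in fractional-coordinate operators for the space groups the package
#' encounters in practice. Files carrying explicit `REMARK 290 SMTRY`
#' records override this table.
#'
#' @param spacegroup Hermann-Maugin symbol; short forms (`"P21"`) accepted.
#' @return List of operators, each `list(R = 3x3, t = length-3)`.
#' @export
spacegroup_symops <- function(spacegroup) {
  key <- toupper(gsub("[[:space:]_]", "", spacegroup))
  I3 <- diag(3)
  ops <- switch(key,
    "P1" = list(sym_op(I3, c(0, 0, 0))),
    "P21" = , "P1211" = list(
      sym_op(I3, c(0, 0, 0)),
      sym_op(diag(c(-1, 1, -1)), c(0, 0.5, 0))),
    "P212121" = list(
      sym_op(I3, c(0, 0, 0)),
      sym_op(diag(c(1, -1, -1)), c(0.5, 0.5, 0)),
      sym_op(diag(c(-1, 1, -1)), c(0, 0.5, 0.5)),
      sym_op(diag(c(-1, -1, 1)), c(0.5, 0, 0.5))),
    "C2" = , "C121" = list(
      sym_op(I3, c(0, 0, 0)),
      sym_op(diag(c(-1, 1, -1)), c(0, 0, 0)),
      sym_op(I3, c(0.5, 0.5, 0)),
      sym_op(diag(c(-1, 1, -1)), c(0.5, 0.5, 0))),
    NULL)
  if (is.null(ops)) {
    stop("no built-in symmetry operators for space group '", spacegroup,
         "'; supply symops explicitly or use a file with REMARK 290 records")
  }
  ops
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a [structure_model()]. All ATOM/HETATM
#' records are retained (waters, altlocs included); anisotropic displacement
#' records are ignored in favour of the stored isotropic B. Crystal cell and
#' symmetry operators are populated when the header carries them.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", dialect, ": ",
                             conditionMessage(e)))
  at <- parsed$atom
  element <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                   guess_element(at$elety), at$elesy)))
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = element,
    altloc = ifelse(is.na(at$alt), "", trimws(at$alt)),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", trimws(at$chain)),
    resseq = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", trimws(at$insert)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    is_water = trimws(at$resid) %in% WATER_RESNAMES,
    is_hetero = at$type == "HETATM"
  )
  cell <- if (dialect == "pdb") parse_pdb_cell(path) else parse_cif_cell(path)
  structure_model(atoms, cell = cell,
                  source_id = sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                                  ignore.case = TRUE))
}

# Fallback element assignment from the atom name, for files that omit the
# element column: strip digits/primes, take the leading alphabetic token.
guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("FE", "CU", "ZN", "MG", "MN", "NA", "CL", "BR"),
         two, substr(gsub("^[0-9']*", "", nm), 1, 1))
}

parse_pdb_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  cl <- cl[1]
  num <- function(from, to) as.numeric(substr(cl, from, to))
  sg <- trimws(substr(cl, 56, 66))
  symops <- parse_remark290(lines)
  if (is.null(symops)) symops <- spacegroup_symops(sg)
  crystal_cell(num(7, 15), num(16, 24), num(25, 33),
               num(34, 40), num(41, 47), num(48, 54),
               spacegroup = sg, symops = symops)
}

parse_remark290 <- function(lines) {
  sm <- grep("^REMARK 290\\s+SMTRY", lines, value = TRUE)
  if (length(sm) == 0) return(NULL)
  fields <- lapply(strsplit(trimws(sm), "\\s+"), function(f) {
    # REMARK 290 SMTRYn opno r1 r2 r3 t
    list(row = as.integer(sub("SMTRY", "", f[3])),
         op = as.integer(f[4]),
         vals = as.numeric(f[5:8]))
  })
  ops <- list()
  for (fl in fields) {
    k <- fl$op
    if (length(ops) < k || is.null(ops[k][[1]])) {
      ops[[k]] <- list(R = matrix(0, 3, 3), t = c(0, 0, 0))
    }
    ops[[k]]$R[fl$row, ] <- fl$vals[1:3]
    ops[[k]]$t[fl$row] <- fl$vals[4]
  }
  ops
}

parse_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  a <- grab("_cell\\.length_a")
  if (is.na(a)) return(NULL)
  sg_ln <- grep("^_symmetry\\.space_group_name_H-M", lines, value = TRUE)
  sg <- if (length(sg_ln) > 0) {
    gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sg_ln[1])))
  } else "P 1"
  crystal_cell(a, grab("_cell\\.length_b"), grab("_cell\\.length_c"),
               grab("_cell\\.angle_alpha"), grab("_cell\\.angle_beta"),
               grab("_cell\\.angle_gamma"), spacegroup = sg)
}

#' Write a structure model as PDB text
#'
#' Emits a fixed-width PDB file (CRYST1, REMARK 290 symmetry records,
#' ATOM/HETATM, TER, END). Output is byte-deterministic for a given model,
#' which the synthetic-data generator relies on.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  lines <- character(0)
  if (!is.null(model$cell)) {
    cc <- model$cell
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cc$a, cc$b, cc$c, cc$alpha, cc$beta, cc$gamma, cc$spacegroup,
      length(cc$symops)))
    for (k in seq_along(cc$symops)) {
      op <- cc$symops[[k]]
      for (r in 1:3) {
        lines <- c(lines, sprintf(
          "REMARK 290   SMTRY%d %3d%10.6f%10.6f%10.6f%15.5f",
          r, k, op$R[r, 1], op$R[r, 2], op$R[r, 3], op$t[r]))
      }
    }
  }
  at <- model$atoms
  rec <- ifelse(at$is_hetero | at$is_water, "HETATM", "ATOM  ")
  # PDB atom-name column rule: 1-3 character names start in column 14
  nm <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
               paste0(" ", formatC(at$name, width = -3)))
  lines <- c(lines, sprintf(
    "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, at$serial %% 100000L, nm, substr(paste0(at$altloc, " "), 1, 1),
    at$resname, substr(paste0(at$chain, " "), 1, 1), at$resseq,
    substr(paste0(at$icode, " "), 1, 1),
    at$x, at$y, at$z, at$occupancy, at$bfactor, at$element))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Qualified atom identifiers
#'
#' `chain/resseq[/icode]/name` labels used throughout reports and graphs.
#'
#' @param atoms Atom tibble.
#' @return Character vector, one id per row.
#' @export
atom_id <- function(atoms) {
  ic <- ifelse(nzchar(atoms$icode), paste0(".", atoms$icode), "")
  paste0(atoms$chain, "/", atoms$resseq, ic, "/", atoms$name)
}

#' Resolve an atom selector string
#'
#' Selectors are `"chain/resseq/name"` (e.g. `"C/104/FE"`). Returns the
#' matching rows of `atoms`.
#'
#' @param atoms Atom tibble.
#' @param selector Selector string.
#' @return Tibble of matching atoms.
#' @export
resolve_selector <- function(atoms, selector) {
  parts <- strsplit(selector, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop("selector must be 'chain/resseq/name', got: ", selector)
  }
  dplyr::filter(atoms, .data$chain == parts[1],
                .data$resseq == as.integer(parts[2]),
                .data$name == parts[3])
}
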