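# One-command orchestration of the full soft-contact interface report.

run_stage <- function(results, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(list(ok = TRUE, value = fun(), error = NULL),
                  error = function(e)
                    list(ok = FALSE, value = NULL,
                         error = conditionMessage(e)))
  out$elapsed <- proc.time()[["elapsed"]] - t0
  results[[name]] <- out
  results
}

#' Run the full interface report
#'
#' Executes, in order: complex selection, the polar-contact inventory, the
#' shortest inter-chain C-alpha distance, the contact surface area, the
#' interface-water census (with contact profile, hydrogen-bond network and
#' B statistics), the B-factor fulcrum profile (anchored on the A-side
#' contact atoms), the tunneling-path search (when donor and acceptor are
#' declared) and the closest crystal-symmetry contact (when a cell is
#' present). Stage failures are recorded and do not abort later stages.
#'
#' @param x A `structure_model` or a path to a PDB/mmCIF file.
#' @param spec A [complex_spec()] or path to its YAML form.
#' @param shell Interface water shell (default 7 A).
#' @param cutoff Interaction / polar-contact / hydrogen-bond cutoff
#'   (default 3.5 A).
#' @param probe SASA probe radius (default 1.4 A).
#' @param n_points SASA sampling density (default 960).
#' @param space_cutoff Through-space edge cutoff for the tunneling graph
#'   (default 5 A).
#' @param k_paths Candidate tunneling routes to enumerate (default 200).
#' @param csa_convention `"half"` or `"full"` buried-area convention.
#' @param extra_bonds Optional covalent bond patches for the tunneling
#'   graph (see [build_coupling_graph()]).
#' @param decay_params Tunneling decay parameters ([et_params()]).
#' @return A `softcontact_report`: list of stage results with the resolved
#'   parameters attached; see [report_summary()].
#' @export
run_report <- function(x, spec, shell = 7, cutoff = 3.5, probe = 1.4,
                       n_points = 960, space_cutoff = 5.0, k_paths = 200,
                       csa_convention = c("half", "full"),
                       extra_bonds = NULL, decay_params = et_params()) {
  csa_convention <- match.arg(csa_convention)
  model <- if (inherits(x, "structure_model")) x else read_structure(x)
  if (is.character(spec)) spec <- read_complex_spec(spec)
  params <- list(shell = shell, cutoff = cutoff, probe = probe,
                 n_points = n_points, space_cutoff = space_cutoff,
                 k_paths = k_paths, csa_convention = csa_convention)
  res <- list()
  res <- run_stage(res, "selection", function() select_complex(model, spec))
  if (!res$selection$ok) {
    return(structure(list(stages = res, params = params,
                          source_id = model$source_id),
                     class = "softcontact_report"))
  }
  sel <- res$selection$value
  res <- run_stage(res, "polar_contacts", function()
    polar_contact_inventory(sel$A, sel$B, max_dist = cutoff))
  res <- run_stage(res, "min_ca_distance", function()
    min_interchain_ca_distance(sel$A, sel$B))
  res <- run_stage(res, "contact_surface_area", function()
    contact_surface_area(sel$A, sel$B, probe = probe, n_points = n_points,
                         convention = csa_convention))
  res <- run_stage(res, "water_census", function() {
    iw <- select_interface_waters(sel$waters, sel$A, sel$B, shell = shell)
    classify_waters(iw, sel$A, sel$B, cutoff = cutoff)
  })
  if (res$water_census$ok) {
    census <- res$water_census$value
    res <- run_stage(res, "water_contacts", function()
      water_contact_profile(census, sel$A, sel$B, waters = sel$waters,
                            cutoff = cutoff))
    res <- run_stage(res, "hbond_network", function()
      build_hbond_network(census, sel$A, sel$B, hb_cutoff = cutoff))
    res <- run_stage(res, "water_bfactors", function()
      water_bfactor_stats(census))
  }
  res <- run_stage(res, "fulcrum", function() {
    contacts <- res$polar_contacts$value
    anchors <- if (!is.null(contacts) && nrow(contacts) > 0) {
      dplyr::filter(sel$A, atom_id(sel$A) %in% contacts$atom_A)
    } else {
      # no polar contacts: anchor on the A atoms nearest to B
      d <- min_dist_to(sel$A, sel$B)
      sel$A[d <= min(d) + 1e-9, ]
    }
    fulcrum_profile(dplyr::filter(sel$A, !.data$is_hetero), anchors)
  })
  if (!is.null(sel$donor) && !is.null(sel$acceptor)) {
    res <- run_stage(res, "et_pathway", function() {
      g <- build_coupling_graph(dplyr::bind_rows(sel$A, sel$B),
                                hb_cutoff = cutoff,
                                space_cutoff = space_cutoff,
                                extra_bonds = extra_bonds,
                                params = decay_params)
      best <- best_path(g, atom_id(sel$donor), atom_id(sel$acceptor))
      list(graph = g, best = best)
    })
  }
  if (!is.null(model$cell)) {
    res <- run_stage(res, "symmetry_contact", function()
      closest_symmetry_contact(model, sel$A))
  } else {
    res[["symmetry_contact"]] <- list(ok = TRUE, value = NULL,
                                      error = NULL, skipped = "no cell",
                                      elapsed = 0)
  }
  structure(list(stages = res, params = params,
                 source_id = model$source_id),
            class = "softcontact_report")
}

#' @export
print.softcontact_report <- function(x, ...) {
  cat("<softcontact_report> ", x$source_id, "\n", sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    status <- if (!is.null(st$skipped)) paste0("skipped: ", st$skipped)
      else if (st$ok) "ok" else paste0("FAILED: ", st$error)
    cat(sprintf("  %-22s %s (%.2fs)\n", nm, status, st$elapsed))
  }
  invisible(x)
}

#' Flat numeric summary of a report
#'
#' One-row tibble of the report's headline numbers, suitable for survey
#' tables and machine-readable export.
#'
#' @param report A `softcontact_report`.
#' @return One-row tibble.
#' @export
report_summary <- function(report) {
  st <- report$stages
  val <- function(nm) if (!is.null(st[[nm]]) && st[[nm]]$ok)
    st[[nm]]$value else NULL
  census <- val("water_census")
  counts <- if (!is.null(census)) table(census$category) else NULL
  best <- val("et_pathway")$best
  tibble::tibble(
    source_id = report$source_id,
    ok = all(vapply(st, function(s) s$ok, logical(1))),
    n_polar_contacts = if (!is.null(val("polar_contacts")))
      nrow(val("polar_contacts")) else NA_integer_,
    min_ca_distance = if (!is.null(val("min_ca_distance")))
      val("min_ca_distance")$distance else NA_real_,
    contact_surface_area = val("contact_surface_area") %||% NA_real_,
    n_interface_waters = if (!is.null(census)) nrow(census) else NA_integer_,
    n_bridging = if (!is.null(counts)) unname(counts["bridging"])
      else NA_integer_,
    n_nonbridging_A = if (!is.null(counts)) unname(counts["nonbridging_A"])
      else NA_integer_,
    n_nonbridging_B = if (!is.null(counts)) unname(counts["nonbridging_B"])
      else NA_integer_,
    n_noninteracting = if (!is.null(counts))
      unname(counts["noninteracting"]) else NA_integer_,
    mean_water_b = if (!is.null(census) && nrow(census) > 0)
      mean(census$bfactor) else NA_real_,
    fulcrum_spearman = if (!is.null(val("fulcrum")))
      val("fulcrum")$spearman else NA_real_,
    t_da = if (!is.null(best) && !best$no_path) best$T_DA else NA_real_,
    et_running_distance = if (!is.null(best) && !best$no_path)
      best$running_distance else NA_real_,
    symmetry_contact = if (!is.null(val("symmetry_contact")))
      val("symmetry_contact")$distance else NA_real_)
}

#' Write a report bundle to disk
#'
#' TSV tables (contacts, water census, network edges, fulcrum profile) plus
#' a JSON summary embedding the resolved parameters.
#'
#' @param report A `softcontact_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  tsv <- function(x, name) readr::write_tsv(x, file.path(dir, name))
  if (isTRUE(st$polar_contacts$ok)) {
    tsv(st$polar_contacts$value, "polar_contacts.tsv")
  }
  if (isTRUE(st$water_census$ok)) {
    tsv(tibble::as_tibble(st$water_census$value), "water_census.tsv")
  }
  if (isTRUE(st$hbond_network$ok)) {
    tsv(st$hbond_network$value$edges, "hbond_edges.tsv")
  }
  if (isTRUE(st$fulcrum$ok)) {
    tsv(st$fulcrum$value$per_atom, "fulcrum_profile.tsv")
  }
  summary <- c(as.list(report_summary(report)), list(params = report$params))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Survey a batch of complexes
#'
#' Runs [run_report()] over a table of entries, tolerating per-entry
#' failure: failed rows are flagged (`ok = FALSE`), and only if every entry
#' fails is an error raised.
#'
#' @param entries Tibble with columns `structure` (paths or
#'   `structure_model`s in a list column) and `spec` (paths or
#'   `complex_spec`s in a list column); an optional `id` column labels rows.
#' @param ... Passed to [run_report()].
#' @return Tibble, one row per entry: id, `ok`, shortest C-alpha distance,
#'   contact surface area and water counts, with `error` text for failed
#'   rows.
#' @export
batch_survey <- function(entries, ...) {
  stopifnot(nrow(entries) >= 1)
  rows <- purrr::map(seq_len(nrow(entries)), function(i) {
    id <- if ("id" %in% names(entries)) entries$id[[i]] else
      as.character(i)
    x <- entries$structure[[i]]
    sp <- entries$spec[[i]]
    tryCatch({
      rep <- run_report(x, sp, ...)
      if (!rep$stages$selection$ok) stop(rep$stages$selection$error)
      out <- report_summary(rep)
      out$source_id <- id
      out$error <- NA_character_
      out
    }, error = function(e) {
      tibble::tibble(source_id = id, ok = FALSE,
                     error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  if (all(!is.na(out$error))) {
    stop("batch_survey: every entry failed")
  }
  out
}
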