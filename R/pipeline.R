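#' Analysis configuration with field-standard defaults
#'
#' Collects every tunable of the pipeline in one validated object. The
#' defaults are the conventional values of the method: contact cutoff
#' 0.45 nm, strength-cutoff scan from 0 to 40 in steps of 0.2, edge
#' persistence threshold 0.5, correlation significance cutoff 0.5, path
#' occurrence threshold 0.15, paths longer than three (at least 4 nodes),
#' long-range class at 8 or more nodes, hub degree at least 4.
#'
#' @param input Path to a multi-model PDB (or `NULL` when the ensemble is
#'   passed to [run_pipeline()] directly).
#' @param targets Integer vector of target residue indices (e.g. the
#'   DNA-binding loops).
#' @param selection_policy Contact atom policy (see [select_atoms()]).
#' @param distance_cutoff Contact distance cutoff in nm.
#' @param seq_exclusion Minimum sequence separation for contacts.
#' @param imin_range,imin_step Strength-cutoff scan grid.
#' @param i_min Fixed strength cutoff; `NULL` (default) uses the detected
#'   critical cutoff.
#' @param persistence_threshold Consensus edge persistence threshold.
#' @param lmi_window_frames Frames per correlation window; `NULL` uses the
#'   ensemble's `frames_per_window`.
#' @param lmi_cutoff Correlation significance cutoff.
#' @param min_occurrence Path occurrence threshold.
#' @param min_node_count Minimum path node count (endpoints included).
#' @param long_range_nodes Node count defining the long-range class.
#' @param hub_min_degree Minimum hub degree.
#' @param seed RNG seed recorded in the run manifest.
#' @param output_dir Output directory for [run_pipeline()].
#' @return An `analysis_config`.
#' @export
analysis_config <- function(input = NULL,
                            targets = integer(0),
                            selection_policy = "side-chain-heavy",
                            distance_cutoff = 0.45,
                            seq_exclusion = 2,
                            imin_range = c(0, 40),
                            imin_step = 0.2,
                            i_min = NULL,
                            persistence_threshold = 0.5,
                            lmi_window_frames = NULL,
                            lmi_cutoff = 0.5,
                            min_occurrence = 0.15,
                            min_node_count = 4,
                            long_range_nodes = 8,
                            hub_min_degree = 4,
                            seed = 0,
                            output_dir = NULL) {
  stopifnot_range <- function(x, lo, hi, name) {
    if (!is.numeric(x) || any(x < lo) || any(x > hi)) {
      abort_invalid(sprintf("`%s` must lie in [%g, %g]", name, lo, hi))
    }
  }
  stopifnot_range(distance_cutoff, 1e-6, 10, "distance_cutoff")
  stopifnot_range(persistence_threshold, 0, 1, "persistence_threshold")
  stopifnot_range(lmi_cutoff, 1e-9, 1 - 1e-9, "lmi_cutoff")
  stopifnot_range(min_occurrence, 0, 1, "min_occurrence")
  if (imin_step <= 0) abort_invalid("`imin_step` must be positive")
  if (length(imin_range) != 2 || imin_range[2] <= imin_range[1]) {
    abort_invalid("`imin_range` must be an increasing pair")
  }
  if (min_node_count < 2) abort_invalid("`min_node_count` must be at least 2")
  if (long_range_nodes < 2) abort_invalid("`long_range_nodes` must be at least 2")
  if (hub_min_degree < 1) abort_invalid("`hub_min_degree` must be at least 1")
  structure(
    list(input = input, targets = as.integer(targets),
         selection_policy = selection_policy,
         distance_cutoff = distance_cutoff, seq_exclusion = as.integer(seq_exclusion),
         imin_range = imin_range, imin_step = imin_step, i_min = i_min,
         persistence_threshold = persistence_threshold,
         lmi_window_frames = lmi_window_frames, lmi_cutoff = lmi_cutoff,
         min_occurrence = min_occurrence, min_node_count = as.integer(min_node_count),
         long_range_nodes = as.integer(long_range_nodes),
         hub_min_degree = as.integer(hub_min_degree),
         seed = as.integer(seed), output_dir = output_dir),
    class = "analysis_config"
  )
}

#' Read/write an analysis configuration as YAML
#'
#' The configuration round-trips through its file representation without
#' loss, so a run can always be reproduced from its recorded config.
#'
#' @param config An [analysis_config()].
#' @param path YAML file path.
#' @return [write_config()]: `path`, invisibly. [read_config()]: an
#'   `analysis_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(analysis_config, x)
}

#' Run the full ensemble-to-paths pipeline
#'
#' Executes, in order: atom selection, per-frame contact counting,
#' normalization and interaction strengths, the strength-cutoff scan with
#' critical-cutoff detection, the consensus network with hub analysis,
#' windowed LMI correlation matrices, per-window consensus networks,
#' correlation-filtered shortest paths to the targets, the long-range
#' partition, and the occurrence-weighted meta-graph. Artifacts (CSV, JSON,
#' GML) and a machine-readable manifest are written to
#' `config$output_dir` when set. Any stage failure aborts with the stage
#' name and leaves a `FAILED` marker in the output directory.
#'
#' @param config An [analysis_config()].
#' @param ensemble Optional in-memory [ensemble()]; otherwise read from
#'   `config$input`.
#' @return A `psn_run` list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, ensemble = NULL) {
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  fail <- function(stage, err) {
    if (!is.null(out_dir)) {
      writeLines(c(stage, conditionMessage(err)), file.path(out_dir, "FAILED"))
    }
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(err)),
                 class = "psnpaths_stage_error", parent = err)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  if (is.null(ensemble)) {
    ensemble <- stage("read", {
      if (is.null(config$input)) abort_invalid("no input file and no in-memory ensemble")
      read_ensemble(config$input)
    })
  }
  selection <- stage("select", select_atoms(ensemble, config$selection_policy))
  record <- stage("contacts", count_atom_pairs(
    ensemble, selection, cutoff = config$distance_cutoff,
    seq_exclusion = config$seq_exclusion))
  record <- stage("strengths", interaction_strength(record))
  scan <- stage("scan", imin_scan(record$I_mean, range = config$imin_range,
                                  step = config$imin_step))
  icrit <- stage("icrit", tryCatch(detect_icrit(scan),
                                   psnpaths_no_transition = function(e) NULL))
  i_min <- config$i_min
  if (is.null(i_min)) {
    if (is.null(icrit)) fail("icrit", simpleError("no transition and no explicit i_min"))
    i_min <- icrit$i_crit
  }
  consensus <- stage("consensus", consensus_psn(
    record, i_min = i_min, persistence_threshold = config$persistence_threshold))
  hub_table <- stage("hubs", hubs(consensus, min_degree = config$hub_min_degree))

  window_frames <- config$lmi_window_frames
  if (is.null(window_frames)) window_frames <- ensemble$frames_per_window
  lmi <- stage("lmi", lmi_windows(ensemble, window_frames = window_frames))
  window_graphs <- stage("window-graphs", {
    nw <- lmi$n_windows
    lapply(seq_len(nw), function(w) {
      frames <- ((w - 1L) * window_frames + 1L):(w * window_frames)
      consensus_psn(record$I_ij[, , frames, drop = FALSE], i_min = i_min,
                    persistence_threshold = config$persistence_threshold,
                    labels = record$residue_types)
    })
  })
  paths <- NULL; partition <- NULL; meta <- NULL
  if (length(config$targets) > 0) {
    paths <- stage("paths", paths_to_targets(
      consensus, lmi$average, window_graphs, targets = config$targets,
      min_occurrence = config$min_occurrence,
      min_node_count = config$min_node_count,
      lmi_cutoff = config$lmi_cutoff))
    partition <- stage("long-range", classify_long_range(paths, config$long_range_nodes))
    if (nrow(paths) > 0) meta <- stage("metagraph", build_metagraph(paths))
  }

  manifest <- list(
    package = "psnpaths",
    version = as.character(utils::packageVersion("psnpaths")),
    seed = config$seed,
    n_frames = n_frames(ensemble),
    n_residues = n_residues(ensemble),
    i_min = i_min,
    i_crit = if (!is.null(icrit)) icrit$i_crit,
    stages = c("read", "select", "contacts", "strengths", "scan", "icrit",
               "consensus", "hubs", "lmi", "window-graphs",
               if (!is.null(paths)) c("paths", "long-range", "metagraph")),
    parameters = unclass(config)[setdiff(names(unclass(config)), c("input", "output_dir"))]
  )

  run <- structure(
    list(config = config, ensemble = ensemble, record = record, scan = scan,
         icrit = icrit, i_min = i_min, consensus = consensus, hubs = hub_table,
         lmi = lmi, window_graphs = window_graphs, paths = paths,
         partition = partition, metagraph = meta, manifest = manifest),
    class = "psn_run"
  )
  if (!is.null(out_dir)) stage("write", write_run_artifacts(run, out_dir))
  run
}

# CSV/JSON/GML artifacts of a completed run
write_run_artifacts <- function(run, out_dir) {
  labels <- run$record$residue_types
  write_matrix_csv(apply(run$record$n_ij, c(1, 2), mean),
                   file.path(out_dir, "n_ij_mean.csv"), labels)
  write_matrix_csv(run$record$I_mean, file.path(out_dir, "I_ij_mean.csv"), labels)
  utils::write.csv(as.data.frame(run$scan), file.path(out_dir, "imin_scan.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(node_degrees(run$consensus)),
                   file.path(out_dir, "degrees.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$hubs), file.path(out_dir, "hubs.csv"),
                   row.names = FALSE)
  write_matrix_csv(run$lmi$average, file.path(out_dir, "lmi_average.csv"), labels)
  write_matrix_dat(run$lmi$average, file.path(out_dir, "lmi_average.dat"))
  write_graph_file(run$consensus, file.path(out_dir, "consensus_psn.gml"), "gml")
  if (!is.null(run$paths)) {
    write_paths_json(run$paths, file.path(out_dir, "paths.json"), labels = NULL)
    utils::write.csv(as.data.frame(run$partition$histogram),
                     file.path(out_dir, "path_length_histogram.csv"), row.names = FALSE)
    if (!is.null(run$metagraph)) {
      write_graph_file(run$metagraph, file.path(out_dir, "metagraph.gml"), "gml")
      utils::write.csv(as.data.frame(run$metagraph$nodes),
                       file.path(out_dir, "mediators.csv"), row.names = FALSE)
    }
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.psn_run <- function(x, ...) {
  cat(sprintf("<psn_run> %d residues, %d frames; i_min %.3g; %d consensus edges",
              n_residues(x$ensemble), n_frames(x$ensemble), x$i_min,
              nrow(x$consensus$edges)))
  if (!is.null(x$paths)) cat(sprintf("; %d retained paths", nrow(x$paths)))
  cat("\n")
  invisible(x)
}

#' Compare two completed runs
#'
#' Reports per-residue hub-degree differences, the path-set differences
#' (paths only in A, only in B, shared), the ratio of long-range path
#' counts, and the Frobenius comparison of the two average correlation
#' matrices. Applied to a free and a ligand-bound condition of the same
#' protein, this is the comparison that reveals strengthened or lost
#' long-range communication routes.
#'
#' @param run_a,run_b `psn_run` objects over the same residue set.
#' @return A `run_comparison` list: `hub_deltas`, `path_diff`,
#'   `long_range_ratio`, `lmi_comparison`.
#' @export
compare_runs <- function(run_a, run_b) {
  na <- n_residues(run_a$ensemble); nb <- n_residues(run_b$ensemble)
  if (na != nb) {
    abort_invalid(sprintf(
      "runs have different residue counts (%d vs %d); map numbering before comparing", na, nb))
  }
  da <- node_degrees(run_a$consensus); db <- node_degrees(run_b$consensus)
  hub_deltas <- tibble::tibble(
    residue = da$residue, label = da$label,
    degree_a = da$degree, degree_b = db$degree,
    delta = db$degree - da$degree
  )
  path_diff <- NULL; long_range_ratio <- NA_real_
  if (!is.null(run_a$paths) && !is.null(run_b$paths)) {
    path_diff <- compare_path_sets(run_a$paths, run_b$paths)
    la <- nrow(run_a$partition$long_range); lb <- nrow(run_b$partition$long_range)
    long_range_ratio <- if (la > 0) lb / la else NA_real_
  }
  structure(
    list(hub_deltas = hub_deltas, path_diff = path_diff,
         long_range_ratio = long_range_ratio,
         lmi_comparison = frobenius_norm(run_a$lmi$average, run_b$lmi$average)),
    class = "run_comparison"
  )
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("<run_comparison> LMI Frobenius %.3f; long-range ratio %.3g; max |hub delta| %d\n",
              x$lmi_comparison$frobenius, x$long_range_ratio, max(abs(x$hub_deltas$delta))))
  invisible(x)
}
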