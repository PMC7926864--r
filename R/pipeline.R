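#' Build a validated analysis configuration
#'
#' Collects the tunable parameters of the full pipeline in one object:
#' cutoff `rc` (9 Angstrom by default, the B-factor-calibrated value), spring
#' constant `gamma` (1, arbitrary units; the spectrum scale), dominant-mode
#' overlap threshold (0.35), hot-spot fraction (0.02), SPM perturbation
#' fraction `delta_gamma` (0.01) and whether the end conformation is aligned
#' before the transition vector is taken.
#'
#' @param start_structure,end_structure `structure_model`s or PDB paths for
#'   the start (reference) and end conformations.
#' @param segments optional named list of node-index vectors; defaults to the
#'   start structure's own segment map.
#' @param rc,gamma,overlap_threshold,hotspot_fraction,delta_gamma,align
#'   pipeline parameters (see description).
#' @param outdir output directory for the report bundle.
#' @param seed seed recorded in the run metadata.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(start_structure, end_structure, segments = NULL,
                            rc = 9, gamma = 1, overlap_threshold = 0.35,
                            hotspot_fraction = 0.02, delta_gamma = 0.01,
                            align = TRUE, outdir = tempfile("enmspm-run-"),
                            seed = 1L) {
  if (rc <= 0 || gamma <= 0 || delta_gamma <= 0)
    stop("rc, gamma and delta_gamma must be positive")
  if (overlap_threshold < 0 || overlap_threshold > 1)
    stop("overlap_threshold must be in [0, 1]")
  if (hotspot_fraction <= 0 || hotspot_fraction > 1)
    stop("hotspot_fraction must be in (0, 1]")
  load <- function(x) if (inherits(x, "structure_model")) x else read_structure(x)
  start <- load(start_structure); end <- load(end_structure)
  if (is.null(segments)) segments <- start$segments
  structure(list(start = start, end = end, segments = segments, rc = rc,
                 gamma = gamma, overlap_threshold = overlap_threshold,
                 hotspot_fraction = hotspot_fraction,
                 delta_gamma = delta_gamma, align = align, outdir = outdir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

config_echo <- function(config) {
  list(start = config$start$label, end = config$end$label,
       n_nodes = n_nodes(config$start),
       segments = lapply(config$segments, range),
       rc = config$rc, gamma = config$gamma,
       overlap_threshold = config$overlap_threshold,
       hotspot_fraction = config$hotspot_fraction,
       delta_gamma = config$delta_gamma, align = config$align,
       seed = config$seed)
}

#' Run the full normal-mode / perturbation analysis pipeline
#'
#' Stage sequence: build the elastic network; compute the full mode spectrum
#' (aborting with a component diagnostic if the network is disconnected);
#' take the transition vector between the two conformations; compute the
#' per-mode overlap profile and the dominant-mode set; then, per dominant
#' mode, the covariance map, displacement profile and SPM response with its
#' hot-spot list; plus the displacement sum over all dominant modes (also
#' written as a B-factor-annotated PDB) and segment-block summaries. All
#' artifacts are written under `config$outdir` along with a JSON metadata
#' record echoing the configuration; re-running an identical configuration
#' reproduces the CSV outputs exactly (deterministic eigenvector signs).
#'
#' @param config an `analysis_config`.
#' @return an `analysis_report`: in-memory tables (`overlap`, `dominant`,
#'   `covariances`, `displacements`, `displacement_sum`, `responses`,
#'   `hotspots`, `segment_summaries`, `coupling`), the file manifest
#'   (`files`), and collected `warnings`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)
  stage_times <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(force(expr), warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })
    stage_times[name] <<- proc.time()[["elapsed"]] - t0
    message(sprintf("[enmspm] %-14s %6.2fs", name, stage_times[[name]]))
    res
  }

  net <- stage("network", build_network(config$start, config$rc, config$gamma))
  modes <- stage("modes", compute_modes(build_hessian(net)))
  if (modes$n_zero > 6) {
    comp <- network_components(net)
    if (max(comp) > 1)
      stop("disconnected network at rc = ", config$rc, ": ",
           max(comp), " components with sizes ",
           paste(tabulate(comp), collapse = ", "))
    stop("network at rc = ", config$rc, " is connected but has ",
         modes$n_zero, " zero modes (floppy mechanisms); increase rc")
  }
  tv <- stage("transition",
              transition_vector(config$start, config$end, align = config$align))
  ov <- stage("overlap", overlap(modes, tv, config$overlap_threshold))
  dom <- ov$dominant
  if (length(dom) == 0)
    note(sprintf("no dominant mode: no nonzero mode reaches overlap %.2f",
                 config$overlap_threshold))

  files <- list()
  out <- function(name) file.path(config$outdir, name)
  write_overlap(ov, files$overlap <- out("overlap.csv"))
  dom_table <- data.frame(mode = dom, overlap = ov$profile$overlap[dom])
  utils::write.csv(dom_table, files$dominant <- out("dominant_modes.csv"),
                   row.names = FALSE)

  covs <- list(); disps <- list(); resps <- NULL; hots <- list()
  if (length(dom) > 0) {
    covs <- stage("covariance", lapply(stats::setNames(dom, dom), function(m)
      covariance(modes, m)))
    for (m in names(covs))
      write_covariance(covs[[m]],
                       files[[paste0("covariance_mode", m)]] <-
                         out(sprintf("covariance_mode%s.csv", m)))
    disps <- stage("displacement", lapply(stats::setNames(dom, dom), function(m)
      displacement(modes, m)))
    resps <- stage("spm", spm_response(net, modes, dom, config$delta_gamma))
    hots <- lapply(stats::setNames(dom, dom), function(m)
      select_hotspots(resps, m, config$hotspot_fraction))
    for (m in names(hots))
      write_hotspots(hots[[m]], config$start,
                     files[[paste0("hotspots_mode", m)]] <-
                       out(sprintf("hotspots_mode%s.txt", m)))
    utils::write.csv(as.data.frame(resps$response),
                     files$spm <- out("spm_response.csv"), row.names = FALSE)
  }

  disp_sum <- if (length(dom) > 0) displacement(modes, dom) else NULL
  if (!is.null(disp_sum)) {
    utils::write.csv(data.frame(node = seq_along(disp_sum$values),
                                displacement_sum = disp_sum$values),
                     files$displacement_sum <- out("displacement_sum.csv"),
                     row.names = FALSE)
    write_structure(config$start,
                    files$displacement_pdb <- out("displacement_sum.pdb"),
                    per_node_scalar = disp_sum$values)
  }

  seg_sum <- list()
  if (length(config$segments) > 0 && length(dom) > 0) {
    seg_sum <- c(
      lapply(covs, segment_summary, segments = config$segments),
      list(displacement_sum = segment_summary(disp_sum, config$segments)))
    coupling <- coupling_report(hots, config$segments)
    utils::write.csv(coupling, files$coupling <- out("hotspot_coupling.csv"),
                     row.names = FALSE)
  } else coupling <- NULL

  meta <- list(package = "enmspm",
               version = as.character(utils::packageVersion("enmspm")),
               config = config_echo(config),
               n_contacts = nrow(net$contacts), n_zero_modes = modes$n_zero,
               stage_seconds = as.list(round(stage_times, 3)),
               warnings = c(modes$warnings, warnings))
  jsonlite::write_json(meta, files$metadata <- out("metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(overlap = ov, dominant = dom_table, network = net,
                 modes = modes, covariances = covs, displacements = disps,
                 displacement_sum = disp_sum, responses = resps,
                 hotspots = hots, segment_summaries = seg_sum,
                 coupling = coupling, files = files,
                 warnings = c(modes$warnings, warnings), metadata = meta),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:\n")
  if (nrow(x$dominant) > 0) {
    cat("  dominant modes:\n")
    for (r in seq_len(nrow(x$dominant)))
      cat(sprintf("    mode %d  overlap %.3f\n",
                  x$dominant$mode[r], x$dominant$overlap[r]))
  } else cat("  no dominant modes\n")
  cat(sprintf("  artifacts: %d files in %s\n", length(x$files),
              dirname(x$files[[1]])))
  if (length(x$warnings) > 0)
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Run an analysis and compare dominant modes against reference values
#'
#' Runs [run_analysis()] on prepared start/end structures and emits a
#' side-by-side table of the computed dominant modes against externally
#' reported reference (mode, overlap) pairs, annotating agreement within a
#' tolerance. Mismatches are annotated, never fatal; a node-count mismatch
#' between the two conformations (which makes the transition ill-defined) or
#' against `expected_nodes` aborts before any analysis.
#'
#' @param config an `analysis_config`.
#' @param reference data.frame with columns `mode` and `overlap` holding the
#'   reported dominant modes, in rank order.
#' @param expected_nodes optional required node count for the start structure.
#' @param tolerance allowed absolute deviation in overlap for a row to be
#'   annotated as matching (default 0.15).
#' @return list with the `report` and a `comparison` data.frame
#'   (rank, reference mode/overlap, computed mode/overlap, annotations).
#' @export
run_reference_comparison <- function(config, reference, expected_nodes = NULL,
                                   tolerance = 0.15) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(expected_nodes) && n_nodes(config$start) != expected_nodes)
    stop("node count ", n_nodes(config$start),
         " does not match the expected ", expected_nodes)
  if (n_nodes(config$start) != n_nodes(config$end))
    stop("start and end conformations differ in node count (",
         n_nodes(config$start), " vs ", n_nodes(config$end),
         "); the transition requires matched nodes")
  report <- run_analysis(config)
  k <- max(nrow(reference), nrow(report$dominant))
  pick <- function(v, i) ifelse(i <= length(v), v[i], NA)
  comparison <- data.frame(
    rank = seq_len(k),
    reference_mode = pick(reference$mode, seq_len(k)),
    reference_overlap = pick(reference$overlap, seq_len(k)),
    computed_mode = pick(report$dominant$mode, seq_len(k)),
    computed_overlap = pick(report$dominant$overlap, seq_len(k)))
  comparison$mode_match <- !is.na(comparison$reference_mode) &
    !is.na(comparison$computed_mode) &
    comparison$reference_mode == comparison$computed_mode
  dev <- abs(comparison$computed_overlap - comparison$reference_overlap)
  comparison$overlap_within_tol <- !is.na(dev) & dev <= tolerance
  comparison$note <- ifelse(
    comparison$mode_match & comparison$overlap_within_tol, "match",
    ifelse(is.na(comparison$computed_mode), "not computed",
           ifelse(is.na(comparison$reference_mode), "extra computed mode",
                  "deviates")))
  utils::write.csv(comparison,
                   file.path(config$outdir, "reference_comparison.csv"),
                   row.names = FALSE)
  list(report = report, comparison = comparison)
}
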