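#' Run configuration
#'
#' Assembles (and validates) the single configuration object driving
#' [run_pipeline()]. Configurations can also be read from YAML with
#' [read_run_config()].
#'
#' @param mode `"simulate"` (generate a synthetic cohort and analyze it),
#'   `"analyze"` (analyze subject directories on disk) or
#'   `"reproduce-table"` (summarize a cohort table, by default the packaged
#'   reference table).
#' @param output_dir Directory for outputs (`NULL` = don't write files).
#' @param n_subjects,seed,qc_failure_rate Simulation-mode cohort settings.
#' @param qc_failures Optional exact number of injected quality failures
#'   (simulate mode), overriding the Bernoulli draw at `qc_failure_rate`.
#' @param subject_dirs Character vector of subject directories
#'   (analyze mode).
#' @param table_path Cohort CSV (reproduce-table mode); default the
#'   packaged table.
#' @param fd_threshold,step_threshold QC thresholds (mm, mmHg).
#' @param z_threshold Steal Z-score threshold (atlas SDs).
#' @param delay Hemodynamic delay in seconds for the CVR fit.
#' @param min_cluster_voxels Steal-mask cluster filter (0 = off).
#' @param write_volumes Write per-subject NIfTI outputs (CVR map, Z map,
#'   steal mask) under `output_dir`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "analyze", "reproduce-table"),
                       output_dir = NULL, n_subjects = 21L, seed = 1L,
                       qc_failure_rate = 5 / 26, qc_failures = NULL,
                       subject_dirs = NULL,
                       table_path = NULL, fd_threshold = 2,
                       step_threshold = 6, z_threshold = 2, delay = 0,
                       min_cluster_voxels = 0, write_volumes = FALSE) {
  mode <- match.arg(mode)
  if (mode == "analyze" && length(subject_dirs) == 0)
    stop("analyze mode requires subject_dirs", call. = FALSE)
  stopifnot(fd_threshold > 0, step_threshold > 0, z_threshold > 0)
  structure(list(mode = mode, output_dir = output_dir,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 qc_failure_rate = qc_failure_rate,
                 qc_failures = qc_failures,
                 subject_dirs = subject_dirs, table_path = table_path,
                 fd_threshold = fd_threshold, step_threshold = step_threshold,
                 z_threshold = z_threshold, delay = delay,
                 min_cluster_voxels = min_cluster_voxels,
                 write_volumes = write_volumes),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

analyze_bundle <- function(bundle, config) {
  cvr <- compute_cvr(bundle$bold, bundle$petco2, bundle$protocol,
                     bundle$grid, brain_mask = bundle$brain_mask,
                     delay = config$delay)
  if (is.null(bundle$atlas_ref))
    stop("subject has no healthy-reference atlas", call. = FALSE)
  z <- zscore_map(cvr, bundle$atlas_ref)
  steal <- detect_steal(cvr, z, z_threshold = config$z_threshold)
  if (config$min_cluster_voxels > 0)
    steal <- clean_mask(steal, config$min_cluster_voxels)
  if (is.null(bundle$lesion_mask))
    stop("subject has no lesion mask", call. = FALSE)
  roi <- roi_statistics(cvr, bundle$territories, bundle$lesion_mask, steal,
                        affected_side = bundle$affected_side)
  list(cvr = cvr, zmap = z, steal = steal,
       row = cbind(data.frame(subject_id = bundle$subject_id,
                              stringsAsFactors = FALSE), roi))
}

write_pipeline_volumes <- function(res, bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$grid
  cvr <- res$cvr$values; cvr[is.na(cvr)] <- 0
  z <- res$zmap$values; z[is.na(z)] <- 0
  RNifti::writeNifti(nifti_of(cvr, g), file.path(dir, "cvr.nii"))
  RNifti::writeNifti(nifti_of(z, g), file.path(dir, "zmap.nii"))
  RNifti::writeNifti(nifti_of(res$steal$values, g, "uint8"),
                     file.path(dir, "steal_mask.nii"))
  jsonlite::write_json(c(res$steal$criterion, res$cvr$params),
                       file.path(dir, "criterion.json"), auto_unbox = TRUE)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates one run: obtain subjects (simulated or from disk), apply the
#' quality gates, map CVR, standardize against the healthy atlas, classify
#' steal voxels, partition volumes against the lesion, and summarize the
#' passing cohort. Subjects failing QC are excluded from the cohort
#' statistics and listed with their reasons; a stage error in one subject is
#' recorded and the run continues with the others. With an `output_dir` the
#' run writes `cohort.csv`, `summary.csv`, `summary.txt`, `qc_log.jsonl`
#' and a resolved `config.yaml` snapshot.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @param phantom,protocol Generation settings for simulate mode.
#' @return List with `cohort` (per-subject table of passing subjects),
#'   `summary` (a [cohort_summary()]), `qc` (list of `qc_report`),
#'   `excluded` (data frame of excluded subjects and reasons), `errors`
#'   (named list of per-subject error messages).
#' @export
run_pipeline <- function(config, phantom = phantom_spec(),
                         protocol = co2_protocol()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_event <- function(...) {
    line <- jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA)
    log_lines <<- c(log_lines, line)
  }

  if (config$mode == "reproduce-table") {
    tab <- load_cohort_table(config$table_path %||% steal_table_path())
    summ <- cohort_summary(tab)
    result <- list(cohort = tab, summary = summ, qc = list(),
                   excluded = data.frame(), errors = list())
  } else {
    bundles <- if (config$mode == "simulate") {
      spec <- cohort_spec(n_subjects = config$n_subjects,
                          qc_failure_rate = config$qc_failure_rate,
                          qc_failures = config$qc_failures,
                          seed = config$seed)
      synthesize_cohort(spec, images = TRUE, phantom = phantom,
                        protocol = protocol)$bundles
    } else {
      lapply(config$subject_dirs, function(d) d)  # paths; loaded lazily
    }
    rows <- list()
    qcs <- list()
    excluded <- list()
    errors <- list()
    for (i in seq_along(bundles)) {
      b <- bundles[[i]]
      id <- if (is.character(b)) basename(b) else b$subject_id
      res <- tryCatch({
        if (is.character(b)) b <- load_subject(b)
        qc <- qc_subject(b, fd_threshold = config$fd_threshold,
                         step_threshold = config$step_threshold)
        qcs[[length(qcs) + 1L]] <- qc
        log_event(stage = "qc", subject_id = b$subject_id,
                  passed = qc$passed, mean_fd = qc$mean_fd,
                  co2_step = qc$co2_step, reasons = qc$reasons)
        if (!qc$passed) {
          excluded[[length(excluded) + 1L]] <-
            data.frame(subject_id = b$subject_id,
                       reasons = paste(qc$reasons, collapse = ";"))
          NULL
        } else {
          r <- analyze_bundle(b, config)
          log_event(stage = "analysis", subject_id = b$subject_id,
                    steal_ml = r$row$steal_aca_mca_ml,
                    lesion_ml = r$row$lesion_ml)
          if (isTRUE(config$write_volumes) && !is.null(out_dir))
            write_pipeline_volumes(r, b, file.path(out_dir, b$subject_id))
          clin <- b$clinical
          if (!is.null(clin))
            r$row <- cbind(r$row, clin[setdiff(names(clin),
                                               names(r$row))])
          r$row
        }
      }, error = function(e) {
        errors[[id]] <<- conditionMessage(e)
        log_event(stage = "error", subject_id = id,
                  message = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    cohort <- if (length(rows)) do.call(rbind, rows) else data.frame()
    summ <- if (nrow(cohort) >= 3) cohort_summary(cohort) else NULL
    result <- list(cohort = cohort, summary = summ, qc = qcs,
                   excluded = if (length(excluded)) do.call(rbind, excluded)
                              else data.frame(),
                   errors = errors)
  }

  if (!is.null(out_dir)) {
    if (nrow(result$cohort))
      utils::write.csv(result$cohort, file.path(out_dir, "cohort.csv"),
                       row.names = FALSE)
    if (!is.null(result$summary)) {
      utils::write.csv(as.data.frame(result$summary),
                       file.path(out_dir, "summary.csv"), row.names = FALSE)
      utils::capture.output(print(result$summary),
                            file = file.path(out_dir, "summary.txt"))
    }
    writeLines(log_lines, file.path(out_dir, "qc_log.jsonl"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  result
}
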