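# On-disk formats: NIfTI volumes with JSON sidecars for acquisition
# metadata, CSV for cell and ROI tables, JSON + Markdown for reports.

#' Write an MR series as NIfTI with a JSON sidecar
#'
#' The 4th dimension indexes b-value or echo; b-values (s/mm^2) or echo
#' times (seconds) go to `<path>.json`.
#'
#' @param series An `mri_series`.
#' @param path Output path without extension; `.nii.gz` and `.json` are
#'   appended.
#' @return The NIfTI path, invisibly.
#' @export
write_mri_series <- function(series, path) {
  stopifnot(inherits(series, "mri_series"))
  im <- RNifti::asNifti(series$data)
  RNifti::pixdim(im) <- c(series$voxel_mm, 1)
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(im, nii)
  side <- list(type = series$type, sigma = series$sigma,
               slices = series$slices)
  if (series$type == "dwi") side$bvalues <- series$bvalues
  else side$echo_times_s <- series$echo_times_s
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(nii)
}

#' Read an MR series written by [write_mri_series()]
#' @param path Path without extension.
#' @return An `mri_series`.
#' @export
read_mri_series <- function(path) {
  im <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  idx <- if (side$type == "dwi") side$bvalues else side$echo_times_s
  nm <- if (side$type == "dwi") "bvalues" else "echo_times_s"
  .series(array(as.vector(im), dim(im)), idx, nm,
          RNifti::pixdim(im)[1:3], side$slices, side$sigma, side$type)
}

#' Write a label volume as NIfTI with a JSON sidecar
#' @param labels A `tissue_labels`.
#' @param path Output path without extension.
#' @return The NIfTI path, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "tissue_labels"))
  im <- RNifti::asNifti(labels$labels)
  RNifti::pixdim(im) <- labels$voxel_mm
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(im, nii, datatype = "int16")
  jsonlite::write_json(
    list(codes = as.list(labels$codes),
         tumor_center_mm = labels$tumor_center_mm,
         tumor_radius_mm = labels$tumor_radius_mm, meta = labels$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(nii)
}

#' Read a label volume written by [write_labels()]
#' @param path Path without extension.
#' @return A `tissue_labels`.
#' @export
read_labels <- function(path) {
  im <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(labels = array(as.integer(im), dim(im)),
                 voxel_mm = RNifti::pixdim(im)[1:3],
                 codes = unlist(side$codes),
                 tumor_center_mm = side$tumor_center_mm,
                 tumor_radius_mm = side$tumor_radius_mm,
                 meta = side$meta),
            class = "tissue_labels")
}

#' Write / read a cell table as CSV
#'
#' Header columns: `x_mm`, `y_mm`, `slice`, `intensity`.
#' @param cells A `cell_table`.
#' @param path CSV file path.
#' @return The path (write) or a `cell_table` (read).
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells)[, c("x_mm", "y_mm", "slice",
                                            "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  tab <- utils::read.csv(path)
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Write a report to disk
#'
#' Emits `report.json`, Markdown tables in `report.md`, and the
#' correlation scatter data (tumor-ROI imaging values paired with HIF
#' scores) as `scatter.csv`.
#'
#' @param report An `hif_report`.
#' @param dir Output directory (created if needed).
#' @param roi_table Optional pooled ROI table for the scatter export.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, roi_table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(comparisons = report$comparisons,
         correlations = report$correlations, counts = report$counts,
         alpha = report$alpha, notes = report$notes),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  writeLines(report_to_markdown(report), file.path(dir, "report.md"))
  if (!is.null(roi_table)) {
    tum <- roi_table[roi_table$analyzed %in% TRUE &
                       roi_table$tissue == "tumor",
                     c("roi_id", "D", "Dstar", "f", "perfusion", "R2star",
                       "hif_score")]
    utils::write.csv(tum, file.path(dir, "scatter.csv"), row.names = FALSE)
  }
  invisible(dir)
}

.config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Load a pipeline run configuration
#'
#' Reads a YAML (or JSON) document with optional sections `phantom`
#' (arguments of [phantom_config()]), `analysis` (arguments of
#' [analysis_config()]) and top-level `n_animals` / `seed`.
#'
#' @param path YAML or JSON file.
#' @return A list with `phantom`, `analysis`, `n_animals`, `seed`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ph_args <- raw$phantom %||% list()
  if (!is.null(ph_args$fractions)) ph_args$fractions <- unlist(ph_args$fractions)
  if (!is.null(ph_args$coupling)) ph_args$coupling <- unlist(ph_args$coupling)
  an_args <- raw$analysis %||% list()
  list(phantom = do.call(phantom_config, ph_args),
       analysis = do.call(analysis_config, an_args),
       n_animals = raw$n_animals %||% 8,
       seed = raw$seed %||% 1L)
}

#' Run the full pipeline with on-disk artifacts
#'
#' Orchestrates simulate -> fit -> grid -> score -> stats for a
#' multi-animal synthetic study, writing every intermediate in its
#' declared format under `out_dir` (per-animal labels, MR series, cell
#' table and ROI table; pooled ROI table; report; run manifest). With
#' `resume = TRUE`, animals whose ROI tables already exist are loaded
#' instead of recomputed, so only missing stages re-execute.
#'
#' @param config A configuration file path (YAML/JSON), a list as
#'   returned by [load_run_config()], or `NULL` for defaults.
#' @param out_dir Output directory.
#' @param seed Master seed (overrides the config seed).
#' @param n_animals Optional override of the animal count.
#' @param resume Skip animals with existing outputs.
#' @return The `hif_study`, invisibly; artifacts and `manifest.json` on
#'   disk.
#' @export
run_pipeline <- function(config = NULL, out_dir = "hifmri_run",
                         seed = NULL, n_animals = NULL, resume = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config))
    config <- list(phantom = phantom_config(), analysis = analysis_config(),
                   n_animals = 8, seed = 1L)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(n_animals)) config$n_animals <- n_animals
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- list(); warns <- character(0)
  tabs <- vector("list", config$n_animals)
  for (i in seq_len(config$n_animals)) {
    adir <- file.path(out_dir, sprintf("animal_%02d", i))
    roi_csv <- file.path(adir, "roi.csv")
    t0 <- Sys.time()
    if (resume && file.exists(roi_csv)) {
      tabs[[i]] <- utils::read.csv(roi_csv)
    } else {
      dir.create(adir, showWarnings = FALSE, recursive = TRUE)
      cfg_i <- config$phantom
      cfg_i$seed <- stage_seed(config$seed, "animal", i)
      ph <- withCallingHandlers(
        simulate_phantom(cfg_i),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      write_labels(ph$labels, file.path(adir, "labels"))
      write_mri_series(ph$dwi, file.path(adir, "dwi"))
      write_mri_series(ph$mege, file.path(adir, "mege"))
      write_cell_table(ph$cells, file.path(adir, "cells.csv"))
      an <- analyze_phantom(ph, config$analysis)
      an$roi$animal <- i
      utils::write.csv(an$roi, roi_csv, row.names = FALSE)
      tabs[[i]] <- an$roi
    }
    timings[[sprintf("animal_%02d", i)]] <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  roi_table <- do.call(rbind, tabs)
  utils::write.csv(roi_table, file.path(out_dir, "roi_pooled.csv"),
                   row.names = FALSE)
  report <- build_report(roi_table)
  write_report(report, file.path(out_dir, "report"), roi_table)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hifmri")),
    seed = config$seed,
    n_animals = config$n_animals,
    config_hash = .config_hash(list(phantom = unclass(config$phantom),
                                    analysis = unclass(config$analysis),
                                    n_animals = config$n_animals,
                                    seed = config$seed)),
    stage_seconds = timings,
    warnings = warns,
    outputs = list(roi_pooled = "roi_pooled.csv", report = "report/")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(list(roi_table = roi_table, report = report,
                           accounting = NULL, seed = config$seed,
                           n_animals = config$n_animals),
                      class = "hif_study"))
}
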