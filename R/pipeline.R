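#' Run configuration for the quantification pipeline
#'
#' One configuration drives a whole longitudinal study: voxel spacing,
#' study-wide threshold policy, the VOI slice window, plate-analysis geometry
#' and the statistical policy. Serialises losslessly to YAML.
#'
#' @param spacing_um voxel spacing in micrometres (default 8.7).
#' @param threshold fixed study-wide grey threshold, or `NULL` to derive one
#'   with [suggest_threshold()] on the first (calibration) volume and reuse
#'   it for the whole batch.
#' @param voi_start 0-based first slice of the VOI window.
#' @param voi_slices VOI window height in slices (default 52).
#' @param plate_width_mm,plate_length_mm in-plane plate analysis rectangle.
#' @param gap_bridge_um plate gap-bridging length (default 52.2).
#' @param alpha type-I error level (default 0.05).
#' @param holm_family Holm family policy label (default
#'   `"per-parameter-compartment"`).
#' @param gate ANOVA gate for paired tests (`"any"`, `"interaction"`,
#'   `"none"`).
#' @param seed integer seed for all randomness.
#' @param out_dir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spacing_um = 8.7, threshold = NULL, voi_start = 0L,
                       voi_slices = 52L, plate_width_mm = 1.5,
                       plate_length_mm = 2.5, gap_bridge_um = 52.2,
                       alpha = 0.05, holm_family = "per-parameter-compartment",
                       gate = "any", seed = 1L, out_dir = ".") {
  check_spacing(spacing_um)
  if (voi_slices < 1L) stop("voi_slices must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!gate %in% c("any", "interaction", "none")) stop("invalid gate")
  structure(list(spacing_um = spacing_um, threshold = threshold,
                 voi_start = as.integer(voi_start),
                 voi_slices = as.integer(voi_slices),
                 plate_width_mm = plate_width_mm,
                 plate_length_mm = plate_length_mm,
                 gap_bridge_um = gap_bridge_um, alpha = alpha,
                 holm_family = holm_family, gate = gate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s\n", nm,
                if (is.null(x[[nm]])) "(auto)" else format(x[[nm]])))
  invisible(x)
}

#' Read/write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Quantify a batch of volumes
#'
#' For each manifest entry: read the volume, segment it at the study-wide
#' threshold (fixed in the config, or suggested once on the first volume and
#' reused), rasterise its ROI stack, restrict to the VOI slice window,
#' compute trabecular morphometry per compartment and plate metrics on
#' posterior-anchored analysis rectangles. Per-volume failures are flagged
#' and the batch continues. Results are written as one JSON per volume plus
#' a combined CSV, with a structured log line per volume.
#'
#' @param config a [run_config()].
#' @param manifest data.frame with columns `id`, `volume` (TIFF path or
#'   directory) and `roi` (ROI JSON path).
#' @return List of class `quantify_run`: `results` (combined data.frame),
#'   `failures` (per-volume error messages), `threshold` (study-wide value
#'   used), `log` (character vector).
#' @export
run_quantify <- function(config, manifest) {
  stopifnot(inherits(config, "run_config"))
  req <- c("id", "volume", "roi")
  if (!is.data.frame(manifest) || !all(req %in% names(manifest)))
    stop("manifest needs columns id, volume, roi")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  threshold <- config$threshold
  results <- list(); failures <- list(); log <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$id[i]
    res <- tryCatch({
      gray <- read_volume(manifest$volume[i], config$spacing_um)
      # calibration volume: first successful read fixes the study threshold
      if (is.null(threshold)) threshold <- suggest_threshold(gray)
      mask <- apply_threshold(gray, threshold)
      rois <- read_roi_json(manifest$roi[i])
      vois <- rasterize_voi(rois, dim(gray$voxels), config$spacing_um)
      vois$medial <- voi_window(vois$medial, config$voi_start,
                                config$voi_slices)
      vois$lateral <- voi_window(vois$lateral, config$voi_start,
                                 config$voi_slices)
      morph <- compute_morphometry(mask, vois)
      regions <- list(
        medial = compartment_plate_region(vois$medial, config),
        lateral = compartment_plate_region(vois$lateral, config))
      plate <- compute_plate_metrics(mask, regions, config$gap_bridge_um)
      out <- merge(as.data.frame(morph), plate, by = "compartment",
                   sort = TRUE)
      out <- cbind(id = id, out)
      jsonlite::write_json(out, file.path(config$out_dir,
                                          paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      out
    }, error = function(e) structure(conditionMessage(e), class = "try-error"))
    if (inherits(res, "try-error")) {
      failures[[as.character(id)]] <- as.character(res)
      log <- c(log, sprintf("volume=%s status=failed error=%s", id,
                            as.character(res)))
    } else {
      results[[length(results) + 1L]] <- res
      log <- c(log, sprintf(
        "volume=%s status=ok threshold=%s voi_start=%d voi_slices=%d gap_bridge=%g",
        id, format(threshold), config$voi_start, config$voi_slices,
        config$gap_bridge_um))
    }
  }
  combined <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(combined))
    utils::write.csv(combined, file.path(config$out_dir, "morphometry.csv"),
                     row.names = FALSE)
  writeLines(log, file.path(config$out_dir, "quantify.log"))
  structure(list(results = combined, failures = failures,
                 threshold = threshold, log = log),
            class = "quantify_run")
}

# posterior-anchored plate rectangle from a compartment VOI's in-plane bbox
compartment_plate_region <- function(voi, config) {
  inplane <- apply(voi$voxels, c(1, 2), any)
  if (!any(inplane)) stop("compartment VOI is empty in-plane")
  xs <- range(which(apply(inplane, 1, any)))
  ys <- range(which(apply(inplane, 2, any)))
  shape <- dim(voi$voxels)
  wx <- min(round(config$plate_width_mm * 1000 / voi$spacing_um),
            xs[2] - xs[1] + 1L)
  ly <- min(round(config$plate_length_mm * 1000 / voi$spacing_um),
            ys[2] - ys[1] + 1L)
  list(x_range = c(xs[1], xs[1] + wx - 1L),
       y_range = c(ys[2] - ly + 1L, ys[2]))
}

#' @export
print.quantify_run <- function(x, ...) {
  n_ok <- if (is.null(x$results)) 0L else length(unique(x$results$id))
  cat(sprintf("<quantify_run> %d volumes quantified, %d failed, threshold %s\n",
              n_ok, length(x$failures), format(x$threshold)))
  invisible(x)
}

#' Run a full simulated or quantified study
#'
#' Assembles the longitudinal dataset (simulating one from the published
#' 12-animal design when none is given), runs the inferential recipe and
#' writes the summary tables and ANOVA report to the output directory.
#'
#' @param config a [run_config()].
#' @param dataset optional `longitudinal_dataset`; when `NULL` a cohort is
#'   simulated from [mia_table_design()] under the config seed.
#' @return List of class `study_run`: `tables` ([build_tables()] output) and
#'   `dataset`.
#' @export
run_study <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    design <- cohort_design(mia_table_design(), n_animals = 12L,
                            correlation = 0.7, seed = config$seed)
    dataset <- simulate_cohort(design)
  }
  n <- length(unique(dataset$animal))
  if (n < 2L)
    stop("inference refused: the dataset has ", n,
         " animal(s); paired inference needs at least 2")
  incomplete <- find_incomplete_animals(dataset)
  if (length(incomplete))
    stop("incomplete pairing for animal(s): ",
         paste(incomplete, collapse = ", "))
  tables <- build_tables(dataset, alpha = config$alpha, gate = config$gate)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tables$comparisons,
                   file.path(config$out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$comparisons_rounded,
                   file.path(config$out_dir, "comparisons_rounded.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$anova, file.path(config$out_dir, "anova.csv"),
                   row.names = FALSE)
  write_cohort_csv(dataset, file.path(config$out_dir, "cohort.csv"))
  structure(list(tables = tables, dataset = dataset), class = "study_run")
}

find_incomplete_animals <- function(dataset) {
  bad <- character(0)
  for (key in split(as.data.frame(dataset),
                    dataset[, c("parameter", "compartment")], drop = TRUE)) {
    counts <- table(key$animal, key$limb, key$week)
    full <- apply(counts == 1L, 1, all)
    bad <- union(bad, rownames(counts)[!full])
  }
  bad
}

#' @export
print.study_run <- function(x, ...) {
  cat("<study_run>\n")
  print(x$tables)
  invisible(x)
}
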