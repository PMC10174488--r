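DR_COLS <- c("cell_line", "drug", "dose_uM", "replicate_id", "relative_count")
GRID_COLS <- c("cell_line", "drug_a", "dose_a_uM", "drug_b", "dose_b_uM",
               "replicate_id", "relative_count")

# Accepts an optional dose_unit column ("nM" or "uM") and converts to uM.
apply_dose_units <- function(tab, dose_cols) {
  if (!"dose_unit" %in% names(tab)) return(tab)
  u <- tolower(tab$dose_unit)
  bad <- !u %in% c("nm", "um")
  if (any(bad))
    stop("unknown dose_unit in row(s) ", paste(which(bad), collapse = ", "),
         " (expected nM or uM)", call. = FALSE)
  f <- ifelse(u == "nm", 1e-3, 1)
  for (cc in dose_cols) tab[[cc]] <- tab[[cc]] * f
  tab$dose_unit <- NULL
  tab
}

check_numeric_col <- function(tab, col) {
  v <- suppressWarnings(as.numeric(tab[[col]]))
  bad <- which(is.na(v) & !is.na(tab[[col]]) | is.na(tab[[col]]))
  if (length(bad))
    stop("malformed value in column '", col, "' at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  v
}

#' Read a long-form plate CSV
#'
#' Single-drug tables need columns `cell_line, drug, dose_uM,
#' replicate_id, relative_count`; combination tables need `cell_line,
#' drug_a, dose_a_uM, drug_b, dose_b_uM, replicate_id, relative_count`.
#' An optional `dose_unit` column (`nM`/`uM`) converts doses to uM.
#' Replicates are aggregated to per-dose mean, sd and standard error.
#'
#' @param path CSV file path.
#' @return A [dose_response_data()] or [dose_grid()] depending on the
#'   columns present.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(GRID_COLS %in% names(tab))) {
    for (cc in c("dose_a_uM", "dose_b_uM", "relative_count"))
      tab[[cc]] <- check_numeric_col(tab, cc)
    tab <- apply_dose_units(tab, c("dose_a_uM", "dose_b_uM"))
    if (any(tab$relative_count < 0))
      stop("negative relative counts in ", path, call. = FALSE)
    key <- paste(tab$dose_a_uM, tab$dose_b_uM, tab$replicate_id)
    if (anyDuplicated(key))
      stop("duplicate well at data row(s) ",
           paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
    doses_a <- sort(unique(tab$dose_a_uM))
    doses_b <- sort(unique(tab$dose_b_uM))
    reps <- unique(tab$replicate_id)
    arr <- array(NA_real_, c(length(doses_a), length(doses_b), length(reps)))
    for (k in seq_len(nrow(tab))) {
      i <- match(tab$dose_a_uM[k], doses_a)
      j <- match(tab$dose_b_uM[k], doses_b)
      r <- match(tab$replicate_id[k], reps)
      arr[i, j, r] <- tab$relative_count[k]
    }
    vals <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    se <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE) /
      sqrt(apply(!is.na(arr), c(1, 2), sum))
    return(dose_grid(tab$drug_a[1], tab$drug_b[1], doses_a, doses_b, vals,
                     se = se, cell_line = tab$cell_line[1]))
  }
  if (all(DR_COLS %in% names(tab))) {
    for (cc in c("dose_uM", "relative_count"))
      tab[[cc]] <- check_numeric_col(tab, cc)
    tab <- apply_dose_units(tab, "dose_uM")
    if (any(tab$relative_count < 0))
      stop("negative relative counts in ", path, call. = FALSE)
    key <- paste(tab$dose_uM, tab$replicate_id)
    if (anyDuplicated(key))
      stop("duplicate well at data row(s) ",
           paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
    agg <- stats::aggregate(tab$relative_count, list(dose = tab$dose_uM),
                            function(v) c(mean = mean(v), sd = stats::sd(v),
                                          n = length(v)))
    return(dose_response_data(
      drug = tab$drug[1], cell_line = tab$cell_line[1],
      doses = agg$dose, mean_counts = agg$x[, "mean"], sd = agg$x[, "sd"],
      se = agg$x[, "sd"] / sqrt(agg$x[, "n"]),
      replicates = data.frame(dose_uM = tab$dose_uM,
                              replicate_id = tab$replicate_id,
                              relative_count = tab$relative_count)))
  }
  stop("unrecognised plate CSV schema in ", path, ": need columns ",
       paste(DR_COLS, collapse = ", "), " or ",
       paste(GRID_COLS, collapse = ", "), call. = FALSE)
}

#' Write dose-response replicates to long-form CSV
#'
#' @param data a [dose_response_data()] with replicate-level values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(data, path) {
  stopifnot(inherits(data, "dose_response_data"))
  reps <- data$replicates
  if (is.null(reps))
    reps <- data.frame(dose_uM = data$doses, replicate_id = "mean",
                       relative_count = data$mean_counts)
  out <- data.frame(cell_line = data$cell_line, drug = data$drug,
                    dose_uM = reps$dose_uM, replicate_id = reps$replicate_id,
                    relative_count = reps$relative_count)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a dose grid to long-form CSV (plus optional matrix export)
#'
#' @param grid a [dose_grid()].
#' @param path output path for the long form.
#' @param matrix_path optional path for a human-readable 8x8 matrix CSV.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, matrix_path = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  out <- data.frame(cell_line = grid$cell_line %||% NA,
                    drug_a = grid$drug_a,
                    dose_a_uM = rep(grid$doses_a, times = length(grid$doses_b)),
                    drug_b = grid$drug_b,
                    dose_b_uM = rep(grid$doses_b, each = length(grid$doses_a)),
                    replicate_id = "mean",
                    relative_count = as.vector(grid$values))
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(matrix_path))
    utils::write.csv(as.data.frame(grid$values), matrix_path)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML with keys `cell_line`, `seed`, and optional `noise_cv`,
#' `detect_p`, `fit_starts`, `include_death`, `out_dir`, plus optional
#' `constraints: {doubling_time_h, ratios}` overriding the built-ins.
#'
#' @param path YAML file path.
#' @return A validated config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cell_line) || is.null(cfg$seed))
    stop("config must set cell_line and seed", call. = FALSE)
  cfg
}

#' Run the full modelling pipeline on a synthetic study
#'
#' Orchestrates every stage in order on an [end_to_end_fixture()]:
#' growth calibration, single-drug fitting (with and without death terms,
#' compared by pooled AIC), combination-surface prediction with no
#' refitting, predicted-vs-measured comparison, and excess-over-Bliss
#' scoring of both predicted and measured grids. All seeds derive from
#' `config$seed`; reruns with the same config reproduce the report.
#'
#' @param config list with `cell_line`, `seed`, and optional `noise_cv`,
#'   `detect_p`, `fit_starts` (default 20), `out_dir` (write CSV/JSON
#'   artefacts there when set).
#' @return A report list: `calibration`, `fits` (per drug, death model),
#'   `fits_nodeath`, `aic_comparison`, `fitted_model`, `grids` (per pair:
#'   predicted, measured, `pearson_r`), `eob` (per pair: predicted and
#'   measured summaries), `truth`, `seeds`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$cell_line), !is.null(config$seed))
  fit_starts <- config$fit_starts %||% 20L
  fx <- end_to_end_fixture(config$seed, config$cell_line,
                           noise_cv = config$noise_cv %||% 0.1,
                           detect_p = config$detect_p %||% 0.95)
  base <- fx$calibration$params
  drugs <- names(fx$truth$drugs)

  fits <- list(); fits0 <- list()
  for (d in drugs) {
    dr <- plate_to_dose_response(fx$single_plates[[d]])
    ts <- fx$truth$drugs[[d]]$target_state
    fits[[d]] <- fit_drug_params(dr, base, ts, include_death = TRUE,
                                 n_starts = fit_starts,
                                 seed = derive_seed(config$seed, 31L + ts))
    fits0[[d]] <- fit_drug_params(dr, base, ts, include_death = FALSE,
                                  n_starts = fit_starts,
                                  seed = derive_seed(config$seed, 41L + ts))
  }
  aic_cmp <- compare_aic(fits, fits0)
  fitted_model <- cell_line_model(config$cell_line, base,
                                  lapply(fits, `[[`, "params"))

  grids <- list(); eob <- list()
  for (pair in names(fx$combo_plates)) {
    measured <- plate_to_dose_grid(fx$combo_plates[[pair]])
    predicted <- predict_grid(fitted_model, measured$drug_a, measured$drug_b,
                              measured$doses_a, measured$doses_b)
    cmp <- compare_grids(predicted, measured)
    grids[[pair]] <- list(predicted = predicted, measured = measured,
                          pearson_r = cmp$pearson_r)
    eob[[pair]] <- list(
      predicted = eob_from_grid(predicted, seed = derive_seed(config$seed, 51L)),
      measured = eob_from_grid(measured, seed = derive_seed(config$seed, 52L)))
  }

  report <- list(cell_line = config$cell_line,
                 calibration = fx$calibration,
                 fits = fits, fits_nodeath = fits0,
                 aic_comparison = aic_cmp,
                 fitted_model = fitted_model,
                 grids = grids, eob = eob, truth = fx$truth,
                 seeds = list(master = config$seed))
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Serialise a pipeline report to disk
#'
#' Writes a machine-readable JSON summary (`report.json`) plus per-pair
#' long-form grid CSVs under `out_dir`.
#'
#' @param report a [run_pipeline()] report.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(
    schema_version = "1.0",
    cell_line = report$cell_line,
    transition_params = unclass(report$calibration$params),
    calibration_sse = report$calibration$sse,
    drug_params = lapply(report$fits, function(f) unclass(f$params)),
    delta_aic = report$aic_comparison$delta_aic,
    combination_r = lapply(report$grids, `[[`, "pearson_r"),
    eob = lapply(report$eob, function(e)
      list(predicted_mean = e$predicted$mean_eob,
           predicted_se = e$predicted$se_eob,
           measured_mean = e$measured$mean_eob,
           measured_se = e$measured$se_eob)),
    seeds = report$seeds)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (pair in names(report$grids)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", pair)
    write_grid_csv(report$grids[[pair]]$predicted,
                   file.path(out_dir, paste0("predicted_", safe, ".csv")))
    write_grid_csv(report$grids[[pair]]$measured,
                   file.path(out_dir, paste0("measured_", safe, ".csv")))
  }
  invisible(out_dir)
}
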