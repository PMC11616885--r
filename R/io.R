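# File formats: long-format measurements CSV, FOH reports CSV, feature
# matrix CSV (missing values as empty fields), ground-truth CSVs, and a
# YAML run configuration.  All interchange is plain CSV so fixtures stay
# reviewable; timestamps are ISO-8601 without timezone (single-site
# semantics), dates are calendar dates.

.minute_to_hms <- function(minute) {
  sprintf("%02d:%02d:00", minute %/% 60L, minute %% 60L)
}

#' Write measurements to CSV
#'
#' Columns `patient_id`, `timestamp` (ISO-8601 `YYYY-MM-DDTHH:MM:SS`),
#' `channel`, `value`.
#'
#' @param measurements Measurement data frame (`patient_id`, `date`,
#'   `minute`, `channel`, `value`).
#' @param path Output file.
#' @export
write_measurements <- function(measurements, path) {
  out <- data.frame(
    patient_id = measurements$patient_id,
    timestamp = paste0(format(as.Date(measurements$date), "%Y-%m-%d"), "T",
                       .minute_to_hms(measurements$minute)),
    channel = measurements$channel,
    value = measurements$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read measurements from CSV
#'
#' Expects a header `patient_id, timestamp, channel, value`; timestamps are
#' parsed as ISO-8601.  Rows whose timestamp or value cannot be parsed are
#' rejected; their line numbers are attached as attribute `"rejected"` (and
#' reported via a warning).  Unknown channels are preserved.
#'
#' @param path CSV file.
#' @return Measurement data frame (`patient_id`, `date`, `minute`,
#'   `channel`, `value`).
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  .assert(all(c("patient_id", "timestamp", "channel", "value") %in% names(raw)),
          "measurements CSV must have patient_id, timestamp, channel, value")
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- is.na(ts) | is.na(val)
  if (any(bad))
    warning(sum(bad), " malformed row(s) rejected at line(s): ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
  ok <- !bad
  lt <- as.POSIXlt(ts[ok])
  out <- data.frame(patient_id = raw$patient_id[ok],
                    date = as.Date(ts[ok], tz = "UTC"),
                    minute = lt$hour * 60L + lt$min,
                    channel = raw$channel[ok],
                    value = val[ok], stringsAsFactors = FALSE)
  attr(out, "rejected") <- which(bad) + 1L   # +1 for the header line
  out
}

#' Write FOH reports to CSV
#'
#' Columns `patient_id`, `date`, `raw_value` (1-5), `dialect`, plus any
#' derived columns present (e.g. `canonical`, `transformed`).
#'
#' @param reports Reports data frame.
#' @param path Output file.
#' @export
write_reports <- function(reports, path) {
  reports$date <- format(as.Date(reports$date), "%Y-%m-%d")
  utils::write.csv(reports, path, row.names = FALSE, quote = FALSE)
}

#' Read FOH reports from CSV
#'
#' @param path CSV file with `patient_id`, `date`, `raw_value`, `dialect`.
#' @return Reports data frame with `date` parsed as `Date`.
#' @export
read_reports <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("patient_id", "date", "raw_value", "dialect") %in% names(out)),
          "reports CSV must have patient_id, date, raw_value, dialect")
  out$date <- as.Date(out$date)
  .assert(all(out$raw_value %in% 1:5), "raw_value must be in 1..5")
  out
}

#' Write a feature matrix to CSV
#'
#' Missing values are written as empty fields.
#'
#' @param matrix Feature matrix.
#' @param path Output file.
#' @export
write_feature_matrix <- function(matrix, path) {
  matrix$date <- format(as.Date(matrix$date), "%Y-%m-%d")
  utils::write.csv(matrix, path, row.names = FALSE, na = "")
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [write_feature_matrix()].
#' @return Feature matrix with `date` parsed and empty fields as `NA`.
#' @export
read_feature_matrix <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "")
  out$date <- as.Date(out$date)
  out
}

#' Write the generator's ground truth as a CSV set
#'
#' Writes `latent.csv`, `baselines.csv` and `masked_values.csv` into a
#' directory; used so recovery experiments can run from files.
#'
#' @param truth The `truth` element of a `foh_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lat <- truth$latent
  lat$date <- format(as.Date(lat$date), "%Y-%m-%d")
  utils::write.csv(lat, file.path(dir, "latent.csv"), row.names = FALSE)
  if (!is.null(truth$baselines))
    utils::write.csv(truth$baselines, file.path(dir, "baselines.csv"),
                     row.names = FALSE)
  if (!is.null(truth$masked_values))
    write_measurements(truth$masked_values,
                       file.path(dir, "masked_values.csv"))
  invisible(dir)
}

#' Read a run configuration from YAML
#'
#' Validates the fields a run needs (dialect, class count, scheme list,
#' imputation plan, seed, optional embedded generator settings) and returns
#' a list with a ready [sim_config()] and [imputation_plan()].
#'
#' @param path YAML file.
#' @return List with `sim`, `plan`, `schemes`, `n_classes`,
#'   `transform_labels`, `prevday`, `threshold`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .assert(is.list(cfg), "config must be a YAML mapping")
  bad <- setdiff(names(cfg), c("dialect", "n_classes", "schemes",
                               "transform_labels", "prevday", "threshold",
                               "imputation", "seed", "synthetic"))
  .assert(length(bad) == 0,
          paste("unknown config field(s):", paste(bad, collapse = ", ")))
  dialect <- cfg$dialect %||% "heartman"
  .assert(dialect %in% c("heartman", "chiron"),
          "config field 'dialect' must be heartman or chiron")
  n_classes <- cfg$n_classes %||% 3
  .assert(n_classes %in% c(2, 3), "config field 'n_classes' must be 2 or 3")
  schemes <- cfg$schemes %||% "kfold10"
  .assert(all(schemes %in% c("kfold10", "loso", "leave_half")),
          "config field 'schemes' has an unknown scheme")
  imp <- cfg$imputation %||% list()
  plan <- imputation_plan(method = imp$method %||% "knn",
                          scope = imp$scope %||% "global",
                          k_neighbors = imp$k_neighbors %||% 5,
                          max_iter = imp$max_iter %||% 10)
  seed <- as.integer(cfg$seed %||% 1L)
  syn <- cfg$synthetic %||% list()
  sim_args <- c(syn, list(dialect = dialect, seed = seed))
  sim <- do.call(sim_config, sim_args[!duplicated(names(sim_args))])
  list(sim = sim, plan = plan, schemes = schemes, n_classes = n_classes,
       transform_labels = isTRUE(cfg$transform_labels),
       prevday = isTRUE(cfg$prevday),
       threshold = cfg$threshold %||% NULL, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
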