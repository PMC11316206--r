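#' Write a parcel time series to disk
#'
#' Stores the epoch array as an RDS container `<subject_id>.rds` plus a
#' JSON sidecar `<subject_id>.json` carrying `subject_id`, `fs`,
#' `band = "broadband"`, `region_labels` and `epoch_seconds`, so readers
#' can validate metadata before touching the array.
#'
#' @param pts a [parcel_ts].
#' @param dir output directory (created if needed).
#' @return Invisibly, the path of the array file.
#' @export
write_parcel_ts <- function(pts, dir) {
  stopifnot(inherits(pts, "parcel_ts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr_path <- file.path(dir, paste0(pts$subject_id, ".rds"))
  saveRDS(pts$epochs, arr_path)
  sidecar <- list(subject_id = pts$subject_id, fs = pts$fs,
                  band = "broadband", region_labels = pts$region_labels,
                  epoch_seconds = dim(pts$epochs)[3] / pts$fs)
  jsonlite::write_json(sidecar, file.path(dir, paste0(pts$subject_id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(arr_path)
}

#' Read a parcel time series written by [write_parcel_ts()]
#'
#' The JSON sidecar is read first and its region label order validated
#' against the shipped atlas before the array is accepted.
#'
#' @param dir directory containing the pair of files.
#' @param subject_id subject identifier.
#' @return A [parcel_ts].
#' @export
read_parcel_ts <- function(dir, subject_id) {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(subject_id, ".json")),
                                 simplifyVector = TRUE)
  check_region_labels(sidecar$region_labels)
  arr <- readRDS(file.path(dir, paste0(subject_id, ".rds")))
  parcel_ts(arr, sidecar$fs, sidecar$region_labels, sidecar$subject_id)
}

#' Write a connectivity matrix as TSV plus JSON sidecar
#'
#' The TSV has one header row of region labels and one labelled row per
#' region; the sidecar records `stage`, `band`, `n_epochs` and options.
#'
#' @param m connectivity matrix with region dimnames (e.g. from
#'   [subject_connectivity()]).
#' @param path output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param meta optional extra sidecar fields.
#' @return Invisibly, `path`.
#' @export
write_connectivity_tsv <- function(m, path, meta = list()) {
  if (!is_square_symmetric(m, tol = 1e-10)) stop("matrix must be symmetric")
  if (is.null(rownames(m))) stop("matrix must carry region labels")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(m)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  sidecar <- c(list(stage = attr(m, "stage") %||% "normalized",
                    band = attr(m, "band"),
                    band_name = attr(m, "band_name"),
                    subject_id = attr(m, "subject_id"),
                    n_epochs = attr(m, "n_epochs")),
               meta)
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a connectivity TSV written by [write_connectivity_tsv()]
#'
#' Validates the region label order against the atlas, symmetry of the
#' stored values, and restores the sidecar metadata as attributes.
#'
#' @param path TSV path.
#' @return The connectivity matrix.
#' @export
read_connectivity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  labels <- rownames(m)
  if (!identical(labels, colnames(m))) {
    stop("row and column label order differ")
  }
  check_region_labels(labels)
  if (max(abs(m - t(m))) > 1e-9) {
    stop("asymmetric connectivity entries in ", path)
  }
  json_path <- sub("\\.tsv$", ".json", path)
  if (file.exists(json_path)) {
    sidecar <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    for (f in c("stage", "band", "band_name", "subject_id", "n_epochs")) {
      if (!is.null(sidecar[[f]])) attr(m, f) <- sidecar[[f]]
    }
  }
  m
}

#' Write / read the long-format metric table
#'
#' @param metrics data.frame from [metric_table()].
#' @param path CSV path.
#' @return Invisibly `path` / the data.frame.
#' @export
write_metrics_csv <- function(metrics, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the cohort table
#'
#' CSV with header `subject_id,group,sex,age,WMI,PSI`.
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @return Invisibly `path` / the data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  need <- c("subject_id", "group", "sex", "age", "WMI", "PSI")
  if (!all(need %in% names(cohort))) {
    stop("cohort table missing columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write an arbitrary results object as JSON
#'
#' @param x a list of results (e.g. an MTPC summary).
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_results_json <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
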