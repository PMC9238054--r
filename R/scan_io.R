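#' Read an LSFG composite map from disk
#'
#' Two open dialects are supported:
#'
#' * `"csv"` — a headerless matrix of floats, one image row per line.
#'   Invalid pixels are encoded as `NaN`. Lossless (64-bit) round trip.
#' * `"tiff"` — single-channel 32-bit float TIFF. Because the TIFF writer
#'   stores float samples in \[0, 1\], valid MBR values are mapped into
#'   \[0.01, 0.99\] using the documented full-scale value `tiff_scale`
#'   (default 100 AU) and invalid pixels are stored as 0. This dialect is
#'   lossy at single-float epsilon and clamps values above `tiff_scale`.
#'
#' The dialect is inferred from the file extension unless given explicitly.
#'
#' @param path File to read.
#' @param patient_id,eye,irradiated,scan_index Provenance metadata attached
#'   to the returned scan (see [lsfg_scan()]).
#' @param dialect `"csv"`, `"tiff"`, or `NULL` to infer from the extension.
#' @param tiff_scale Full-scale MBR (AU) used by the TIFF encoding.
#' @return An [lsfg_scan()]. Non-finite stored values become invalid pixels.
#' @export
read_scan <- function(path, patient_id = NA_character_, eye = "OD",
                      irradiated = FALSE, scan_index = 1L,
                      dialect = NULL, tiff_scale = 100) {
  if (!file.exists(path)) {
    abort(sprintf("Scan file does not exist: %s", path), class = "lsfg_io_error")
  }
  dialect <- dialect %||% infer_dialect(path)
  mbr <- switch(dialect,
    csv = read_matrix_csv(path),
    tiff = read_matrix_tiff(path, tiff_scale),
    abort(sprintf("Unknown scan dialect '%s' (use 'csv' or 'tiff').", dialect),
          class = "lsfg_io_error")
  )
  if (!is.matrix(mbr) || any(dim(mbr) < 1)) {
    abort(sprintf("File %s does not contain a 2-D matrix.", path),
          class = "lsfg_io_error")
  }
  if (any(is.finite(mbr) & mbr < 0)) {
    abort(sprintf("File %s contains negative finite MBR values.", path),
          class = "lsfg_negative_mbr")
  }
  lsfg_scan(mbr, patient_id = patient_id, eye = eye,
            irradiated = irradiated, scan_index = scan_index)
}

#' Write an LSFG composite map to disk
#'
#' Invalid pixels are encoded as `NaN` (CSV dialect) or as 0 under the scaled
#' float encoding (TIFF dialect); see [read_scan()] for the dialect
#' definitions.
#'
#' @param scan An [lsfg_scan()].
#' @param path Destination file.
#' @param dialect `"csv"`, `"tiff"`, or `NULL` to infer from the extension.
#' @param tiff_scale Full-scale MBR (AU) for the TIFF encoding.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, dialect = NULL, tiff_scale = 100) {
  stopifnot(inherits(scan, "lsfg_scan"))
  dialect <- dialect %||% infer_dialect(path)
  m <- scan$mbr
  m[!scan$valid] <- NaN
  switch(dialect,
    csv = write_matrix_csv(m, path),
    tiff = write_matrix_tiff(m, path, tiff_scale),
    abort(sprintf("Unknown scan dialect '%s' (use 'csv' or 'tiff').", dialect),
          class = "lsfg_io_error")
  )
  invisible(path)
}

infer_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv",
    tif = ,
    tiff = "tiff",
    abort(sprintf("Cannot infer scan dialect from extension '.%s'.", ext),
          class = "lsfg_io_error")
  )
}

read_matrix_csv <- function(path) {
  df <- utils::read.table(path, sep = ",", header = FALSE,
                          colClasses = "numeric",
                          na.strings = c("NA", "NaN", "nan"))
  as.matrix(df) |> unname()
}

write_matrix_csv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  # format() with digits = 17 keeps doubles exact through the round trip
  lines <- apply(m, 1, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = ",")
  })
  writeLines(lines, con)
}

read_matrix_tiff <- function(path, tiff_scale) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  out <- (x - 0.01) * tiff_scale / 0.98
  out[x < 0.005] <- NaN
  out[out < 0 & is.finite(out)] <- 0
  out
}

write_matrix_tiff <- function(m, path, tiff_scale) {
  enc <- 0.01 + 0.98 * pmin(m, tiff_scale) / tiff_scale
  enc[!is.finite(m)] <- 0
  suppressWarnings(
    tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "none")
  )
}

cohort_metadata_cols <- c(
  "patient_id", "eye", "irradiated", "scan_path_1", "scan_path_2",
  "scan_path_3", "time_from_treatment", "sbp", "dbp", "iop",
  "dose_to_disc", "distance_to_disc", "disc_cy", "disc_cx", "disc_r"
)

#' Write a cohort to disk
#'
#' Writes one scan file per (patient, eye, scan index) plus a metadata table
#' `cohort.csv` with one row per (patient, eye) and columns
#' `patient_id, eye, irradiated, scan_path_1..3, time_from_treatment, sbp,
#' dbp, iop, dose_to_disc, distance_to_disc, disc_cy, disc_cx, disc_r`.
#' Scan paths are stored relative to the directory. The master seed of a
#' synthetic cohort is recorded in `manifest.json`.
#'
#' @param cohort An `lsfg_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param dir Output directory (created if needed).
#' @param dialect Scan file dialect, `"csv"` (default, lossless) or `"tiff"`.
#' @return The path to the metadata table, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = "csv") {
  stopifnot(inherits(cohort, "lsfg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (dialect == "tiff") "tif" else "csv"
  scans <- cohort$scans
  scans$path <- sprintf("%s_%s_%d.%s", scans$patient_id, scans$eye,
                        scans$scan_index, ext)
  purrr::walk2(scans$scan, scans$path, function(sc, p) {
    write_scan(sc, file.path(dir, p), dialect = dialect)
  })
  wide <- scans |>
    dplyr::select("patient_id", "eye", "irradiated", "scan_index", "path") |>
    tidyr::pivot_wider(names_from = "scan_index", values_from = "path",
                       names_prefix = "scan_path_")
  meta <- dplyr::left_join(wide, cohort$patients, by = "patient_id")
  meta$iop <- ifelse(meta$irradiated, meta$iop_irradiated, meta$iop_fellow)
  meta <- meta[, cohort_metadata_cols]
  readr::write_csv(meta, file.path(dir, "cohort.csv"))
  jsonlite::write_json(
    list(seed = cohort$seed, n_patients = nrow(cohort$patients),
         shape = dim(cohort$scans$scan[[1]]$mbr), dialect = dialect),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(file.path(dir, "cohort.csv"))
}

#' Read a cohort from a metadata table plus scan files
#'
#' Validates the paired-eye structure the downstream statistics assume:
#' every patient must have exactly two eyes, three scans per eye, and
#' exactly one irradiated eye. Missing covariates are allowed only for
#' `dose_to_disc` and `distance_to_disc`.
#'
#' @param table_path Metadata CSV (see [write_cohort()] for the layout).
#' @param scan_dir Directory that scan paths are relative to; defaults to
#'   the directory of `table_path`.
#' @param dialect Scan dialect passed to [read_scan()] (`NULL`: infer).
#' @return An `lsfg_cohort`: a list with tibbles `patients` (one row per
#'   patient) and `scans` (one row per scan with an [lsfg_scan()]
#'   list-column), plus the recorded `seed` when a manifest is present.
#' @export
read_cohort <- function(table_path, scan_dir = dirname(table_path),
                        dialect = NULL) {
  meta <- readr::read_csv(table_path, show_col_types = FALSE)
  missing_cols <- setdiff(cohort_metadata_cols, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("Cohort table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "lsfg_cohort_error")
  }
  required <- setdiff(cohort_metadata_cols,
                      c("dose_to_disc", "distance_to_disc"))
  for (cl in required) {
    if (anyNA(meta[[cl]])) {
      abort(sprintf("Column '%s' has missing values (only dose/distance may be missing).", cl),
            class = "lsfg_cohort_error")
    }
  }
  split_rows <- split(meta, meta$patient_id)
  for (pid in names(split_rows)) {
    rows <- split_rows[[pid]]
    if (nrow(rows) != 2 || length(unique(rows$eye)) != 2) {
      abort(sprintf("Patient %s must have exactly 2 eye rows (OD and OS).", pid),
            class = "lsfg_cohort_error")
    }
    if (sum(rows$irradiated) != 1) {
      abort(sprintf("Patient %s must have exactly one irradiated eye.", pid),
            class = "lsfg_cohort_error")
    }
  }
  long <- tidyr::pivot_longer(meta,
                              cols = dplyr::starts_with("scan_path_"),
                              names_to = "scan_index", values_to = "path",
                              names_prefix = "scan_path_")
  long$scan_index <- as.integer(long$scan_index)
  if (anyNA(long$path)) {
    bad <- unique(long$patient_id[is.na(long$path)])
    abort(sprintf("Patient(s) %s do not have 3 scans per eye.",
                  paste(bad, collapse = ", ")),
          class = "lsfg_cohort_error")
  }
  long$scan <- purrr::pmap(
    list(long$path, long$patient_id, long$eye, long$irradiated,
         long$scan_index),
    function(p, pid, eye, irr, idx) {
      fp <- file.path(scan_dir, p)
      if (!file.exists(fp)) {
        abort(sprintf("Missing scan file for patient %s (%s): %s", pid, eye, fp),
              class = "lsfg_cohort_error")
      }
      read_scan(fp, patient_id = pid, eye = eye, irradiated = irr,
                scan_index = idx, dialect = dialect)
    }
  )
  patients <- meta |>
    dplyr::mutate(iop_col = ifelse(meta$irradiated, "iop_irradiated", "iop_fellow")) |>
    dplyr::select("patient_id", "irradiated", "eye", "iop", "time_from_treatment",
                  "sbp", "dbp", "dose_to_disc", "distance_to_disc",
                  "disc_cy", "disc_cx", "disc_r") |>
    tidyr::pivot_wider(
      id_cols = c("patient_id", "time_from_treatment", "sbp", "dbp",
                  "dose_to_disc", "distance_to_disc", "disc_cy", "disc_cx",
                  "disc_r"),
      names_from = "irradiated", values_from = c("iop", "eye")
    ) |>
    dplyr::rename(iop_irradiated = "iop_TRUE", iop_fellow = "iop_FALSE",
                  irradiated_eye = "eye_TRUE") |>
    dplyr::select(-"eye_FALSE")
  seed <- NA_integer_
  mf <- file.path(scan_dir, "manifest.json")
  if (file.exists(mf)) {
    seed <- tryCatch(jsonlite::read_json(mf)$seed, error = function(e) NA_integer_)
  }
  new_lsfg_cohort(
    patients = patients,
    scans = long[, c("patient_id", "eye", "irradiated", "scan_index", "scan")],
    seed = seed
  )
}

new_lsfg_cohort <- function(patients, scans, seed = NA_integer_,
                            effect = NULL) {
  structure(list(patients = as_tibble(patients), scans = as_tibble(scans),
                 seed = seed, effect = effect),
            class = "lsfg_cohort")
}

#' @export
print.lsfg_cohort <- function(x, ...) {
  cat(sprintf("<lsfg_cohort> %d patients, %d scans (%s)\n",
              nrow(x$patients), nrow(x$scans),
              if (is.null(x$effect)) "loaded" else "synthetic"))
  if (!is.na(x$seed)) cat(sprintf("  master seed: %d\n", x$seed))
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Accepts YAML or JSON key-value files; keys mirror the arguments of
#' [pipeline_config()].
#'
#' @param path Config file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path) # yaml is a superset of the JSON we emit
  do.call(pipeline_config, cfg)
}
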