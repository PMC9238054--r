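#' LSFG composite scan object
#'
#' An `lsfg_scan` bundles one composite mean-blur-rate (MBR) map with its
#' validity mask and provenance. MBR is the per-pixel output of laser speckle
#' flowgraphy, in arbitrary units (AU), proportional to relative blood-flow
#' velocity. Pixels where the instrument could not compute a value over the
#' acquisition period are marked invalid (`valid = FALSE`); their stored MBR
#' is `NaN`.
#'
#' Pixel geometry throughout the package: matrices are indexed `[row, col]`,
#' 1-based, origin at the top-left, and distances are measured between pixel
#' centers.
#'
#' @param mbr Numeric matrix of MBR values (AU). Non-finite entries are
#'   treated as invalid pixels.
#' @param valid Logical matrix of the same shape, or `NULL` to derive it from
#'   finiteness of `mbr`.
#' @param patient_id Character identifier.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param irradiated Logical flag: is this the treated eye?
#' @param scan_index Integer in 1..3; LSFG protocols take three successive
#'   scans per eye.
#'
#' @return An object of class `lsfg_scan`: a list with elements `mbr`,
#'   `valid`, `patient_id`, `eye`, `irradiated`, `scan_index`.
#' @export
#' @examples
#' sc <- lsfg_scan(matrix(c(1, 2, 3, NaN), 2), patient_id = "P1", eye = "OD")
#' sc$valid
lsfg_scan <- function(mbr, valid = NULL, patient_id = NA_character_,
                      eye = c("OD", "OS"), irradiated = FALSE,
                      scan_index = 1L) {
  if (!is.matrix(mbr) || !is.numeric(mbr)) {
    abort("`mbr` must be a numeric matrix (2-D MBR map).", class = "lsfg_bad_scan")
  }
  eye <- match.arg(eye)
  if (is.null(valid)) {
    valid <- is.finite(mbr)
  }
  if (!is.logical(valid) || !identical(dim(valid), dim(mbr))) {
    abort("`valid` must be a logical matrix with the same shape as `mbr`.",
          class = "lsfg_bad_scan")
  }
  valid <- valid & is.finite(mbr)
  if (any(mbr[valid] < 0)) {
    abort("Valid MBR values must be >= 0 AU.", class = "lsfg_negative_mbr")
  }
  mbr[!valid] <- NaN
  if (!scan_index %in% 1:3) {
    abort("`scan_index` must be 1, 2 or 3.", class = "lsfg_bad_scan")
  }
  structure(
    list(mbr = mbr, valid = valid, patient_id = as.character(patient_id),
         eye = eye, irradiated = isTRUE(irradiated),
         scan_index = as.integer(scan_index)),
    class = "lsfg_scan"
  )
}

#' @export
print.lsfg_scan <- function(x, ...) {
  d <- dim(x$mbr)
  v <- x$mbr[x$valid]
  cat(sprintf(
    "<lsfg_scan> %d x %d px | patient %s, eye %s%s, scan %d\n",
    d[1], d[2], x$patient_id, x$eye,
    if (x$irradiated) " (irradiated)" else "", x$scan_index
  ))
  cat(sprintf("  valid pixels: %d/%d (%.1f%%)\n",
              sum(x$valid), length(x$valid), 100 * mean(x$valid)))
  if (length(v)) {
    cat(sprintf("  MBR (AU): median %.2f, range [%.2f, %.2f]\n",
                stats::median(v), min(v), max(v)))
  }
  invisible(x)
}

#' Convert a scan to a tidy pixel table
#'
#' @param x An [lsfg_scan()].
#' @param ... Unused.
#' @return A tibble with one row per pixel: `row`, `col`, `mbr`, `valid`.
#' @export
as_tibble.lsfg_scan <- function(x, ...) {
  d <- dim(x$mbr)
  tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    mbr = as.vector(x$mbr),
    valid = as.vector(x$valid)
  )
}

#' Plot an MBR map
#'
#' Renders the composite MBR map with the conventional LSFG color scale
#' (low flow blue, high flow red); invalid pixels are drawn white.
#'
#' @param object An [lsfg_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsfg_scan <- function(object, ...) {
  px <- as_tibble(object)
  px$mbr[!px$valid] <- NA_real_
  ggplot2::ggplot(px, ggplot2::aes(.data$col, .data$row, fill = .data$mbr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = c("#313695", "#74add1", "#ffffbf", "#f46d43", "#a50026"),
      na.value = "white", name = "MBR (AU)"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Patient %s, %s, scan %d", object$patient_id,
                      object$eye, object$scan_index),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

scan_shape <- function(scan) dim(scan$mbr)
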