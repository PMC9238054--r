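#' SLIC superpixel segmentation of an MBR map
#'
#' Groups pixels of the composite MBR map into approximately `n_target`
#' spatially connected superpixels using simple linear iterative clustering
#' (SLIC): local k-means in (MBR, row, col) space, initialized on a regular
#' grid with spacing `S = sqrt(n_pixels / n_target)`, using the distance
#' `D^2 = (dMBR / compactness)^2 + (drow^2 + dcol^2) / S^2` over 10
#' iterations, followed by a connectivity pass that merges orphan fragments
#' into an adjacent superpixel. Higher `compactness` weights spatial
#' proximity over MBR uniformity. Invalid pixels participate in the
#' segmentation with the mean valid MBR substituted, so labels partition
#' the full frame; validity is accounted for in [superpixel_means()].
#'
#' The algorithm is deterministic for a given scan; `seed` is accepted for
#' interface stability and recorded, but no step of the computation is
#' randomized.
#'
#' @param scan An [lsfg_scan()], at least 32 x 32 px.
#' @param n_target Target superpixel count (default 1500, the whole-frame
#'   operating point; must be >= 4 and at most the pixel count).
#' @param compactness Compactness factor (default 50).
#' @param seed Recorded in the result; see above.
#' @param max_iter k-means iterations (default 10).
#' @return An `lsfg_superpixels` object: `labels` (integer matrix, 1..k),
#'   `k`, and (after [superpixel_means()]) per-label summaries.
#' @export
slic_segment <- function(scan, n_target = 1500, compactness = 50,
                         seed = 1L, max_iter = 10L) {
  shape <- scan_shape(scan)
  if (any(shape < 32)) {
    abort("Scan must be at least 32 x 32 px for superpixel analysis.",
          class = "lsfg_bad_shape")
  }
  if (n_target < 4) {
    abort("`n_target` must be >= 4.", class = "lsfg_bad_segmentation")
  }
  if (n_target > prod(shape)) {
    abort("`n_target` exceeds the pixel count.", class = "lsfg_bad_segmentation")
  }
  img <- scan$mbr
  if (!all(scan$valid)) {
    img[!scan$valid] <- mean(scan$mbr[scan$valid])
  }
  labels <- .slic_cpp(img, as.integer(n_target), compactness,
                      as.integer(max_iter))
  structure(
    list(labels = labels, k = max(labels), n_target = n_target,
         compactness = compactness, seed = as.integer(seed),
         mean_mbr = NULL, defined = NULL, n_px = NULL, n_valid = NULL),
    class = "lsfg_superpixels"
  )
}

#' @export
print.lsfg_superpixels <- function(x, ...) {
  cat(sprintf("<lsfg_superpixels> k = %d (target %d), compactness %g\n",
              x$k, x$n_target, x$compactness))
  if (!is.null(x$defined)) {
    cat(sprintf("  defined superpixels: %d, undefined: %d\n",
                sum(x$defined), sum(!x$defined)))
  }
  invisible(x)
}

#' Per-superpixel mean MBR
#'
#' Fills each superpixel's mean MBR over its valid pixels. Superpixels with
#' a valid-pixel fraction below `validity_cutoff` are marked undefined
#' (mirroring the white, undefined superpixels in instrument output) and
#' take no part in the flow histograms.
#'
#' @param scan The [lsfg_scan()] that was segmented.
#' @param seg An `lsfg_superpixels` from [slic_segment()].
#' @param validity_cutoff Minimum valid-pixel fraction (default 0.5).
#' @return `seg` with `mean_mbr` (NA where undefined), `defined`, `n_px`
#'   and `n_valid` filled.
#' @export
superpixel_means <- function(scan, seg, validity_cutoff = 0.5) {
  stopifnot(inherits(seg, "lsfg_superpixels"))
  if (!identical(dim(seg$labels), dim(scan$mbr))) {
    abort("Segmentation labels do not cover this scan (shape mismatch).",
          class = "lsfg_bad_segmentation")
  }
  lab <- as.vector(seg$labels)
  val <- as.vector(scan$valid)
  mbr <- as.vector(scan$mbr)
  n_px <- tabulate(lab, nbins = seg$k)
  n_valid <- tabulate(lab[val], nbins = seg$k)
  sums <- rep(0, seg$k)
  s <- rowsum(mbr[val], lab[val])
  sums[as.integer(rownames(s))] <- s[, 1]
  mean_mbr <- ifelse(n_valid > 0, sums / n_valid, NA_real_)
  defined <- n_valid / n_px >= validity_cutoff & n_valid > 0
  mean_mbr[!defined] <- NA_real_
  seg$mean_mbr <- mean_mbr
  seg$defined <- defined
  seg$n_px <- n_px
  seg$n_valid <- n_valid
  seg
}

#' Categorical flow-range histogram of superpixel means
#'
#' Bins the defined superpixel means into the five categorical MBR ranges
#' `< 5`, `5 to 10`, `10 to 15`, `15 to 20` and `>= 20` AU and reports the
#' percentage of defined superpixels in each. Bins are half-open
#' `[lo, hi)`; a mean of exactly 5 falls in `[5, 10)`, and the last bin is
#' `[20, Inf)`.
#'
#' @param seg An `lsfg_superpixels` with means filled (see
#'   [superpixel_means()]).
#' @param bin_edges Lower edges plus `Inf` (default `c(0, 5, 10, 15, 20,
#'   Inf)`).
#' @return An `lsfg_flow_histogram`: a tibble with columns `bin`, `lo`,
#'   `hi`, `n`, `percent`, and attributes `n_defined`, `n_undefined`.
#' @export
bin_histogram <- function(seg, bin_edges = c(0, 5, 10, 15, 20, Inf)) {
  stopifnot(inherits(seg, "lsfg_superpixels"))
  if (is.null(seg$mean_mbr)) {
    abort("Run superpixel_means() before bin_histogram().",
          class = "lsfg_bad_segmentation")
  }
  means <- seg$mean_mbr[seg$defined]
  if (length(means) == 0) {
    abort("No defined superpixels: flow histogram is undefined.",
          class = "lsfg_no_defined_superpixels")
  }
  nb <- length(bin_edges) - 1
  idx <- findInterval(means, bin_edges[-c(1, length(bin_edges))]) + 1L
  n <- tabulate(idx, nbins = nb)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  out <- tibble(
    bin = seq_len(nb),
    label = ifelse(is.infinite(hi), sprintf(">= %g", lo),
                   ifelse(lo == bin_edges[1], sprintf("< %g", hi),
                          sprintf("%g to %g", lo, hi))),
    lo = lo, hi = hi, n = n,
    percent = 100 * n / length(means)
  )
  attr(out, "n_defined") <- length(means)
  attr(out, "n_undefined") <- sum(!seg$defined)
  attr(out, "bin_edges") <- bin_edges
  class(out) <- c("lsfg_flow_histogram", class(out))
  out
}

#' Pixel mask of one categorical flow range
#'
#' @param seg An `lsfg_superpixels` with means filled.
#' @param bin_index Bin number 1..5 (1 is `< 5` AU, 5 is `>= 20` AU).
#' @param bin_edges As in [bin_histogram()].
#' @return Logical matrix, `TRUE` on pixels whose superpixel's mean MBR
#'   falls in the bin; pixels of undefined superpixels are in no bin.
#' @export
range_map <- function(seg, bin_index, bin_edges = c(0, 5, 10, 15, 20, Inf)) {
  nb <- length(bin_edges) - 1
  if (!bin_index %in% seq_len(nb)) {
    abort(sprintf("`bin_index` must be in 1..%d.", nb),
          class = "lsfg_bad_segmentation")
  }
  in_bin <- !is.na(seg$mean_mbr) &
    seg$mean_mbr >= bin_edges[bin_index] &
    seg$mean_mbr < bin_edges[bin_index + 1]
  matrix(in_bin[as.vector(seg$labels)], nrow(seg$labels), ncol(seg$labels))
}

#' Headline whole-scan flow measures
#'
#' Projects the flow histogram onto the two measures used for analysis:
#' the percent of superpixels with mean MBR >= 20 AU (superficial retinal
#' vessel flow area) and < 5 AU (lowest choroidal flow area).
#'
#' @param seg An `lsfg_superpixels` with means filled.
#' @return A one-row tibble: `pct_ge20`, `pct_lt5`.
#' @export
flow_measures <- function(seg) {
  h <- bin_histogram(seg)
  tibble(pct_ge20 = h$percent[5], pct_lt5 = h$percent[1])
}

#' Plot a flow-range histogram
#'
#' @param object An `lsfg_flow_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsfg_flow_histogram <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$percent, fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("#313695", "#74add1", "#ffffbf",
                                          "#f46d43", "#a50026")) +
    ggplot2::labs(x = "MBR range (AU)", y = "% of superpixels") +
    ggplot2::theme_minimal()
}
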