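# Euclidean distance of every pixel center from `center` (row, col), 1-based.
pixel_distance <- function(shape, center) {
  dr <- seq_len(shape[1]) - center[1]
  dc <- seq_len(shape[2]) - center[2]
  sqrt(outer(dr^2, dc^2, "+"))
}

#' Define the peripapillary measurement annulus
#'
#' Standard LSFG peripapillary analysis places two concentric rings centered
#' on the optic nerve head: the inner ring at the disc margin and the outer
#' ring one disc radius further out, so the measured band covers the
#' peripapillary retinal vasculature. Accordingly `inner_radius =
#' disc_radius` and `outer_radius = 2 * disc_radius`.
#'
#' @param center `c(row, col)` of the disc center (1-based pixel
#'   coordinates).
#' @param disc_radius Disc radius in pixels (> 0).
#' @param shape Image dimensions `c(nrow, ncol)`; the outer ring must fit
#'   inside the frame.
#' @return An `annulus_spec`: list with `center`, `inner_radius`,
#'   `outer_radius`.
#' @export
#' @examples
#' make_annulus(c(180, 375), 40, shape = c(360, 750))
make_annulus <- function(center, disc_radius, shape) {
  if (disc_radius <= 0) {
    abort("`disc_radius` must be > 0.", class = "lsfg_bad_annulus")
  }
  outer_r <- 2 * disc_radius
  if (center[1] - outer_r < 1 || center[1] + outer_r > shape[1] ||
      center[2] - outer_r < 1 || center[2] + outer_r > shape[2]) {
    abort(paste0(
      "The outer annulus (radius ", outer_r, " px) crosses the frame edge; ",
      "use a smaller disc radius or re-center the disc."
    ), class = "lsfg_bad_annulus")
  }
  structure(list(center = center, inner_radius = disc_radius,
                 outer_radius = outer_r),
            class = "annulus_spec")
}

#' Rasterize an annulus into a boolean mask
#'
#' A pixel belongs to the annulus when its center's Euclidean distance `d`
#' from the annulus center satisfies `inner_radius <= d < outer_radius`.
#'
#' @param spec An `annulus_spec` (see [make_annulus()]), or any list with
#'   `center`, `inner_radius`, `outer_radius`.
#' @param shape Image dimensions `c(nrow, ncol)`.
#' @return Logical matrix.
#' @export
annulus_mask <- function(spec, shape) {
  if (spec$inner_radius <= 0 || spec$outer_radius <= spec$inner_radius) {
    abort("Annulus radii must satisfy 0 < inner < outer.",
          class = "lsfg_bad_annulus")
  }
  d <- pixel_distance(shape, spec$center)
  d >= spec$inner_radius & d < spec$outer_radius
}

#' Histogram threshold separating vessel from tissue flow
#'
#' Computes Otsu's threshold on a 256-bin histogram spanning the value
#' range: the cut maximizing between-class variance. In the peripapillary
#' band, pixels above the threshold are attributed to superficial retinal
#' arterioles and venules (MV) and pixels at or below it to choroidal
#' tissue (MT). Ties between equally good cuts are resolved by averaging
#' the tied cut positions.
#'
#' @param values Numeric vector of MBR values (AU); at least 2 distinct
#'   finite values.
#' @return The threshold (AU), strictly between `min(values)` and
#'   `max(values)`.
#' @export
threshold_vessel_tissue <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2 || min(v) == max(v)) {
    abort("degenerate histogram: need >= 2 distinct finite values to split MV/MT.",
          class = "lsfg_degenerate_histogram")
  }
  n_bins <- 256L
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / n_bins
  bin <- pmin(floor((v - lo) / width) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / length(v)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(p)[-n_bins]            # class weight below/at cut t
  mu0 <- cumsum(p * mids)[-n_bins]    # unnormalized class-0 mean
  mu_t <- sum(p * mids)
  # between-class variance at each of the 255 cuts
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  best <- which(sigma_b == max(sigma_b))
  lo + mean(best) * width             # cut at the upper edge of bin t
}

#' Peripapillary vessel and tissue flow (MV / MT)
#'
#' Applies the annulus mask, thresholds the valid outer-band MBR values
#' with [threshold_vessel_tissue()], and returns the mean blur rate of the
#' above-threshold compartment (MV, superficial retinal vessels) and the
#' at-or-below-threshold compartment (MT, choroidal tissue). The mean MBR
#' inside the inner band (on-disc flow) is computed as `inner_mean` but is
#' not part of the headline outputs.
#'
#' @param scan An [lsfg_scan()].
#' @param spec An `annulus_spec` (see [make_annulus()]).
#' @param min_valid_px Robustness floor on the number of valid annulus
#'   pixels (default 100).
#' @return A one-row tibble: `mv`, `mt`, `threshold` (AU), `n_vessel_px`,
#'   `n_tissue_px`, `inner_mean`.
#' @export
compute_mv_mt <- function(scan, spec, min_valid_px = 100) {
  shape <- scan_shape(scan)
  ring <- annulus_mask(spec, shape)
  sel <- ring & scan$valid
  vals <- scan$mbr[sel]
  if (length(vals) < min_valid_px) {
    abort(sprintf(
      "Only %d valid pixels in the annulus (need >= %d); widen the band or check the mask.",
      length(vals), min_valid_px
    ), class = "lsfg_too_few_pixels")
  }
  thr <- threshold_vessel_tissue(vals)
  vessel <- vals > thr
  d <- pixel_distance(shape, spec$center)
  inner_sel <- d < spec$inner_radius & scan$valid
  tibble(
    mv = mean(vals[vessel]),
    mt = mean(vals[!vessel]),
    threshold = thr,
    n_vessel_px = sum(vessel),
    n_tissue_px = sum(!vessel),
    inner_mean = if (any(inner_sel)) mean(scan$mbr[inner_sel]) else NA_real_
  )
}
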