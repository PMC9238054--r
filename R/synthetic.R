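#' Irradiation effect model for synthetic cohorts
#'
#' Parameterises the generative model used by [render_scan()] and
#' [generate_cohort()]. A scan is a spatially correlated choroidal background
#' around `baseline_choroid_mbr_mean`, overwritten by a branching vessel tree
#' near `baseline_vessel_mbr` and a high-flow optic-disc region. In the
#' irradiated eye the whole map is multiplied by a time-dependent flow
#' multiplier
#' \deqn{m(t) = \max(m_{min},\; 1 - k\, t)}
#' with `t` the time from treatment in months; fellow eyes always receive
#' multiplier 1. Independent Gaussian scan noise is added per scan and a
#' small fraction of pixels is marked undefined, as in instrument output.
#'
#' @param baseline_vessel_mbr Vessel MBR at baseline (AU, default 25).
#' @param baseline_choroid_mbr_mean Mean choroidal background MBR (AU,
#'   default 10).
#' @param choroid_mbr_sd Marginal SD of the choroidal background field (AU,
#'   default 3).
#' @param flow_decay_per_month `k`, fractional flow loss per month in the
#'   irradiated eye (default 0.01).
#' @param min_flow_multiplier `m_min`, floor of the multiplier (default 0.4;
#'   must be > 0).
#' @param scan_noise_sd Per-scan independent noise SD (AU, default 1).
#' @param undefined_pixel_fraction Fraction of pixels marked undefined
#'   (default 0.005; must be in \[0, 1)).
#' @param choroid_corr_px Gaussian correlation length of the background
#'   field, in pixels (default 30).
#' @param disc_mbr MBR of the optic-disc region (AU, default 30).
#' @return An object of class `lsfg_effect_model`.
#' @export
#' @examples
#' eff <- effect_model()
#' flow_multiplier(eff, t_months = 60, irradiated = TRUE) # hits the 0.4 floor
effect_model <- function(baseline_vessel_mbr = 25,
                         baseline_choroid_mbr_mean = 10,
                         choroid_mbr_sd = 3,
                         flow_decay_per_month = 0.01,
                         min_flow_multiplier = 0.4,
                         scan_noise_sd = 1,
                         undefined_pixel_fraction = 0.005,
                         choroid_corr_px = 30,
                         disc_mbr = 30) {
  if (baseline_vessel_mbr < 0 || baseline_choroid_mbr_mean < 0 || disc_mbr < 0) {
    abort("Baseline MBR levels must be >= 0 AU (flow cannot be negative).",
          class = "lsfg_bad_effect")
  }
  if (min_flow_multiplier <= 0) {
    abort("`min_flow_multiplier` must be > 0.", class = "lsfg_bad_effect")
  }
  if (flow_decay_per_month < 0) {
    abort("`flow_decay_per_month` must be >= 0.", class = "lsfg_bad_effect")
  }
  if (choroid_mbr_sd < 0 || scan_noise_sd < 0) {
    abort("Noise standard deviations must be >= 0.", class = "lsfg_bad_effect")
  }
  if (undefined_pixel_fraction < 0 || undefined_pixel_fraction >= 1) {
    abort("`undefined_pixel_fraction` must be in [0, 1).",
          class = "lsfg_bad_effect")
  }
  structure(
    list(baseline_vessel_mbr = baseline_vessel_mbr,
         baseline_choroid_mbr_mean = baseline_choroid_mbr_mean,
         choroid_mbr_sd = choroid_mbr_sd,
         flow_decay_per_month = flow_decay_per_month,
         min_flow_multiplier = min_flow_multiplier,
         scan_noise_sd = scan_noise_sd,
         undefined_pixel_fraction = undefined_pixel_fraction,
         choroid_corr_px = choroid_corr_px,
         disc_mbr = disc_mbr),
    class = "lsfg_effect_model"
  )
}

#' @rdname effect_model
#' @param effect An `lsfg_effect_model`.
#' @param t_months Time from treatment (months, >= 0).
#' @param irradiated Is the eye the treated one?
#' @export
flow_multiplier <- function(effect, t_months, irradiated) {
  stopifnot(inherits(effect, "lsfg_effect_model"), all(t_months >= 0))
  ifelse(irradiated,
         pmax(effect$min_flow_multiplier,
              1 - effect$flow_decay_per_month * t_months),
         1)
}

#' Generate a branching retinal vessel tree mask
#'
#' Draws curvilinear branching trunks radiating from a disc-center point by
#' seeded persistent random walks, emulating the branch retinal arterioles
#' and venules visible in LSFG composites. The vessel pixel fraction is
#' enforced by construction to lie in \[0.02, 0.20\]: trunks are added until
#' the lower bound is reached and stamping stops before the upper bound is
#' exceeded.
#'
#' @param shape `c(nrow, ncol)`, both >= 32.
#' @param seed Integer RNG seed; identical inputs give identical masks.
#' @param branching_params Optional list overriding `n_trunks` (default 7),
#'   `branch_prob` (per-step child spawn probability, default 0.02),
#'   `max_depth` (branching generations below the trunks, default 2),
#'   `center` (default frame center), `step_sd` (angular jitter SD per step,
#'   radians, default 0.12), and `trunk_thickness` (px, default 2).
#'   `branch_prob = 0` yields trunks only.
#' @return Logical matrix; `TRUE` on vessel pixels.
#' @export
generate_vessel_tree <- function(shape, seed, branching_params = list()) {
  if (length(shape) != 2 || any(shape < 32)) {
    abort("`shape` must be c(nrow, ncol) with both dimensions >= 32.",
          class = "lsfg_bad_shape")
  }
  p <- modifyList(
    list(n_trunks = 7L, branch_prob = 0.02, max_depth = 2L,
         center = (shape + 1) / 2, step_sd = 0.12, trunk_thickness = 2L),
    branching_params
  )
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(FALSE, nr, nc)
  max_px <- 0.20 * nr * nc

  with_seed(seed, {
    stamp_branch <- function(r0, c0, angle, len, thickness, depth = 0L) {
      if (sum(mask) >= max_px) return(invisible(NULL))
      ang <- angle + cumsum(rnorm(len, 0, p$step_sd))
      rr <- r0 + cumsum(sin(ang))
      cc <- c0 + cumsum(cos(ang))
      keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      rr <- rr[keep]; cc <- cc[keep]
      if (!length(rr)) return(invisible(NULL))
      ri <- round(rr); ci <- round(cc)
      if (thickness > 1) {
        off <- expand.grid(dr = -(thickness - 1):(thickness - 1),
                           dc = -(thickness - 1):(thickness - 1))
        off <- off[off$dr^2 + off$dc^2 <= (thickness - 1)^2, , drop = FALSE]
        ri <- rep(ri, each = nrow(off)) + off$dr
        ci <- rep(ci, each = nrow(off)) + off$dc
        ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
        ri <- ri[ok]; ci <- ci[ok]
      }
      n_new <- sum(!mask[cbind(ri, ci)])
      if (sum(mask) + n_new > max_px) return(invisible(NULL))
      mask[cbind(ri, ci)] <<- TRUE
      # children spawn along the parent path
      if (p$branch_prob > 0 && depth < p$max_depth && len > 12) {
        spawn <- which(runif(length(rr)) < p$branch_prob)
        for (s in spawn) {
          stamp_branch(rr[s], cc[s], ang[s] + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
                       round(len / 2), max(1L, thickness - 1L), depth + 1L)
        }
      }
      invisible(NULL)
    }

    add_trunks <- function(n) {
      base_angle <- runif(1, 0, 2 * pi)
      for (i in seq_len(n)) {
        ang <- base_angle + 2 * pi * (i - 1) / n + rnorm(1, 0, 0.2)
        stamp_branch(p$center[1], p$center[2], ang,
                     len = round(0.7 * max(nr, nc)), thickness = p$trunk_thickness)
      }
    }

    add_trunks(p$n_trunks)
    tries <- 0
    while (mean(mask) < 0.02 && tries < 25) {
      add_trunks(2L)
      tries <- tries + 1
    }
  })
  mask
}

# Separable Gaussian blur by banded-kernel matrix products.
gauss_blur <- function(m, sigma) {
  kern <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  kern(nrow(m)) %*% m %*% t(kern(ncol(m)))
}

# Spatially correlated choroidal background field.
choroid_field <- function(shape, mean, sd, corr_px) {
  w <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  z <- gauss_blur(w, corr_px / 2)
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  mean + sd * z
}

# Noise-free anatomical base map for one eye (shared by its 3 repeat scans).
render_anatomy <- function(spec, eye, effect, shape, disc_center, disc_radius) {
  aseed <- derive_seed(spec$rng_seed, as.integer(eye == "OS"))
  base <- with_seed(aseed, {
    fld <- choroid_field(shape, effect$baseline_choroid_mbr_mean,
                         effect$choroid_mbr_sd, effect$choroid_corr_px)
    fld
  })
  d <- pixel_distance(shape, disc_center)
  base[d < disc_radius] <- effect$disc_mbr
  vessels <- generate_vessel_tree(
    shape, seed = derive_seed(aseed, 7L),
    branching_params = list(center = disc_center)
  )
  base[vessels] <- effect$baseline_vessel_mbr
  pmax(base, 0)
}

#' Render one synthetic LSFG scan
#'
#' Builds the composite MBR map for one (patient, eye, scan) combination:
#' correlated choroidal background, vessel tree and disc region (the
#' anatomy, shared across the eye's three repeat scans), multiplied by the
#' irradiation flow multiplier when the eye is the treated one, plus
#' independent per-scan noise and randomly placed undefined pixels.
#'
#' @param spec One-row tibble or named list with at least `patient_id`,
#'   `irradiated_eye`, `time_from_treatment` and `rng_seed` (see
#'   [generate_cohort()]).
#' @param eye `"OD"` or `"OS"`.
#' @param scan_index 1, 2 or 3.
#' @param effect An [effect_model()].
#' @param shape Image dimensions `c(nrow, ncol)` (default `c(360, 750)`,
#'   the sensor frame).
#' @param disc_center `c(row, col)` of the optic disc (default frame
#'   center).
#' @param disc_radius Disc radius in px (default 40).
#' @return An [lsfg_scan()].
#' @export
render_scan <- function(spec, eye, scan_index, effect = effect_model(),
                        shape = c(360, 750), disc_center = NULL,
                        disc_radius = 40) {
  stopifnot(inherits(effect, "lsfg_effect_model"))
  if (!scan_index %in% 1:3) {
    abort("`scan_index` must be 1, 2 or 3.", class = "lsfg_bad_scan")
  }
  disc_center <- disc_center %||% (shape + 1) / 2
  base <- render_anatomy(spec, eye, effect, shape, disc_center, disc_radius)
  add_scan_noise(base, spec, eye, scan_index, effect)
}

add_scan_noise <- function(base, spec, eye, scan_index, effect) {
  irr <- identical(eye, spec$irradiated_eye)
  m <- flow_multiplier(effect, spec$time_from_treatment, irr)
  nseed <- derive_seed(spec$rng_seed, as.integer(eye == "OS"), scan_index + 100L)
  with_seed(nseed, {
    mbr <- base * m + matrix(rnorm(length(base), 0, effect$scan_noise_sd),
                             nrow(base), ncol(base))
    mbr <- pmax(mbr, 0)
    valid <- matrix(TRUE, nrow(base), ncol(base))
    n_undef <- round(effect$undefined_pixel_fraction * length(base))
    if (n_undef > 0) {
      idx <- sample.int(length(base), n_undef)
      valid[idx] <- FALSE
    }
    lsfg_scan(mbr, valid, patient_id = spec$patient_id, eye = eye,
              irradiated = irr, scan_index = scan_index)
  })
}

#' Generate a synthetic paired-eye LSFG cohort
#'
#' Produces `n_patients` patients, each with two eyes (one irradiated) and
#' three repeat scans per eye, plus hemodynamic and treatment covariates
#' drawn around published cohort means (SBP 136 +/- 17 mmHg, DBP 80 +/- 10,
#' IOP ~ 14-15 mmHg, dose to disc centered on 38 Gy). Times from treatment
#' are log-normal (median 24 months, mean about 33 months, matching the
#' follow-up structure of published brachytherapy cohorts) clamped to
#' `t_range`, so early and late follow-up are both represented.
#'
#' @inheritParams render_scan
#' @param n_patients Number of patients (>= 2; paired statistics are
#'   undefined below that).
#' @param seed Master seed; the full cohort is reproducible from it.
#' @param t_range Range of times from treatment in months (default
#'   `c(0.5, 144)`).
#' @return An `lsfg_cohort`: tibbles `patients` (one row per patient) and
#'   `scans` (one row per scan, list-column `scan` of [lsfg_scan()]s), the
#'   `effect` model and master `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(3, seed = 1, shape = c(64, 96), disc_radius = 10,
#'                        effect = effect_model(choroid_corr_px = 8))
#' coh$patients
generate_cohort <- function(n_patients, effect = effect_model(), seed = 1,
                            shape = c(360, 750), disc_center = NULL,
                            disc_radius = 40, t_range = c(0.5, 144)) {
  if (n_patients < 2) {
    abort("`n_patients` must be >= 2 (paired statistics are undefined otherwise).",
          class = "lsfg_bad_cohort")
  }
  stopifnot(inherits(effect, "lsfg_effect_model"))
  disc_center <- disc_center %||% (shape + 1) / 2

  patients <- with_seed(seed, {
    sbp <- pmax(round(rnorm(n_patients, 136, 17)), 90)
    dbp <- pmin(pmax(round(rnorm(n_patients, 80, 10)), 50), sbp - 10)
    tibble(
      patient_id = sprintf("P%02d", seq_len(n_patients)),
      irradiated_eye = sample(c("OD", "OS"), n_patients, replace = TRUE),
      time_from_treatment = round(pmin(pmax(
        exp(rnorm(n_patients, log(24), 0.9)), t_range[1]), t_range[2]), 1),
      sbp = sbp,
      dbp = dbp,
      iop_irradiated = pmax(round(rnorm(n_patients, 14.4, 3.8), 1), 5),
      iop_fellow = pmax(round(rnorm(n_patients, 15.2, 3.2), 1), 5),
      dose_to_disc = pmax(round(rnorm(n_patients, 38, 15), 1), 2),
      distance_tumor_to_disc = round(exp(rnorm(n_patients, log(3), 0.6)), 2),
      disc_cy = disc_center[1],
      disc_cx = disc_center[2],
      disc_r = disc_radius,
      rng_seed = sample.int(2147483646L, n_patients)
    )
  })

  scans <- purrr::map(seq_len(n_patients), function(i) {
    spec <- as.list(patients[i, ])
    purrr::map(c("OD", "OS"), function(eye) {
      base <- render_anatomy(spec, eye, effect, shape, disc_center, disc_radius)
      purrr::map(1:3, function(k) add_scan_noise(base, spec, eye, k, effect))
    })
  })
  scans <- purrr::flatten(purrr::flatten(scans))
  scan_tbl <- tibble(
    patient_id = purrr::map_chr(scans, "patient_id"),
    eye = purrr::map_chr(scans, "eye"),
    irradiated = purrr::map_lgl(scans, "irradiated"),
    scan_index = purrr::map_int(scans, "scan_index"),
    scan = scans
  )
  # column name used by the on-disk metadata dialect
  patients <- dplyr::rename(patients, distance_to_disc = "distance_tumor_to_disc")
  new_lsfg_cohort(patients, scan_tbl, seed = as.integer(seed), effect = effect)
}
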