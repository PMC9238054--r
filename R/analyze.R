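#' Analyze one LSFG scan
#'
#' Runs both analyses on a composite map: the peripapillary annulus
#' analysis ([compute_mv_mt()]) and the whole-scan superpixel analysis
#' ([slic_segment()], [superpixel_means()], [bin_histogram()]).
#'
#' @param scan An [lsfg_scan()].
#' @param disc_center `c(row, col)` of the optic disc.
#' @param disc_radius Disc radius in pixels.
#' @param n_superpixels,compactness,seed Passed to [slic_segment()].
#' @param bin_edges Passed to [bin_histogram()].
#' @param exclude_mask Optional logical matrix; `TRUE` pixels are excluded
#'   from both analyses (treated as invalid).
#' @return A one-row tibble with provenance columns, `mv`, `mt`,
#'   `threshold`, `pct_lt5`, `pct_5_10`, `pct_10_15`, `pct_15_20`,
#'   `pct_ge20`, `n_superpixels`, `n_defined`, `n_undefined`.
#' @export
analyze_scan <- function(scan, disc_center, disc_radius,
                         n_superpixels = 1500, compactness = 50, seed = 1L,
                         bin_edges = c(0, 5, 10, 15, 20, Inf),
                         exclude_mask = NULL) {
  if (!is.null(exclude_mask)) {
    stopifnot(identical(dim(exclude_mask), dim(scan$mbr)))
    scan$valid <- scan$valid & !exclude_mask
    scan$mbr[!scan$valid] <- NaN
  }
  ann <- make_annulus(disc_center, disc_radius, scan_shape(scan))
  peri <- compute_mv_mt(scan, ann)
  seg <- slic_segment(scan, n_target = n_superpixels,
                      compactness = compactness, seed = seed)
  seg <- superpixel_means(scan, seg)
  h <- bin_histogram(seg, bin_edges)
  tibble(
    patient_id = scan$patient_id, eye = scan$eye,
    irradiated = scan$irradiated, scan_index = scan$scan_index,
    mv = peri$mv, mt = peri$mt, threshold = peri$threshold,
    pct_lt5 = h$percent[1], pct_5_10 = h$percent[2],
    pct_10_15 = h$percent[3], pct_15_20 = h$percent[4],
    pct_ge20 = h$percent[5],
    n_superpixels = seg$k,
    n_defined = attr(h, "n_defined"), n_undefined = attr(h, "n_undefined")
  )
}

measure_cols <- c("mv", "mt", "pct_lt5", "pct_5_10", "pct_10_15",
                  "pct_15_20", "pct_ge20")

#' Per-eye measures for a whole cohort
#'
#' Analyzes every scan and averages the three repeat scans of each eye into
#' one per-eye record, attaching the covariates (time from treatment, OPP
#' from the eye's IOP and the patient's cuff pressures, dose and distance
#' to the disc).
#'
#' @param cohort An `lsfg_cohort` (see [generate_cohort()],
#'   [read_cohort()]).
#' @param n_superpixels,compactness,seed,bin_edges,exclude_mask Passed to
#'   [analyze_scan()].
#' @param allow_missing_scans Accept eyes with fewer than 3 scans (with a
#'   warning) instead of erroring.
#' @return A list with tibbles `per_scan` (one row per scan) and `per_eye`
#'   (one row per patient-eye with 3-scan-averaged measures and
#'   covariates).
#' @export
analyze_cohort <- function(cohort, n_superpixels = 1500, compactness = 50,
                           seed = 1L, bin_edges = c(0, 5, 10, 15, 20, Inf),
                           exclude_mask = NULL, allow_missing_scans = FALSE) {
  stopifnot(inherits(cohort, "lsfg_cohort"))
  pats <- cohort$patients
  geom <- setNames(
    purrr::map(seq_len(nrow(pats)), function(i) {
      list(center = c(pats$disc_cy[i], pats$disc_cx[i]), r = pats$disc_r[i])
    }),
    pats$patient_id
  )
  per_scan <- purrr::map_dfr(cohort$scans$scan, function(sc) {
    g <- geom[[sc$patient_id]]
    analyze_scan(sc, g$center, g$r, n_superpixels = n_superpixels,
                 compactness = compactness, seed = seed,
                 bin_edges = bin_edges, exclude_mask = exclude_mask)
  })
  per_eye <- per_scan |>
    dplyr::group_by(.data$patient_id, .data$eye, .data$irradiated) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(measure_cols),
      ~ average_scans(.x, allow_missing = allow_missing_scans)
    ), .groups = "drop")
  cov <- pats |>
    dplyr::mutate(map_mmHg = mean_arterial_pressure(.data$sbp, .data$dbp))
  per_eye <- per_eye |>
    dplyr::left_join(
      cov[, c("patient_id", "irradiated_eye", "time_from_treatment",
              "map_mmHg", "iop_irradiated", "iop_fellow", "dose_to_disc",
              "distance_to_disc")],
      by = "patient_id"
    ) |>
    dplyr::mutate(
      iop = ifelse(.data$irradiated, .data$iop_irradiated, .data$iop_fellow),
      opp = ocular_perfusion_pressure(.data$map_mmHg, .data$iop)
    ) |>
    dplyr::select(-"iop_irradiated", -"iop_fellow", -"irradiated_eye") |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$irradiated))
  list(per_scan = per_scan, per_eye = per_eye)
}

#' Fit the cohort statistics
#'
#' Runs the full statistical battery on a per-eye measures table: paired
#' two-tailed t-tests (irradiated vs fellow eye) with per-patient
#' difference counts, simple linear regressions of each measure on time
#' from treatment (irradiated and fellow eyes separately), and the Spearman
#' correlation matrix relating the irradiated-eye flow measures to time
#' from treatment, dose to the disc and tumor-to-disc distance.
#'
#' @param per_eye Per-eye measures tibble (see [analyze_cohort()]).
#' @param measures Measure columns to test (default: MV, MT and the five
#'   flow-range percentages).
#' @param alpha Significance level for the Spearman `significant` flag
#'   (default 0.01, the 99% confidence level).
#' @param bonferroni If `TRUE`, additionally report Bonferroni-adjusted
#'   paired-test p-values (`p_adjusted` column). Raw p-values are always
#'   reported.
#' @return An `lsfg_cohort_fit` with tibbles `paired`, `regressions`,
#'   `spearman`, `differences`, and the input `per_eye`.
#' @export
fit_cohort_stats <- function(per_eye,
                             measures = c("mv", "mt", "pct_ge20", "pct_lt5",
                                          "pct_5_10", "pct_10_15",
                                          "pct_15_20"),
                             alpha = 0.01, bonferroni = FALSE) {
  irr <- per_eye[per_eye$irradiated, ] |> dplyr::arrange(.data$patient_id)
  fel <- per_eye[!per_eye$irradiated, ] |> dplyr::arrange(.data$patient_id)
  if (!identical(irr$patient_id, fel$patient_id)) {
    abort("Per-eye table must contain one irradiated and one fellow record per patient.",
          class = "lsfg_misaligned")
  }

  paired <- purrr::map_dfr(measures, function(m) {
    res <- paired_t(irr[[m]], fel[[m]])
    diffs <- paired_differences(irr[[m]], fel[[m]])
    res$measure <- m
    res$n_decreased <- attr(diffs, "n_negative")
    res
  })
  if (bonferroni) {
    paired$p_adjusted <- stats::p.adjust(paired$p_value, method = "bonferroni")
  }

  differences <- purrr::map_dfr(measures, function(m) {
    tibble(measure = m, patient_id = irr$patient_id,
           delta = irr[[m]] - fel[[m]])
  })

  regressions <- purrr::map_dfr(measures, function(m) {
    purrr::map_dfr(list(irr = irr, fellow = fel), function(df) {
      res <- linreg_vs_time(df$time_from_treatment, df[[m]])
      res$measure <- m
      res
    }, .id = "group") |>
      dplyr::mutate(group = ifelse(.data$group == "irr", "irradiated", "fellow"))
  })

  sp_data <- tibble(
    mean_retinal_mv = irr$mv,
    mean_choroidal_mt = irr$mt,
    pct_superpx_ge20 = irr$pct_ge20,
    pct_superpx_lt5 = irr$pct_lt5,
    time_from_treatment = irr$time_from_treatment,
    dose_to_disc = irr$dose_to_disc,
    distance_to_disc = irr$distance_to_disc
  )
  spearman <- spearman_matrix(sp_data, alpha = alpha)

  structure(
    list(paired = paired, differences = differences,
         regressions = regressions, spearman = spearman, per_eye = per_eye,
         measures = measures, alpha = alpha),
    class = "lsfg_cohort_fit"
  )
}

#' @export
print.lsfg_cohort_fit <- function(x, ...) {
  n <- nrow(x$per_eye) / 2
  cat(sprintf("<lsfg_cohort_fit> %d patients, %d measures\n", n,
              length(x$measures)))
  sig <- x$paired$measure[x$paired$p_value < 0.05]
  cat("  paired p < 0.05:", if (length(sig)) paste(sig, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Tidy the fitted cohort statistics
#'
#' @param x An `lsfg_cohort_fit`.
#' @param ... Unused.
#' @return A long tibble with one row per test: `kind`, `measure`, `group`,
#'   `statistic`, `estimate`, `p_value`, `n`, `direction`.
#' @export
tidy.lsfg_cohort_fit <- function(x, ...) {
  paired <- dplyr::mutate(x$paired, group = "irradiated_vs_fellow")
  keep <- c("kind", "measure", "group", "statistic", "estimate", "p_value",
            "n", "direction")
  dplyr::bind_rows(
    paired[, intersect(c(keep, "n_decreased"), names(paired))],
    x$regressions[, intersect(c(keep, "intercept"), names(x$regressions))],
    dplyr::transmute(
      as_tibble(x$spearman)[x$spearman$var1 < x$spearman$var2, ],
      kind = "spearman",
      measure = paste(.data$var1, .data$var2, sep = " ~ "),
      group = "irradiated", statistic = .data$rho, estimate = .data$rho,
      p_value = .data$p_value, n = .data$n,
      direction = as.integer(sign(.data$rho))
    )
  )
}

#' One-row summary of a fitted cohort
#'
#' @param x An `lsfg_cohort_fit`.
#' @param ... Unused.
#' @return A one-row tibble: patient count, number of paired tests with
#'   p < 0.05, and the strongest off-diagonal Spearman correlation with
#'   time from treatment.
#' @export
glance.lsfg_cohort_fit <- function(x, ...) {
  sp <- x$spearman[x$spearman$var1 == "time_from_treatment" &
                     x$spearman$var2 != "time_from_treatment", ]
  top <- sp[which.max(abs(sp$rho)), ]
  tibble(
    n_patients = nrow(x$per_eye) / 2,
    n_paired_sig = sum(x$paired$p_value < 0.05),
    strongest_time_corr_var = top$var2,
    strongest_time_corr_rho = top$rho,
    strongest_time_corr_p = top$p_value
  )
}
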