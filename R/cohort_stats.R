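#' Average the three repeat scans of an eye
#'
#' LSFG protocols take three successive scans per eye; their per-scan
#' measures are averaged into one per-eye value before any statistics.
#'
#' @param x Numeric vector of per-scan measures.
#' @param allow_missing If `TRUE`, accept 1 or 2 finite values with a
#'   warning instead of requiring exactly 3.
#' @return The arithmetic mean.
#' @export
average_scans <- function(x, allow_missing = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) != 3) {
    if (allow_missing && length(x) >= 1) {
      warn(sprintf("Averaging %d scan(s) instead of 3.", length(x)))
    } else {
      abort(sprintf("Expected exactly 3 finite per-scan values, got %d.",
                    length(x)),
            class = "lsfg_bad_average")
    }
  }
  mean(x)
}

new_stat_result <- function(kind, statistic, p_value, n, direction,
                            estimate = NA_real_, ...) {
  tibble(kind = kind, statistic = statistic, estimate = estimate,
         p_value = p_value, n = as.integer(n),
         direction = as.integer(direction), ...)
}

#' Paired two-tailed t-test, irradiated vs fellow eye
#'
#' Tests the within-patient differences `d = irr - fellow` against zero
#' using the paired t statistic `mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom (computed via [stats::t.test()]). If all differences
#' are identical the t statistic is undefined: an all-zero `d` is an error,
#' a nonzero constant `d` is reported with `p = 0`.
#'
#' @param irr,fellow Equal-length numeric vectors aligned by patient
#'   (n >= 3).
#' @return A one-row tibble: `kind`, `statistic` (t), `estimate`
#'   (mean difference), `p_value`, `n`, `direction` (sign of the mean
#'   difference).
#' @export
paired_t <- function(irr, fellow) {
  check_aligned(irr, fellow)
  if (length(irr) < 3) {
    abort("Paired t-test needs n >= 3 pairs.", class = "lsfg_bad_stat")
  }
  d <- irr - fellow
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      abort("All paired differences are exactly zero; t is undefined.",
            class = "lsfg_degenerate_stat")
    }
    return(new_stat_result("paired_t", sign(mean(d)) * Inf, 0,
                           length(d), sign(mean(d)), estimate = mean(d)))
  }
  tt <- t.test(irr, fellow, paired = TRUE, alternative = "two.sided")
  new_stat_result("paired_t", unname(tt$statistic), tt$p.value,
                  length(d), sign(mean(d)), estimate = mean(d))
}

#' Per-patient paired differences
#'
#' @param irr,fellow Equal-length numeric vectors aligned by patient.
#' @param sign_convention `"irradiated_minus_fellow"` (default) or
#'   `"fellow_minus_irradiated"`.
#' @return A tibble with column `delta`; the attribute `n_negative` counts
#'   patients whose delta is < 0 (i.e. decreased flow in the irradiated eye
#'   under the default convention).
#' @export
paired_differences <- function(irr, fellow,
                               sign_convention = c("irradiated_minus_fellow",
                                                   "fellow_minus_irradiated")) {
  check_aligned(irr, fellow)
  sign_convention <- match.arg(sign_convention)
  delta <- if (sign_convention == "irradiated_minus_fellow") irr - fellow
           else fellow - irr
  out <- tibble(delta = delta)
  attr(out, "n_negative") <- sum(delta < 0)
  out
}

check_aligned <- function(irr, fellow) {
  if (length(irr) != length(fellow)) {
    abort("`irr` and `fellow` must be aligned by patient (equal length).",
          class = "lsfg_misaligned")
  }
  if (any(!is.finite(irr)) || any(!is.finite(fellow))) {
    abort("Paired measures must be finite.", class = "lsfg_misaligned")
  }
  invisible(TRUE)
}

#' Simple linear regression of a measure on time from treatment
#'
#' Ordinary least squares `y ~ time`; the slope (per month) is tested
#' against zero with the t-distribution on `n - 2` degrees of freedom
#' (via [stats::lm()]). Degenerate cases are handled explicitly: a constant
#' `y` gives slope 0 with `p = 1`; an exact non-constant linear fit (zero
#' residual variance) is flagged with `p = 0`.
#'
#' @param time Months from treatment (not all equal).
#' @param y Measure values, same length (n >= 3).
#' @return A one-row tibble: `kind`, `statistic` (slope per month),
#'   `estimate` (slope), `p_value`, `n`, `direction`, `intercept`.
#' @export
linreg_vs_time <- function(time, y) {
  if (length(time) != length(y) || length(y) < 3) {
    abort("Need aligned vectors with n >= 3.", class = "lsfg_bad_stat")
  }
  if (var(time) == 0) {
    abort("`time` is constant; the slope is undefined.",
          class = "lsfg_degenerate_stat")
  }
  fit <- lm(y ~ time)
  beta <- unname(coef(fit)[2])
  alpha <- unname(coef(fit)[1])
  rss <- sum(fit$residuals^2)
  if (var(y) == 0) {
    p <- 1; beta <- 0
  } else if (rss < .Machine$double.eps * sum(y^2)) {
    p <- 0 # exact linear relation: zero-residual degenerate case
  } else {
    p <- summary(fit)$coefficients[2, 4]
  }
  new_stat_result("linreg", beta, p, length(y), sign(beta),
                  estimate = beta, intercept = alpha)
}

#' Spearman rank correlation matrix
#'
#' Computes Spearman's rho for every pair of variables as the Pearson
#' correlation of mid-ranks (average ranks on ties) with the two-tailed p
#' from the t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom (via [stats::cor.test()] with
#' `exact = FALSE`). Rows with missing values are dropped pairwise, so
#' covariates missing for some patients (dose, distance) shrink only their
#' own pairs. Pairs with fewer than `min_n` complete observations, or with
#' an all-tied variable, are returned as `NA` with a warning.
#'
#' @param data Data frame of numeric variables (one row per patient or
#'   eye).
#' @param alpha Significance level for the `significant` flag (default
#'   0.01, matching a 99% confidence level).
#' @param min_n Minimum complete observations per pair (default 4).
#' @return An `lsfg_spearman` tibble in long format: `var1`, `var2`, `rho`,
#'   `p_value`, `n`, `significant`; symmetric with a unit diagonal.
#' @export
spearman_matrix <- function(data, alpha = 0.01, min_n = 4) {
  data <- as.data.frame(data)
  stopifnot(all(vapply(data, is.numeric, logical(1))))
  vars <- names(data)
  grid <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  res <- purrr::pmap_dfr(grid, function(var1, var2) {
    x <- data[[var1]]; y <- data[[var2]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (var1 == var2) {
      return(tibble(var1 = var1, var2 = var2, rho = 1, p_value = NA_real_,
                    n = n))
    }
    if (n < min_n) {
      warn(sprintf("Fewer than %d complete pairs for (%s, %s); reporting NA.",
                   min_n, var1, var2))
      return(tibble(var1 = var1, var2 = var2, rho = NA_real_,
                    p_value = NA_real_, n = n))
    }
    if (var(x[ok]) == 0 || var(y[ok]) == 0) {
      warn(sprintf("All-tied variable in pair (%s, %s); rho undefined.",
                   var1, var2))
      return(tibble(var1 = var1, var2 = var2, rho = NA_real_,
                    p_value = NA_real_, n = n))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE,
               alternative = "two.sided")
    )
    tibble(var1 = var1, var2 = var2, rho = unname(ct$estimate),
           p_value = ct$p.value, n = n)
  })
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  attr(res, "alpha") <- alpha
  class(res) <- c("lsfg_spearman", class(res))
  res
}

#' Significance-coded correlation heatmap
#'
#' @param object An `lsfg_spearman` from [spearman_matrix()].
#' @param ... Unused.
#' @return A ggplot object; non-significant cells are blanked.
#' @export
autoplot.lsfg_spearman <- function(object, ...) {
  df <- as_tibble(object)
  df$shown_rho <- ifelse(df$var1 == df$var2 | df$significant, df$rho, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(.data$var1, .data$var2, fill = .data$shown_rho)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$shown_rho), "", sprintf("%.2f", .data$shown_rho))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", limits = c(-1, 1),
                                  na.value = "grey95", name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = sprintf("cells shown where p < %g",
                                     attr(object, "alpha") %||% 0.01)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
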