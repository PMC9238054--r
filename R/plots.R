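#' Pairwise irradiated-vs-fellow plot for one measure
#'
#' @param per_eye Per-eye measures tibble (see [analyze_cohort()]).
#' @param measure Column name, e.g. `"mv"` or `"pct_ge20"`.
#' @return A ggplot object: one line per patient connecting the fellow and
#'   irradiated values.
#' @export
plot_paired <- function(per_eye, measure) {
  df <- per_eye |>
    dplyr::mutate(eye_group = factor(ifelse(.data$irradiated, "irradiated",
                                            "fellow"),
                                     levels = c("irradiated", "fellow")))
  ggplot2::ggplot(df, ggplot2::aes(.data$eye_group, .data[[measure]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$eye_group), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(irradiated = "#6a3d9a",
                                           fellow = "black")) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_classic()
}

#' Per-patient difference bars for one measure
#'
#' @inheritParams plot_paired
#' @param fit An `lsfg_cohort_fit` (uses its `differences` table).
#' @return A ggplot object of `irradiated - fellow` per patient.
#' @export
plot_differences <- function(fit, measure) {
  df <- fit$differences[fit$differences$measure == measure, ]
  df <- df[order(df$delta), ]
  df$patient_id <- factor(df$patient_id, levels = df$patient_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$patient_id, .data$delta,
                                   fill = .data$delta < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#6a3d9a",
                                          `FALSE` = "grey40")) +
    ggplot2::labs(x = "patient", y = sprintf("%s, irradiated - fellow", measure)) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Measure versus time from treatment, with trendlines
#'
#' @inheritParams plot_paired
#' @return A ggplot object: irradiated and fellow eyes with separate OLS
#'   trendlines.
#' @export
plot_flow_vs_time <- function(per_eye, measure) {
  df <- per_eye |>
    dplyr::mutate(eye_group = ifelse(.data$irradiated, "irradiated", "fellow"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_from_treatment,
                                   .data[[measure]], color = .data$eye_group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_color_manual(values = c(irradiated = "#6a3d9a",
                                           fellow = "black"), name = NULL) +
    ggplot2::labs(x = "time from treatment (months)", y = measure) +
    ggplot2::theme_classic()
}

write_pipeline_figures <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_fig <- function(plot, name, width = 5, height = 4) {
    p <- file.path(dir, paste0(name, ".pdf"))
    ggplot2::ggsave(p, plot, width = width, height = height)
    paths <<- c(paths, p)
  }
  for (m in c("mv", "mt", "pct_ge20", "pct_lt5")) {
    save_fig(plot_paired(fit$per_eye, m), paste0("paired_", m))
    save_fig(plot_differences(fit, m), paste0("differences_", m))
    save_fig(plot_flow_vs_time(fit$per_eye, m), paste0("vs_time_", m))
  }
  save_fig(autoplot(fit$spearman), "spearman_heatmap", width = 6, height = 5)
  paths
}
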