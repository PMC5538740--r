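#' Summary plot of standardized effect sizes by period
#'
#' Mean SES (or NRI/NTI via `convention = "webb"`) per metric x period x
#' scope with +/- 2 SE error bars and dashed reference lines at +/- 1.96 —
#' the pooled-islands view of phylogenetic clustering/overdispersion.
#'
#' @param ses_tbl A tibble from [ses_table()].
#' @param convention `"raw"` (SES; clustering negative) or `"webb"`
#'   (NRI/NTI; clustering positive).
#' @return A ggplot object.
#' @export
plot_ses_summary <- function(ses_tbl, convention = c("raw", "webb")) {
  convention <- match.arg(convention)
  col <- if (convention == "raw") "ses" else "webb"
  dat <- ses_tbl |>
    dplyr::filter(!is.na(.data[[col]])) |>
    dplyr::group_by(.data$metric, .data$period, .data$scope) |>
    dplyr::summarise(
      mean = mean(.data[[col]]),
      se = sd(.data[[col]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$period, y = .data$mean, colour = .data$scope
  )) +
    ggplot2::geom_hline(yintercept = c(-1.96, 1.96), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - 2 * .data$se, ymax = .data$mean + 2 * .data$se),
      position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      y = if (convention == "raw") "standardized effect size" else "NRI / NTI",
      x = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a phylogenetic beta-diversity matrix
#'
#' @param object A `beta_matrix` from [spatial_beta()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_matrix <- function(object, ...) {
  long <- tidy(object)
  long <- dplyr::bind_rows(
    long,
    dplyr::rename(long, island_a = "island_b", island_b = "island_a")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$island_a, .data$island_b, fill = .data$beta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "1 - PhyloSor") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Phylogenetic beta diversity (%s, %s)", object$period, object$scope)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Beta diversity against geographic distance
#'
#' Scatter of pairwise `1 - PhyloSor` against log10 great-circle distance
#' with a linear trend, the standard view of phylogenetic distance decay.
#'
#' @param beta A `beta_matrix` (or a list of them, plotted together and
#'   coloured by period).
#' @param islands Island metadata tibble (`island`, `lat`, `lon`) or an
#'   `island_flora` carrying one.
#' @return A ggplot object.
#' @export
plot_beta_distance <- function(beta, islands) {
  if (inherits(beta, "beta_matrix")) beta <- list(beta)
  geo <- island_distance_km(islands)
  dat <- purrr::map_dfr(beta, function(bm) {
    long <- tidy(bm)
    long$distance_km <- geo[cbind(long$island_a, long$island_b)]
    long$period <- bm$period
    long$scope <- bm$scope
    long
  })
  ggplot2::ggplot(dat, ggplot2::aes(
    x = log10(.data$distance_km), y = .data$beta,
    colour = .data$period, linetype = .data$period
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "geographic distance (log10 km)", y = "1 - PhyloSor"
    ) +
    ggplot2::theme_minimal()
}
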