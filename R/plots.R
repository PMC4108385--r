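# ggplot2 views of the main result types.

#' Plot the identity distribution of duplicate pairs
#'
#' Overlaid 5%-bin histograms of alignment identity for all pairs and the
#' species-specific subset (the classic right-shift view), or intra vs inter
#' when `by = "locality"`.
#'
#' @param pairs Classified pairs from [classify_pairs()].
#' @param by `"lineage"` or `"locality"`.
#' @return A ggplot object.
#' @export
plot_identity_distribution <- function(pairs, by = c("lineage", "locality")) {
  by <- match.arg(by)
  df <- if (by == "lineage") {
    dplyr::bind_rows(
      dplyr::mutate(pairs, group = "all"),
      dplyr::mutate(
        pairs[pairs$lineage == "species_specific", ],
        group = "species_specific"
      )
    )
  } else {
    dplyr::mutate(pairs, group = .data$locality)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$identity, fill = .data$group)) +
    ggplot2::geom_histogram(
      breaks = seq(0, 1, by = 0.05), alpha = 0.6, position = "identity"
    ) +
    ggplot2::labs(
      x = "alignment identity", y = "duplicate gene pairs", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dd_binned_trend <- function(object, ...) {
  ggplot2::ggplot(
    object$bins,
    ggplot2::aes(x = .data$mean_dS, y = .data$proportion_divergent)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "mean dS per bin",
      y = "proportion structurally divergent",
      subtitle = sprintf("r = %.2f, p = %.2g", object$estimate, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dd_binned_regression <- function(object, ...) {
  bins <- purrr::imap_dfr(attr(object, "bins"), function(b, label) {
    dplyr::mutate(b, stratum = label)
  })
  ggplot2::ggplot(
    bins, ggplot2::aes(x = .data$mean_x, y = .data$mean_transformed_r)
  ) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~stratum, scales = "free_x") +
    ggplot2::labs(
      x = paste("mean", object$covariate[1], "per bin"),
      y = "mean transformed r per bin"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dd_group_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$groups,
    ggplot2::aes(x = .data$group, y = .data$mean_transformed_r)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "mean transformed r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dd_ancova <- function(object, ...) {
  df <- object$data
  df$class <- ifelse(df$sd, "SD", "NSD")
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$dS, y = .data$transformed_r, colour = .data$class)
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.4) +
    ggplot2::geom_abline(
      data = object$per_class,
      ggplot2::aes(
        intercept = .data$intercept, slope = .data$slope, colour = .data$class
      )
    ) +
    ggplot2::labs(x = "dS", y = "transformed r", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
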