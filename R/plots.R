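#' Plot a fitted dose-response curve
#'
#' Fitted MD-versus-CF curve with its pointwise 95% confidence ribbon,
#' knot positions marked on the axis.
#'
#' @param object An [fit_rcs_model()] result.
#' @param ... Passed to [predict_curve()].
#' @return A ggplot object.
#' @export
autoplot.rcs_fit <- function(object, ...) {
  curve <- predict_curve(object, ...)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$exposure, y = .data$fitted)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(color = "steelblue", linewidth = 0.9) +
    ggplot2::geom_rug(
      data = tibble(k = object$knots),
      ggplot2::aes(x = .data$k), inherit.aes = FALSE, sides = "b"
    ) +
    ggplot2::labs(
      x = object$exposure, y = paste0("predicted ", object$outcome),
      title = "Restricted cubic spline dose-response",
      subtitle = "shaded band: pointwise 95% CI; rug: knots"
    ) +
    ggplot2::theme_minimal()
}

#' Plot bridge-centrality profiles
#'
#' One panel per index, nodes ordered by value, communities coloured.
#'
#' @param object A [bridge_indices()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bridge_indices <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
    cols = dplyr::starts_with("bridge_"),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$value,
      y = stats::reorder(.data$node, .data$value),
      color = .data$community
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, scales = "free_x", nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Bridge centrality") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot centrality-stability bootstrap profiles
#'
#' Mean subsample-to-full-sample correlation (with a 95% quantile band)
#' against the proportion of retained cases, per index; the 0.7 floor used
#' by the CS coefficient is marked.
#'
#' @param object A [case_drop_bootstrap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_result <- function(object, ...) {
  d <- tidy(object)
  d$retained <- 1 - d$fraction
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$retained, y = .data$mean_cor,
    color = .data$index, fill = .data$index
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q025, ymax = .data$q975),
      alpha = 0.15, color = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.7, linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "proportion of cases retained",
      y = "correlation with full-sample index",
      title = "Case-dropping bootstrap stability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot intervention-simulation results
#'
#' Mean MD sum score per scenario against the baseline (dashed line), per
#' direction; significant scenarios are filled.
#'
#' @param object A [compare_to_baseline()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nira_result <- function(object, ...) {
  base <- dplyr::filter(object, .data$scenario == "baseline")
  scen <- dplyr::filter(object, .data$scenario != "baseline")
  ggplot2::ggplot(scen, ggplot2::aes(
    x = stats::reorder(.data$scenario, .data$mean_md),
    y = .data$mean_md
  )) +
    ggplot2::geom_hline(
      data = base, ggplot2::aes(yintercept = .data$mean_md),
      linetype = "dashed"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::facet_wrap(~direction, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "intervened node", y = "mean MD sum score",
      title = "Simulated threshold interventions",
      subtitle = "dashed line: baseline (unperturbed) network"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' Force-directed plot of an estimated symptom network
#'
#' A basic Fruchterman-Reingold layout for reports: edge width scales with
#' |coupling|, colour by sign, node colour by community.
#'
#' @param model An [ising_model()].
#' @param seed Layout seed (layouts are themselves randomized).
#' @return A ggplot object.
#' @export
plot_network <- function(model, seed = 1) {
  g <- igraph_from_omega(model$omega, model$labels)
  lay <- with_seed_if(seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    node = model$labels, x = lay[, 1], y = lay[, 2],
    community = if (is.null(model$partition)) "all" else unname(model$partition)
  )
  el <- tidy(model)
  edges <- dplyr::left_join(
    dplyr::left_join(el, dplyr::select(nodes,
      from = "node", x0 = "x", y0 = "y"
    ), by = "from"),
    dplyr::select(nodes, to = "node", x1 = "x", y1 = "y"),
    by = "to"
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = abs(.data$weight), color = .data$weight > 0
      ),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$community),
      shape = 21, size = 6
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node), size = 2
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative"),
      name = "coupling"
    ) +
    ggplot2::theme_void()
}
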