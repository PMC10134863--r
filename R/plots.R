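#' Plot a proteome pI profile
#'
#' Kernel density of per-protein isoelectric points with the trough
#' breakpoint marked — the visual check that the acidic/basic partition
#' used by the pI-bias statistic falls between the two modes.
#'
#' @param pis Tibble from [proteome_pi()] (or any tibble with `genome_id`
#'   and `pi` columns).
#' @param breakpoints Optional tibble `genome_id`, `breakpoint` (e.g. from
#'   [proteome_traits()]); drawn as dashed vertical lines.
#' @return A ggplot object, facetted by genome.
#' @export
plot_pi_profile <- function(pis, breakpoints = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(pis, !is.na(.data$pi)),
                       ggplot2::aes(x = .data$pi)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$genome_id)) +
    ggplot2::coord_cartesian(xlim = c(0, 14)) +
    ggplot2::labs(x = "isoelectric point (pH units)", y = "density")
  if (!is.null(breakpoints)) {
    p <- p + ggplot2::geom_vline(
      data = breakpoints,
      ggplot2::aes(xintercept = .data$breakpoint),
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Compare a trait across genome groups
#'
#' Fig-3-style box-and-jitter comparison of one trait between genera (or
#' any grouping), optionally annotated with significance letters from
#' [group_compare()].
#'
#' @param trait_table Tibble with `genome_id` and the trait column.
#' @param group_map Tibble `genome_id`, `group`.
#' @param trait Trait column name (string).
#' @param letters Optional tibble `group`, `letters` (from
#'   [group_compare()]`$letters`).
#' @return A ggplot object.
#' @export
plot_trait_groups <- function(trait_table, group_map, trait,
                              letters = NULL) {
  df <- left_join(trait_table, group_map, by = "genome_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                        y = .data[[trait]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = trait)
  if (!is.null(letters)) {
    ymax <- max(df[[trait]], na.rm = TRUE)
    p <- p + ggplot2::geom_text(
      data = letters,
      ggplot2::aes(x = .data$group, y = ymax, label = .data$letters),
      vjust = -0.5, inherit.aes = FALSE
    )
  }
  p
}

#' @describeIn size_cds_regression Scatter of CDS count against genome
#'   size with the fitted line.
#' @param object A `size_cds_fit`.
#' @param ... Ignored.
#' @export
autoplot.size_cds_fit <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_size,
                                   y = .data$n_cds)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "genome size (bp)", y = "CDS count",
      subtitle = sprintf("adjusted R^2 = %.3f, P = %.3g",
                         object$adj_r_squared, object$p_value)
    )
}

#' @describeIn anc_ml Ancestral-state trajectory: node states against
#'   distance from the root with 95% CI bars, tip values overlaid.
#' @param object An `anc_recon`.
#' @param ... Ignored.
#' @export
autoplot.anc_recon <- function(object, ...) {
  depth <- ape::node.depth.edgelength(object$tree)
  ntip <- ape::Ntip(object$tree)
  est <- mutate(object$estimates, depth = depth[.data$node])
  tips <- tibble(
    depth = depth[seq_len(ntip)],
    state = unname(object$traits[object$tree$tip.label])
  )
  ggplot2::ggplot(est, ggplot2::aes(x = .data$depth, y = .data$state)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_point(data = tips, shape = 1) +
    ggplot2::labs(x = "distance from root", y = "trait value",
                  subtitle = "filled: ancestral ML states; open: tips")
}

#' Plot an AAI matrix as a heatmap
#'
#' @param aai Result of [aai_matrix()] (or its `matrix` element).
#' @return A ggplot tile heatmap.
#' @export
plot_aai_matrix <- function(aai) {
  m <- if (is.list(aai) && !is.data.frame(aai)) aai$matrix else aai
  df <- as_tibble(as.data.frame.table(m, responseName = "aai"))
  names(df)[1:2] <- c("genome_a", "genome_b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_a,
                                   y = .data$genome_b,
                                   fill = .data$aai)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "AAI (%)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
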