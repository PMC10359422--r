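# ggplot2 views of the main result types.

#' Plot a Ks distribution with an optional fitted peak model
#'
#' Histogram of Ks (density scale) with the mixture density and component
#' peak positions overlaid when a model is supplied.
#'
#' @param ks_values Numeric vector of Ks values (NAs dropped).
#' @param model Optional [fit_ks_peaks()] result.
#' @param bins Histogram bins (default 60).
#' @return A ggplot object.
#' @export
plot_ks_distribution <- function(ks_values, model = NULL, bins = 60) {
  df <- tibble(ks = ks_values[!is.na(ks_values)])
  if (!is.null(model)) {
    df <- filter(df, .data$ks >= model$ks_range[1],
                 .data$ks <= model$ks_range[2])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80",
                            colour = "grey50", linewidth = 0.2) +
    ggplot2::labs(x = "Ks (synonymous substitutions per synonymous site)",
                  y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    grid <- seq(min(df$ks), max(df$ks), length.out = 400)
    dens <- rowSums(vapply(seq_len(nrow(model$components)), function(i) {
      cm <- model$components[i, ]
      # mixture fitted on log-Ks: back-transform the density
      cm$weight * stats::dnorm(log(grid), cm$mean_log, cm$sd_log) / grid
    }, numeric(length(grid))))
    p <- p +
      ggplot2::geom_line(data = tibble(ks = grid, dens = dens),
                         ggplot2::aes(x = .data$ks, y = .data$dens),
                         colour = "firebrick", linewidth = 0.7) +
      ggplot2::geom_vline(xintercept = model$components$peak_ks,
                          linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname plot_ks_distribution
#' @param object A `ks_peak_model`.
#' @param ks_values The Ks values the model was fitted on.
#' @param ... Passed to [plot_ks_distribution()].
#' @export
autoplot.ks_peak_model <- function(object, ks_values, ...) {
  plot_ks_distribution(ks_values, model = object, ...)
}

#' Synteny dot plot of anchors or blocks
#'
#' Anchor positions in gene-rank coordinates, faceted by chromosome pair,
#' coloured by block (when block output is supplied) or orientation.
#'
#' @param x [find_anchors()] anchors or [chain_anchors()] blocks.
#' @return A ggplot object.
#' @export
plot_synteny_dotplot <- function(x) {
  if ("anchors" %in% names(x) && is.list(x$anchors)) {
    df <- x |>
      select("block_id", "orientation", "anchors") |>
      tidyr::unnest("anchors")
    aes_pt <- ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                           colour = .data$block_id,
                           shape = .data$orientation)
  } else {
    df <- mutate(x, block_id = NA_character_)
    aes_pt <- ggplot2::aes(x = .data$rank_a, y = .data$rank_b)
  }
  ggplot2::ggplot(df, aes_pt) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(chrom_b ~ chrom_a, scales = "free") +
    ggplot2::labs(x = "gene rank (genome a)", y = "gene rank (genome b)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Syntenic depth track with called TRR intervals
#'
#' @param depth [syntenic_depth()] output.
#' @param trrs Optional [call_trrs()] intervals, shaded.
#' @return A ggplot object.
#' @export
plot_depth_track <- function(depth, trrs = NULL) {
  p <- ggplot2::ggplot(depth, ggplot2::aes(x = .data$rank,
                                           y = .data$depth)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "gene rank along reference chromosome",
                  y = "syntenic depth (retained copies)") +
    ggplot2::theme_minimal()
  if (!is.null(trrs) && nrow(trrs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = trrs,
      ggplot2::aes(xmin = .data$start_rank, xmax = .data$end_rank,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25
    )
  }
  p
}
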