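#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA sample scores
#'
#' @param object An `sma_pca` from [pca_scores()].
#' @param metadata Optional sample metadata joined on `sample_id`.
#' @param colour Metadata column to colour by (default `"subtype"`).
#' @param dims Pair of components to plot (default the first two kept).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sma_pca <- function(object, metadata = NULL, colour = "subtype",
                             dims = NULL, ...) {
  if (is.null(dims)) dims <- object$dims[1:2]
  df <- object$scores
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  xv <- paste0("PC", dims[1]); yv <- paste0("PC", dims[2])
  share <- object$explained[match(dims, object$dims)]
  lab <- function(v, s) {
    sprintf("%s (%s)", v, if (is.na(s)) "?" else sprintf("%.1f%%", 100 * s))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[xv]], .data[[yv]]))
  if (!is.null(metadata) && colour %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = lab(xv, share[1]), y = lab(yv, share[2])) +
    ggplot2::theme_minimal()
}

#' Plot per-repeat importance of the consensus proteins
#'
#' Box plots of each consensus protein's mean-decrease-in-Gini importance
#' across the repeated models, ordered by median importance.
#'
#' @param object An `rf_consensus` from [run_consensus()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rf_consensus <- function(object, ...) {
  if (length(object$consensus) == 0) {
    stop("consensus set is empty; nothing to plot")
  }
  df <- purrr::map_dfr(object$repeats, function(r) {
    dplyr::filter(r$importance, .data$protein_id %in% object$consensus)
  })
  ord <- df |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(med = stats::median(.data$importance)) |>
    dplyr::arrange(.data$med)
  df$protein_id <- factor(df$protein_id, levels = ord$protein_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$protein_id)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Mean decrease in Gini impurity", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential table
#'
#' Effect (log2 difference) against -log10 p, coloured by direction for
#' significant proteins (orange = higher at T302 / in responders, blue =
#' lower), matching the sign convention used throughout the package.
#'
#' @param tab A differential tibble from [paired_treatment_test()] or
#'   [responder_contrast()].
#' @param p_column Which p-value drives the y-axis and colouring
#'   (`"p_adjusted"` if present, else `"p_value"`).
#' @return A ggplot.
#' @export
plot_volcano <- function(tab, p_column = NULL) {
  if (is.null(p_column)) {
    p_column <- if ("p_adjusted" %in% names(tab)) "p_adjusted" else "p_value"
  }
  df <- dplyr::mutate(
    tab,
    neglog10p = -log10(.data[[p_column]]),
    status = dplyr::case_when(
      !.data$significant ~ "ns",
      .data$direction == "up" ~ "up",
      TRUE ~ "down"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$effect, .data$neglog10p,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_colour_manual(
      values = c(up = "darkorange2", down = "steelblue3", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 difference",
                  y = bquote(-log[10] ~ .(p_column))) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of an enrichment table
#'
#' Fold enrichment per gene set, point size = hits, colour = FDR; the
#' usual compact over-representation summary.
#'
#' @param tab An enrichment tibble from [enrich()].
#' @param top Number of top sets (by p) to show (default 20).
#' @return A ggplot.
#' @export
plot_enrichment <- function(tab, top = 20) {
  df <- utils::head(dplyr::arrange(tab, .data$p_value), top)
  if (nrow(df) == 0) stop("empty enrichment table")
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(.data$fold_enrichment, .data$set)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$fold_enrichment,
                                       yend = .data$set), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$hits, colour = .data$fdr)) +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "navy") +
    ggplot2::labs(x = "Fold enrichment", y = NULL) +
    ggplot2::theme_minimal()
}
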