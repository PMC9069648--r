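#' Information-content profile of a motif
#'
#' Per-position information content (2 + sum p*log2 p, bits) with the
#' consensus base lettered on each bar — a compact logo substitute.
#'
#' @param x A `pwm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pwm
#' @export
autoplot.pwm <- function(x, ...) {
  ic <- apply(x$probs, 2L, function(p) 2 + sum(p * log2(p)))
  df <- tibble::tibble(
    position = seq_len(x$width),
    ic = ic,
    base = DNA_BASES[apply(x$probs, 2L, which.max)]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ic,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), vjust = -0.3,
                       size = 3) +
    ggplot2::scale_x_continuous(breaks = df$position) +
    ggplot2::labs(title = x$name, x = "position",
                  y = "information content (bits)") +
    ggplot2::ylim(0, 2.2) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Volcano-style overview of discovered motif pairs
#'
#' Support against -log10 corrected p-value, significant pairs highlighted.
#'
#' @param pairs Motif-pair tibble from [correct_pvalues()].
#' @param alpha Significance level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_motif_pairs <- function(pairs, alpha = 0.01) {
  df <- dplyr::mutate(
    pairs,
    mlogp = -log10(pmax(.data$pvalue_corrected, 1e-300)),
    pair = paste0(.data$motif_E, " → ", .data$motif_P)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support_k, y = .data$mlogp,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "supporting EP pairs",
                  y = expression(-log[10] ~ "corrected p"),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Per-fold cross-validation metrics
#'
#' @param object An `ep_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ep_cv
#' @export
autoplot.ep_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, -"fold",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$folds$fold) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "metric (positive class)") +
    ggplot2::theme_minimal()
}
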