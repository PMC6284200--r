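# ggplot2 views of fitted objects and evaluation curves.

#' Plot a dpseq fit
#'
#' `type = "ma"`: log2 fold change against mean expression, DEGs highlighted.
#' `type = "dispersion"`: the gene-wise, trended and final dispersions against
#' the mean, per family.  `type = "mean_variance"`: pooled variance against
#' pooled mean on the log-log scale with the unit (Poisson) line; points below
#' the line are underdispersed.
#'
#' @param object A [dpseq()] fit.
#' @param type One of `"ma"`, `"dispersion"`, `"mean_variance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpseq_fit <- function(object, type = c("ma", "dispersion",
                                                "mean_variance"), ...) {
  type <- match.arg(type)
  res <- object$results
  if (type == "ma") {
    df <- res[is.finite(res$log2fc), ]
    df$mean_expr <- (df$mu_1 + df$mu_2) / 2
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_expr, y = .data$log2fc,
                                     colour = .data$deg)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                              `TRUE` = "firebrick"),
                                   name = "DEG") +
      ggplot2::labs(x = "mean of group means", y = "log2 fold change")
  } else if (type == "dispersion") {
    d <- object$dispersions
    long <- dplyr::bind_rows(
      tibble(mu = d$mu, value = d$genewise, stage = "genewise", family = d$family),
      tibble(mu = d$mu, value = d$common, stage = "trend", family = d$family),
      tibble(mu = d$mu, value = d$final, stage = "final", family = d$family)
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$value,
                                       colour = .data$stage)) +
      ggplot2::geom_point(size = 0.5, alpha = 0.5) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::facet_wrap(~family, scales = "free_y") +
      ggplot2::labs(x = "pooled mean", y = "dispersion")
  } else {
    d <- object$dispersions[!duplicated(object$dispersions$gene), ]
    df <- tibble(mu = d$mu, sigma2 = pmax(d$sigma2, 1e-8),
                 class = ifelse(d$sigma2 < d$mu, "underdispersed",
                                "non-underdispersed"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$sigma2,
                                     colour = .data$class)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "pooled mean", y = "pooled variance", colour = NULL)
  }
}

#' Plot a ROC curve
#'
#' @param object A [roc_auc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpseq_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' Plot a precision-recall curve
#'
#' @param object A [pr_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dpseq_prc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall,
                                             y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "recall", y = "precision")
}
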