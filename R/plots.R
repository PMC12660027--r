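#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_tile
#'   geom_histogram geom_vline labs theme_minimal scale_fill_gradient
#'   facet_wrap
#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot

#' Plot posterior density estimates from a fit
#'
#' Pointwise posterior mean density with its quantile band for the subject
#' true score and, where present, the rater bias (or one-way error).
#'
#' @param object a `raterfit`
#' @param targets which densities to draw; defaults to all available
#' @param ... passed to [density_grid()]
#' @return a ggplot object
#' @export
autoplot.raterfit <- function(object,
                              targets = NULL, ...) {
  if (is.null(targets)) {
    targets <- if (object$cfg$design == "one_way") c("theta", "error")
    else c("theta", "b")
  }
  df <- purrr::map_dfr(targets, function(tg) {
    g <- density_grid(object, target = tg, ...)
    g$target <- tg
    g
  })
  ggplot(df, aes(x = .data$x)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey80") +
    geom_line(aes(y = .data$mean)) +
    facet_wrap(~target, scales = "free") +
    labs(x = NULL, y = "posterior density") +
    theme_minimal()
}

#' Plot a posterior ICC distribution
#'
#' @param object an `icc_report` from [posterior_icc()]
#' @param bins histogram bins
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.icc_report <- function(object, bins = 40, ...) {
  ggplot(data.frame(icc = object$values), aes(x = .data$icc)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$mean) +
    geom_vline(xintercept = c(object$conf.low, object$conf.high),
               linetype = 2) +
    labs(x = sprintf("ICC (%s)", object$flavor), y = "draws") +
    theme_minimal()
}

#' Heatmap of a posterior similarity matrix
#'
#' Items are ordered by the point-estimate partition so co-clustered blocks
#' appear along the diagonal.
#'
#' @param object a `cluster_estimate` from [cluster_estimate()]
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.cluster_estimate <- function(object, ...) {
  ord <- order(object$partition)
  P <- object$psm[ord, ord]
  df <- expand.grid(i = seq_len(nrow(P)), j = seq_len(ncol(P)))
  df$p <- as.vector(P)
  ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$p)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "grey10", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "P(co-cluster)") +
    theme_minimal()
}
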