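# Minimal trajectory plots mirroring the usual presentation of these
# experiments: one panel row per census size, statistics against years since
# isolation, lifespans as coloured lines.

#' Plot replicate-mean trajectories from a grid result
#'
#' @param res a `grid_result`.
#' @param statistic one of `"he_source"`, `"he_isolated"`, `"theta"`,
#'   `"dapc_misassignment"`, or `"detection_frequency"`.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(res, statistic = "theta") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
  stopifnot(inherits(res, "grid_result"))
  d <- if (statistic == "detection_frequency") {
    if (is.null(res$detection) || !nrow(res$detection))
      stop("no clustering results in this grid run")
    transform(res$detection, mean = detection_frequency)
  } else res$summary[res$summary$statistic == statistic, ]
  ggplot2::ggplot(d, ggplot2::aes(x = year, y = mean,
                                  colour = factor(max_age))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~n_isolated, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "years since isolation", y = statistic,
                  colour = "max age") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("year", "max_age", "n_isolated",
                         "detection_frequency"))
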