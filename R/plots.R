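# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_hline geom_vline
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot the fragment-length distribution
#'
#' Histogram of sequenced fragment lengths with the target size window
#' marked.
#'
#' @param object A `rad_fraglen` object from
#'   [fragment_length_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rad_fraglen <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$length, y = .data$n)) +
    geom_col(width = 1, fill = "grey35") +
    geom_vline(xintercept = object$window + c(-0.5, 0.5),
               linetype = "dashed", colour = "firebrick") +
    labs(x = "fragment length (bp)", y = "read pairs",
         title = sprintf("%.1f%% of pairs within %d-%d bp",
                         100 * object$fraction_in_window,
                         object$window[[1]], object$window[[2]])) +
    theme_minimal()
}

#' Plot per-sample read balance of a pool
#'
#' Per-sample read-pair fractions with the expected equimolar share
#' (`1 / pool size`) marked.
#'
#' @param object A `rad_demux` object from [demultiplex()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rad_demux <- function(object, ...) {
  ggplot(object$report, aes(x = .data$sample_id, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = expected_sample_share(nrow(object$report)),
               linetype = "dashed", colour = "firebrick") +
    labs(x = NULL, y = "fraction of read pairs") +
    theme_minimal()
}

#' Plot observed versus expected genotype-class frequencies
#'
#' Mean observed class frequencies across markers next to the model's
#' expected frequencies.
#'
#' @param object A `rad_segscan` object from [segregation_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rad_segscan <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    class = factor(rep(c("homP1", "het", "homP2"), 2),
                   levels = c("homP1", "het", "homP2")),
    source = rep(c("observed", "expected"), each = 3),
    frequency = c(g$mean_homP1, g$mean_het, g$mean_homP2,
                  unname(object$expected))
  )
  ggplot(df, aes(x = .data$class, y = .data$frequency, fill = .data$source)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "genotype-class frequency") +
    theme_minimal()
}
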