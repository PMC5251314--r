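#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs scale_x_log10 scale_y_log10 facet_wrap
NULL

#' Plot an LD decay curve
#'
#' @param object An [summarize_ld()] result.
#' @param ... Unused.
#' @return A ggplot: mean r-squared per distance bin against bin midpoint.
#' @export
autoplot.ld_summary <- function(object, ...) {
  df <- dplyr::mutate(object$bins, mid = (bin_lo + bin_hi) / 2)
  ggplot(df, aes(x = mid, y = mean_r2)) +
    geom_point(alpha = 0.5) +
    geom_line(alpha = 0.5) +
    labs(x = "Distance (Mbp)", y = expression(mean ~ r^2),
         title = "LD decay")
}

#' Plot an effective population size trajectory
#'
#' @param object An [estimate_ne()] result.
#' @param ... Unused.
#' @return A ggplot of Ne against generations ago (log-log).
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = generations_ago, y = ne)) +
    geom_line() + geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "Generations ago (T = 1/2c)", y = "Effective population size",
         title = "LD-based Ne trajectory")
}

#' Plot principal component scores
#'
#' @param object A [principal_components()] result.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 coloured by population.
#' @export
autoplot.grm_pca <- function(object, ...) {
  vf <- object$variance_fraction
  ggplot(object$scores, aes(x = PC1, y = PC2, colour = population)) +
    geom_point() +
    labs(x = sprintf("PC1 (%.2f%%)", 100 * vf[1]),
         y = sprintf("PC2 (%.2f%%)", 100 * vf[2]),
         title = "GRM principal components")
}

#' Plot phase persistence against distance
#'
#' @param object A [phase_persistence()] result.
#' @param ... Unused.
#' @return A ggplot of the bin-wise correlation of signed phase r.
#' @export
autoplot.phase_persistence <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      mid = (bin_lo + bin_hi) / 2)
  ggplot(df, aes(x = mid, y = r)) +
    geom_line() + geom_point() +
    labs(x = "Distance (Mbp)", y = "Correlation of phase (r)",
         title = "Persistence of gametic phase")
}

#' Plot the ROH segment-length histogram
#'
#' @param object A [summarize_roh()] result.
#' @param ... Unused.
#' @return A ggplot of segment counts per length bin, faceted by
#'   population.
#' @export
autoplot.roh_summary <- function(object, ...) {
  df <- dplyr::mutate(object$histogram,
                      bin = sprintf("%g-%g", bin_lo_kb / 1000,
                                    bin_hi_kb / 1000))
  ggplot(df, aes(x = bin, y = n_segments)) +
    geom_col() +
    facet_wrap(~population) +
    labs(x = "Segment length (Mb)", y = "Number of ROH segments",
         title = "Runs of homozygosity by length")
}
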