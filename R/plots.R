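#' @importFrom ggplot2 ggplot aes geom_raster geom_col geom_line geom_point
#'   geom_text scale_fill_gradient scale_fill_manual facet_wrap labs
#'   theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Heatmap of a contact matrix
#'
#' @param object A `cm_contacts` object.
#' @param chrom Chromosome to draw (default: the first).
#' @param log Log10-transform counts (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cm_contacts <- function(object, chrom = NULL, log = TRUE, ...) {
  g <- bins_genome(object$bins)
  chrom <- chrom %||% g$chrom[1]
  m <- object$mats[[chrom]]
  d <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  d$count <- as.vector(t(m))
  if (log) d$count <- log10(d$count + 1)
  ggplot(d, aes(i, j, fill = count)) +
    geom_raster() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        na.value = "grey80") +
    labs(x = NULL, y = NULL, title = chrom,
         fill = if (log) "log10(n+1)" else "n") +
    theme_minimal()
}

#' Bar-track of a compartment eigenvector
#'
#' @param track A `cm_compartments` track.
#' @return A ggplot faceted by chromosome, A bins above zero in red and B
#'   bins below in blue.
#' @export
plot_compartments <- function(track) {
  d <- track[!is.na(track$pc1), , drop = FALSE]
  ggplot(d, aes(x = (start + end) / 2e6, y = pc1, fill = label)) +
    geom_col(width = (d$end - d$start) / 1e6) +
    scale_fill_manual(values = c(A = "#c23b22", B = "#3b6fc2"),
                      na.value = "grey60") +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (Mb)", y = "PC1") +
    theme_minimal()
}

#' Line plot of a TAD insulation score with optional boundaries
#'
#' @param track A [tad_score()] track.
#' @param boundaries Optional [find_boundaries()] table.
#' @return A ggplot faceted by chromosome.
#' @export
plot_insulation <- function(track, boundaries = NULL) {
  p <- ggplot(track[!is.na(track$value), ],
              aes((start + end) / 2e6, value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (Mb)", y = "TAD separation score") +
    theme_minimal()
  if (!is.null(boundaries) && nrow(boundaries) > 0) {
    p <- p + geom_point(data = boundaries,
                        aes(pos / 1e6, score), colour = "firebrick",
                        size = 1)
  }
  p
}

#' Stage profile lines for switching compartments
#'
#' @param profile A [stage_profiles()] table.
#' @return A ggplot with one panel per metric across stages.
#' @export
plot_stage_profile <- function(profile) {
  d <- tidyr::pivot_longer(profile, -stage, names_to = "metric")
  d$stage <- factor(d$stage, levels = unique(profile$stage))
  ggplot(d, aes(stage, value, group = metric)) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Scatter plot of a sample embedding
#'
#' @param object A [sample_pca()] result.
#' @param ... Unused.
#' @return A ggplot with labelled samples.
#' @export
autoplot.cm_embedding <- function(object, ...) {
  ve <- attr(object, "var_explained")
  ggplot(as_tibble(unclass(object)), aes(PC1, PC2, label = sample)) +
    geom_point() +
    geom_text(vjust = -0.8, size = 3) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * ve[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * ve[2])) +
    theme_minimal()
}
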