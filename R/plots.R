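#' Plot mean ROH coverage per length class and population
#'
#' Bar chart of the mean per-individual summed ROH length (Mb) in each
#' length class, grouped by population.
#'
#' @param roh A `roh_set` from [detect_roh()].
#' @param ... Passed to [roh_class_coverage()].
#' @return A ggplot object.
#' @export
plot_roh_class_coverage <- function(roh, ...) {
  cov <- roh_class_coverage(roh, ...)
  ggplot2::ggplot(cov, ggplot2::aes(x = .data$class, y = .data$mean_mb,
                                    fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "ROH length class (Mb)",
                  y = "Mean sum of ROH (Mb)", fill = "Population") +
    ggplot2::theme_minimal()
}

#' Plot per-individual ROH count against total ROH length
#'
#' @param roh A `roh_set` from [detect_roh()].
#' @return A ggplot object.
#' @export
plot_roh_totals <- function(roh) {
  tot <- roh_individual_totals(roh)
  ggplot2::ggplot(tot, ggplot2::aes(x = .data$total_length_mb,
                                    y = .data$n_segments,
                                    colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Total length of ROH (Mb)", y = "Number of ROH",
                  colour = "Population") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of per-SNP ROH incidence
#'
#' @param incidence Track from [roh_incidence()].
#' @param threshold Optional horizontal threshold line (e.g. from
#'   [incidence_threshold()]).
#' @return A ggplot object.
#' @export
plot_incidence <- function(incidence, threshold = NULL) {
  tr <- tibble::as_tibble(incidence)
  chroms <- unique(tr$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) {
    max(tr$pos_bp[tr$chrom == ch])
  }, numeric(1))))
  tr$gpos <- tr$pos_bp + offs[match(tr$chrom, chroms)]
  tr$band <- factor(match(tr$chrom, chroms) %% 2)
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$gpos / 1e6,
                                        y = .data$incidence,
                                        colour = .data$band)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "Genome position (Mb)",
                  y = "Fraction of individuals in ROH") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Scatter plot of an IBS MDS embedding
#'
#' @param object An `ibs_mds` object from [mds_ibs()].
#' @param dims Pair of dimensions to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ibs_mds
#' @export
autoplot.ibs_mds <- function(object, dims = c(1, 2), ...) {
  pts <- object$points
  xs <- paste0("C", dims[1]); ys <- paste0("C", dims[2])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data[[xs]], y = .data[[ys]],
                                    colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = xs, y = ys, colour = "Population") +
    ggplot2::theme_minimal()
}
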