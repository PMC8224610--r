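#' Per-SNP ROH incidence across the meta-population
#'
#' For every marker, the fraction of individuals carrying at least one ROH
#' that covers the marker position. Computed on the pooled meta-population:
#' the denominator is the full post-QC cohort, not the per-population
#' counts.
#'
#' @param roh A `roh_set` (or segment tibble with `sample_id`, `chrom`,
#'   `start_bp`, `end_bp`).
#' @param map Marker map tibble, sorted.
#' @param n_individuals Cohort size for the denominator; default: number of
#'   rows of the sample table attached to `roh`.
#' @return Tibble of class `roh_incidence`: `chrom`, `marker_id`, `pos_bp`,
#'   `incidence`.
#' @export
roh_incidence <- function(roh, map, n_individuals = NULL) {
  if (is.null(n_individuals)) {
    n_individuals <- nrow(roh_samples(roh))
  }
  stopifnot(n_individuals >= 1)
  validate_map_sorted(map)
  counts <- numeric(nrow(map))
  seg <- tibble::as_tibble(roh)
  # segments of one individual are disjoint per chromosome, so summing
  # per-segment marker cover counts each individual at most once per SNP
  for (ch in unique(seg$chrom)) {
    sel <- which(map$chrom == ch)
    if (length(sel) == 0) next
    pos <- map$pos_bp[sel]
    s <- seg[seg$chrom == ch, ]
    # first marker index >= start, last marker index <= end
    lo <- findInterval(s$start_bp - 1, pos) + 1L
    hi <- findInterval(s$end_bp, pos)
    keep <- lo <= hi
    lo <- lo[keep]; hi <- hi[keep]
    if (length(lo) == 0) next
    delta <- numeric(length(pos) + 1L)
    add <- tabulate(lo, nbins = length(pos))
    sub <- tabulate(hi + 1L, nbins = length(pos) + 1L)
    delta[seq_along(pos)] <- add
    delta <- delta - sub
    counts[sel] <- counts[sel] + cumsum(delta)[seq_along(pos)]
  }
  out <- tibble::tibble(chrom = map$chrom, marker_id = map$marker_id,
                        pos_bp = map$pos_bp,
                        incidence = counts / n_individuals)
  class(out) <- c("roh_incidence", class(out))
  attr(out, "n_individuals") <- n_individuals
  out
}

#' Percentile threshold of the incidence distribution
#'
#' The 99.9th percentile (by default) of the per-SNP ROH incidence values,
#' computed with the linear-interpolation percentile definition
#' (`stats::quantile` type 7). SNPs at or above the threshold are island
#' candidates.
#'
#' @param incidence An incidence track from [roh_incidence()] (or a numeric
#'   vector of incidences).
#' @param q Percentile level in (0, 1], default 0.999.
#' @return The threshold as a single number.
#' @export
incidence_threshold <- function(incidence, q = 0.999) {
  x <- if (is.data.frame(incidence)) incidence$incidence else incidence
  stopifnot(length(x) > 0, q > 0, q <= 1)
  unname(quantile(x, probs = q, type = 7, names = FALSE))
}

#' Call ROH islands from an incidence track
#'
#' Maximal runs of consecutive at-or-above-threshold SNPs on one chromosome
#' become islands when they contain at least `min_consecutive` SNPs. Island
#' start/end are the positions of the first/last SNP of the run, and the
#' reported length is `(end - start) / 1e6` Mb rounded to 2 decimals, the
#' convention used for printed island tables.
#'
#' @param incidence Incidence track from [roh_incidence()].
#' @param threshold Fixed threshold; default `NULL` derives it from the
#'   track via [incidence_threshold()] at level `q`.
#' @param q Percentile level when `threshold` is derived.
#' @param min_consecutive Minimum number of consecutive qualifying SNPs.
#' @return Tibble of class `roh_islands`: `chrom`, `start_bp`, `end_bp`,
#'   `n_snps_above`, `peak_incidence`, `length_mb`; the threshold used is
#'   attached as attribute `"threshold"`.
#' @export
call_roh_islands <- function(incidence, threshold = NULL, q = 0.999,
                             min_consecutive = 2) {
  if (is.null(threshold)) threshold <- incidence_threshold(incidence, q)
  res <- list()
  for (ch in unique(incidence$chrom)) {
    tr <- incidence[incidence$chrom == ch, ]
    above <- tr$incidence >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_consecutive
    if (!any(keep)) next
    res[[ch]] <- tibble::tibble(
      chrom = ch,
      start_bp = tr$pos_bp[starts[keep]],
      end_bp = tr$pos_bp[ends[keep]],
      n_snps_above = r$lengths[keep],
      peak_incidence = vapply(which(keep), function(k) {
        max(tr$incidence[starts[k]:ends[k]])
      }, numeric(1))
    )
  }
  out <- if (length(res) == 0) {
    tibble::tibble(chrom = character(), start_bp = integer(),
                   end_bp = integer(), n_snps_above = integer(),
                   peak_incidence = numeric())
  } else {
    dplyr::bind_rows(res)
  }
  out$length_mb <- round((out$end_bp - out$start_bp) / 1e6, 2)
  attr(out, "threshold") <- threshold
  class(out) <- c("roh_islands", class(out))
  out
}

#' Annotate ROH islands with overlapping genes
#'
#' Attaches, per island, the names of annotation intervals overlapping the
#' island by at least one bp (both in 1-based inclusive coordinates; an
#' interval starting at `end_bp + 1` does not overlap). Names are ordered
#' by interval start position.
#'
#' @param islands Island tibble from [call_roh_islands()].
#' @param annotation Tibble of named intervals (`chrom`, `start_bp`,
#'   `end_bp`, `name`), e.g. from [read_gene_annotation()].
#' @return `islands` with a `genes` list-column and a comma-separated
#'   `genes_chr` convenience column.
#' @export
annotate_islands <- function(islands, annotation) {
  stopifnot(all(c("chrom", "start_bp", "end_bp", "name") %in%
                  names(annotation)))
  genes <- vector("list", nrow(islands))
  for (k in seq_len(nrow(islands))) {
    hit <- annotation$chrom == islands$chrom[k] &
      annotation$start_bp <= islands$end_bp[k] &
      annotation$end_bp >= islands$start_bp[k]
    g <- annotation[hit, ]
    genes[[k]] <- g$name[order(g$start_bp)]
  }
  islands$genes <- genes
  islands$genes_chr <- vapply(genes, paste, character(1), collapse = ",")
  islands
}
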