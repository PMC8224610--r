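#' Drop non-autosomal and unplaced markers
#'
#' Keeps markers whose chromosome label is a recognized autosome and whose
#' position is known (> 0). Sex chromosomes (labels such as "X", "Y") and
#' markers with unknown position are discarded.
#'
#' @param data A [geno_data()] object.
#' @param autosomes Character vector of chromosome labels to keep. Default:
#'   every purely numeric label present in the map.
#' @return A list with `data` (filtered) and `n_removed`.
#' @export
filter_nonautosomal <- function(data, autosomes = NULL) {
  stopifnot(inherits(data, "geno_data"))
  if (is.null(autosomes)) {
    autosomes <- grep("^[0-9]+$", unique(data$map$chrom), value = TRUE)
  }
  keep <- data$map$chrom %in% autosomes &
    !is.na(data$map$pos_bp) & data$map$pos_bp > 0
  list(data = data[, keep], n_removed = sum(!keep))
}

#' Filter markers on minor allele frequency and call rate
#'
#' MAF is computed from non-missing genotypes as `min(p, 1 - p)` of the
#' alternate-allele frequency. Markers with MAF at or below `maf_cut` are
#' removed, then markers with call rate at or below `callrate_cut`;
#' the boundary is removed in both cases, and each marker is attributed to
#' the first rule it fails. A marker with zero non-missing calls has no
#' defined MAF and falls to the call-rate rule.
#'
#' @param data A [geno_data()] object.
#' @param maf_cut Remove markers with MAF <= this value (default 0.02).
#' @param callrate_cut Remove markers with call rate <= this value
#'   (default 0.98).
#' @return A list with `data` (filtered), `n_removed_maf` and
#'   `n_removed_callrate`.
#' @export
filter_markers <- function(data, maf_cut = 0.02, callrate_cut = 0.98) {
  stopifnot(inherits(data, "geno_data"))
  g <- data$geno
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)  # NaN when n_called == 0
  maf <- pmin(p, 1 - p)
  callrate <- n_called / nrow(g)
  fail_maf <- !is.na(maf) & maf <= maf_cut
  fail_cr <- callrate <= callrate_cut
  list(data = data[, !(fail_maf | fail_cr)],
       n_removed_maf = sum(fail_maf),
       n_removed_callrate = sum(fail_cr & !fail_maf))
}

#' Filter samples on genotype missingness
#'
#' Individuals with strictly more than `max_missing` of their genotypes
#' missing are discarded; the boundary is kept. Intended to run after the
#' marker filters so missingness is judged on the retained marker panel.
#'
#' @param data A [geno_data()] object.
#' @param max_missing Maximum tolerated missing fraction (default 0.05).
#' @return A list with `data` (filtered) and `n_removed`.
#' @export
filter_samples <- function(data, max_missing = 0.05) {
  stopifnot(inherits(data, "geno_data"))
  miss <- rowMeans(is.na(data$geno))
  keep <- miss <= max_missing
  list(data = data[keep, ], n_removed = sum(!keep))
}

#' Run the full quality-control cascade
#'
#' Applies, in order: removal of non-autosomal / unplaced markers, the MAF
#' filter, the call-rate filter, then the sample-missingness filter. Marker
#' statistics are computed on the pre-sample-filter cohort and are not
#' recomputed after samples are dropped.
#'
#' @param data A [geno_data()] object.
#' @param maf_cut,callrate_cut,max_missing Thresholds, see
#'   [filter_markers()] and [filter_samples()].
#' @param autosomes Autosome labels, see [filter_nonautosomal()].
#' @return The filtered `geno_data`, with the attrition report attached as
#'   attribute `"qc_report"` (retrieve it with [qc_report()]).
#' @export
#' @examples
#' sim <- simulate_goat_cohort(sim_config(n_markers = 600, n_chromosomes = 3,
#'                             pop_sizes = c(A = 5, B = 5)), seed = 1)
#' qcd <- run_qc(sim$data)
#' qc_report(qcd)
run_qc <- function(data, maf_cut = 0.02, callrate_cut = 0.98,
                   max_missing = 0.05, autosomes = NULL) {
  n_markers_in <- ncol(data$geno)
  n_samples_in <- nrow(data$geno)
  st1 <- filter_nonautosomal(data, autosomes)
  st2 <- filter_markers(st1$data, maf_cut, callrate_cut)
  st3 <- filter_samples(st2$data, max_missing)
  out <- st3$data
  report <- structure(list(
    n_markers_in = n_markers_in,
    n_removed_nonautosomal = st1$n_removed,
    n_removed_maf = st2$n_removed_maf,
    n_removed_callrate = st2$n_removed_callrate,
    n_markers_out = ncol(out$geno),
    n_samples_in = n_samples_in,
    n_removed_missingness = st3$n_removed,
    n_samples_out = nrow(out$geno),
    thresholds = list(maf = maf_cut, callrate = callrate_cut,
                      max_missing = max_missing)
  ), class = "qc_report")
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [run_qc()]
#'
#' @param data A `geno_data` returned by [run_qc()].
#' @return A `qc_report` object.
#' @export
qc_report <- function(data) {
  rep <- attr(data, "qc_report")
  if (is.null(rep)) abort("no qc_report attached; run run_qc() first")
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality control report\n")
  cat(sprintf("  markers: %d in, %d non-autosomal/unplaced, %d MAF <= %.3g, %d call rate <= %.3g, %d retained\n",
              x$n_markers_in, x$n_removed_nonautosomal, x$n_removed_maf,
              x$thresholds$maf, x$n_removed_callrate, x$thresholds$callrate,
              x$n_markers_out))
  cat(sprintf("  samples: %d in, %d with > %.1f%% missing removed, %d retained\n",
              x$n_samples_in, x$n_removed_missingness,
              100 * x$thresholds$max_missing, x$n_samples_out))
  invisible(x)
}

#' Tidy a QC report into a step-by-step attrition table
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return Tibble with one row per filtering step.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  tibble::tibble(
    unit = c("marker", "marker", "marker", "sample"),
    step = c("non_autosomal", "maf", "callrate", "missingness"),
    removed = c(x$n_removed_nonautosomal, x$n_removed_maf,
                x$n_removed_callrate, x$n_removed_missingness)
  )
}

#' Serialize a QC report to JSON
#'
#' @param x A `qc_report`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_qc_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(x)
}
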