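# evenly spaced single-chromosome map
make_map <- function(n, spacing_bp = 1e5, chrom = "1", start = 1e6) {
  tibble::tibble(chrom = chrom,
                 marker_id = sprintf("m%s_%d", chrom, seq_len(n)),
                 pos_bp = as.integer(start + (seq_len(n) - 1) * spacing_bp))
}

toy_geno <- function(geno, map = NULL, populations = NULL) {
  n <- nrow(geno)
  if (is.null(map)) map <- make_map(ncol(geno))
  if (is.null(populations)) populations <- rep("POP", n)
  geno_data(geno, map,
            data.frame(sample_id = sprintf("s%d", seq_len(n)),
                       population = populations))
}

# build a roh_set directly from per-individual segment lengths (Mb);
# segments laid head-to-tail with 1 Mb spacers so they never overlap
make_roh_set <- function(lengths_by_sample, populations,
                         params = rohscan::roh_params()) {
  samples <- tibble::tibble(sample_id = names(lengths_by_sample),
                            population = populations)
  rows <- list()
  for (id in names(lengths_by_sample)) {
    lens <- lengths_by_sample[[id]]
    if (length(lens) == 0) next
    len_bp <- round(lens * 1e6)
    start <- cumsum(c(1, head(len_bp, -1) + 1e6))
    rows[[id]] <- tibble::tibble(
      sample_id = id,
      population = populations[match(id, names(lengths_by_sample))],
      chrom = "1",
      start_bp = start,
      end_bp = start + len_bp - 1,
      start_idx = NA_integer_, end_idx = NA_integer_,
      n_snps = pmax(20L, as.integer(len_bp / 1e5)),
      n_het = 0L, n_missing = 0L,
      length_bp = len_bp,
      length_mb = len_bp / 1e6
    )
  }
  empty <- tibble::tibble(
    sample_id = character(), population = character(), chrom = character(),
    start_bp = numeric(), end_bp = numeric(), start_idx = integer(),
    end_idx = integer(), n_snps = integer(), n_het = integer(),
    n_missing = integer(), length_bp = numeric(), length_mb = numeric())
  rohscan:::as_roh_set(dplyr::bind_rows(c(list(empty), unname(rows))),
                       samples, params)
}

# mean silhouette of a 1-d embedding given two group labels
silhouette_1d <- function(x, labels) {
  stopifnot(length(unique(labels)) == 2)
  s <- vapply(seq_along(x), function(i) {
    own <- labels == labels[i]
    a <- mean(abs(x[i] - x[own & seq_along(x) != i]))
    b <- mean(abs(x[i] - x[!own]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
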