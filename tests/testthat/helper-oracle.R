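# Brute-force ROH oracle: enumerate every SNP interval, keep the valid
# ones, drop intervals contained in another valid interval, then apply the
# same longest-first greedy disjoint selection the caller specifies.
# Independent of the package's scanning algorithm (O(n^2) enumeration).
oracle_roh <- function(g, pos, p) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  ch <- cumsum(het); cm <- cumsum(mis)
  min_len <- p$min_length_mb * 1e6
  dens_bp <- p$min_density_kb_per_snp * 1e3
  max_gap <- p$max_gap_kb * 1e3
  gap_bad <- c(diff(pos) > max_gap, FALSE)
  # last index reachable from i without an oversized gap
  reach <- integer(n)
  r <- n
  for (i in n:1) {
    if (i < n && gap_bad[i]) r <- i
    reach[i] <- r
  }
  vi <- integer(0); vj <- integer(0)
  for (i in seq_len(n)) {
    if (!hom[i]) next
    js <- i:reach[i]
    js <- js[hom[js]]
    nh <- ch[js] - ch[i] + het[i]
    nm <- cm[js] - cm[i] + mis[i]
    nn <- js - i + 1L
    sp <- pos[js] - pos[i] + 1
    ok <- nh <= p$max_het & nm <= p$max_missing & nn >= p$min_snps &
      sp >= min_len & nn * dens_bp >= sp
    vi <- c(vi, rep(i, sum(ok))); vj <- c(vj, js[ok])
  }
  if (length(vi) == 0) return(cbind(i = integer(0), j = integer(0)))
  contained <- vapply(seq_along(vi), function(k) {
    any(vi <= vi[k] & vj >= vj[k] & !(vi == vi[k] & vj == vj[k]))
  }, logical(1))
  vi <- vi[!contained]; vj <- vj[!contained]
  # longest-first greedy, ties leftmost
  span <- pos[vj] - pos[vi] + 1
  o <- order(-span, vi)
  vi <- vi[o]; vj <- vj[o]
  si <- integer(0); sj <- integer(0)
  for (k in seq_along(vi)) {
    if (!any(vi[k] <= sj & vj[k] >= si)) {
      si <- c(si, vi[k]); sj <- c(sj, vj[k])
    }
  }
  o <- order(si)
  cbind(i = si[o], j = sj[o])
}

# random single-chromosome instance designed to exercise every constraint
random_roh_instance <- function(n_max = 300) {
  n <- sample(30:n_max, 1)
  gaps <- round(rexp(n - 1, rate = 1 / 1.1e5)) + 1
  pos <- as.integer(cumsum(c(sample(1e4, 1), gaps)))
  g <- sample(c(0L, 1L, 2L, NA_integer_), n, replace = TRUE,
              prob = c(0.46, 0.06, 0.46, 0.02))
  list(g = g, pos = pos)
}

random_roh_params <- function() {
  roh_params(
    min_length_mb = sample(c(0.5, 1, 2), 1),
    min_snps = sample(c(5, 10, 20), 1),
    max_het = sample(0:2, 1),
    max_missing = sample(0:2, 1),
    min_density_kb_per_snp = sample(c(60, 100, 200), 1),
    max_gap_kb = sample(c(250, 500, 1000), 1)
  )
}

# O(segments x SNPs) incidence oracle
oracle_incidence <- function(roh, map, n_individuals) {
  sapply(seq_len(nrow(map)), function(j) {
    covered <- unique(roh$sample_id[
      roh$chrom == map$chrom[j] &
        roh$start_bp <= map$pos_bp[j] &
        roh$end_bp >= map$pos_bp[j]])
    length(covered) / n_individuals
  })
}
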