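#' ROH calling parameters
#'
#' Constraint set for run-of-homozygosity detection. Defaults are the
#' standard medium-density SNP-array settings for livestock: runs at least
#' 2 Mb long with at least 20 SNPs, at most one heterozygous and one
#' missing call, at least one SNP per 100 kb, and no gap between
#' consecutive SNPs above 500 kb.
#'
#' `window_size` and `window_threshold` only affect window mode and are the
#' PLINK `--homozyg` scanner defaults (50-SNP windows, per-SNP hit fraction
#' 0.05); they are not part of the run-mode constraint set.
#'
#' @param min_length_mb Minimum segment length in Mb.
#' @param min_snps Minimum number of SNPs spanned by a segment.
#' @param max_het Maximum heterozygous calls tolerated inside a segment
#'   (per window in window mode).
#' @param max_missing Maximum missing calls tolerated inside a segment
#'   (per window in window mode).
#' @param min_density_kb_per_snp Minimum SNP density: the segment must carry
#'   at least one SNP per this many kb (exact equality passes).
#' @param max_gap_kb Maximum gap between consecutive SNPs inside a segment.
#' @param window_size Sliding-window size in SNPs (window mode).
#' @param window_threshold Minimum fraction of homozygous windows
#'   overlapping a SNP for it to be eligible (window mode).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_mb = 2, min_snps = 20, max_het = 1,
                       max_missing = 1, min_density_kb_per_snp = 100,
                       max_gap_kb = 500, window_size = 50,
                       window_threshold = 0.05) {
  stopifnot(min_length_mb > 0, min_snps >= 1, max_het >= 0, max_missing >= 0,
            min_density_kb_per_snp > 0, max_gap_kb > 0, window_size >= 1,
            window_threshold >= 0)
  structure(list(min_length_mb = min_length_mb, min_snps = min_snps,
                 max_het = max_het, max_missing = max_missing,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb, window_size = window_size,
                 window_threshold = window_threshold),
            class = "roh_params")
}

#' @export
print.roh_params <- function(x, ...) {
  cat(sprintf(
    "<roh_params> >=%g Mb, >=%d SNPs, <=%d het, <=%d missing, >=1 SNP/%g kb, gap <=%g kb\n",
    x$min_length_mb, x$min_snps, x$max_het, x$max_missing,
    x$min_density_kb_per_snp, x$max_gap_kb))
  invisible(x)
}

empty_segments <- function() {
  tibble::tibble(chrom = character(), start_bp = integer(), end_bp = integer(),
                 start_idx = integer(), end_idx = integer(), n_snps = integer(),
                 n_het = integer(), n_missing = integer(), length_bp = numeric())
}

# Segment candidates for one chromosome of one individual, run mode.
# g: codes (0/1/2/NA) aligned to pos (sorted bp). Returns index pairs of
# maximal valid intervals reduced to a disjoint set (longest-first greedy).
run_mode_chrom <- function(g, pos, p) {
  n <- length(g)
  if (n == 0) return(NULL)
  min_len <- p$min_length_mb * 1e6
  dens_bp <- p$min_density_kb_per_snp * 1e3
  max_gap <- p$max_gap_kb * 1e3

  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  if (!any(hom)) return(NULL)

  idx <- seq_len(n)
  # farthest feasible right end J(i) for the hereditary constraints:
  # het budget, missing budget, gap ceiling
  bound_from_events <- function(ev, budget) {
    ei <- which(ev)
    if (length(ei) <= budget) return(rep(n, n))
    before <- findInterval(idx - 0.5, ei)       # events strictly left of i
    need <- before + budget + 1L
    nxt <- rep(n + 1L, n)
    in_range <- need <= length(ei)
    nxt[in_range] <- ei[need[in_range]]
    nxt - 1L
  }
  blk <- cumsum(c(0L, diff(pos) > max_gap))
  blk_end <- stats::ave(idx, blk, FUN = max)
  J <- pmin(bound_from_events(het, p$max_het),
            bound_from_events(mis, p$max_missing),
            blk_end)

  # maximal hereditary-feasible windows: J is non-decreasing, so window
  # [i, J(i)] is maximal iff J steps up at i
  starts <- which(idx == 1L | J > c(-1L, J[-n]))
  starts <- starts[J[starts] >= starts]
  if (length(starts) == 0) return(NULL)
  ends <- J[starts]

  next_hom <- rev(cummin(rev(ifelse(hom, idx, n + 1L))))
  prev_hom <- cummax(ifelse(hom, idx, 0L))

  i0 <- next_hom[starts]
  j0 <- prev_hom[ends]
  ok <- i0 <= n & i0 <= j0
  i0 <- i0[ok]; j0 <- j0[ok]; ends <- ends[ok]
  if (length(i0) == 0) return(NULL)

  nsnp <- j0 - i0 + 1L
  span <- pos[j0] - pos[i0] + 1
  size_ok <- nsnp >= p$min_snps & span >= min_len
  dens_ok <- as.numeric(nsnp) * dens_bp >= span

  cand_i <- i0[size_ok & dens_ok]
  cand_j <- j0[size_ok & dens_ok]

  # fallback: the full window fails only the density bound; some proper
  # sub-interval may still pass. Enumerate, per homozygous start, the
  # largest valid end (maximal candidates are a subset of these).
  for (w in which(size_ok & !dens_ok)) {
    hs <- which(hom[i0[w]:j0[w]]) + i0[w] - 1L
    for (a in hs) {
      bs <- hs[hs >= a]
      for (b in rev(bs)) {
        nn <- b - a + 1L
        sp <- pos[b] - pos[a] + 1
        if (nn < p$min_snps || sp < min_len) break
        if (as.numeric(nn) * dens_bp >= sp) {
          cand_i <- c(cand_i, a); cand_j <- c(cand_j, b)
          break
        }
      }
    }
  }
  if (length(cand_i) == 0) return(NULL)

  # drop duplicates and candidates contained in another candidate
  o <- order(cand_i, -cand_j)
  cand_i <- cand_i[o]; cand_j <- cand_j[o]
  keep <- !duplicated(cbind(cand_i, cand_j))
  cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
  run_max <- -1L
  maximal <- logical(length(cand_i))
  for (k in seq_along(cand_i)) {
    maximal[k] <- cand_j[k] > run_max
    run_max <- max(run_max, cand_j[k])
  }
  cand_i <- cand_i[maximal]; cand_j <- cand_j[maximal]

  greedy_disjoint(cand_i, cand_j, pos)
}

# Longest-first (bp length) greedy selection of disjoint intervals;
# ties broken by leftmost start.
greedy_disjoint <- function(ci, cj, pos) {
  span <- pos[cj] - pos[ci] + 1
  o <- order(-span, ci)
  ci <- ci[o]; cj <- cj[o]
  sel_i <- integer(0); sel_j <- integer(0)
  for (k in seq_along(ci)) {
    if (!any(ci[k] <= sel_j & cj[k] >= sel_i)) {
      sel_i <- c(sel_i, ci[k]); sel_j <- c(sel_j, cj[k])
    }
  }
  o <- order(sel_i)
  cbind(i = sel_i[o], j = sel_j[o])
}

segments_from_idx <- function(pairs, g, pos, chrom) {
  if (is.null(pairs) || nrow(pairs) == 0) return(empty_segments())
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ch <- cumsum(het); cm <- cumsum(mis)
  i <- pairs[, "i"]; j <- pairs[, "j"]
  tibble::tibble(
    chrom = chrom,
    start_bp = pos[i],
    end_bp = pos[j],
    start_idx = as.integer(i),
    end_idx = as.integer(j),
    n_snps = as.integer(j - i + 1L),
    n_het = as.integer(ch[j] - ch[i] + het[i]),
    n_missing = as.integer(cm[j] - cm[i] + mis[i]),
    length_bp = pos[j] - pos[i] + 1
  )
}

#' Call ROH for one individual, exhaustive run mode
#'
#' Returns every maximal SNP interval that satisfies all constraints in
#' `params` (homozygous first/last SNP, het/missing allowances, minimum
#' length, SNP count and density, maximum gap), reduced to a disjoint set
#' by longest-first greedy selection with leftmost tie-break. "Maximal"
#' means the interval is not contained in any other valid interval.
#'
#' @param geno_row Integer vector of genotype codes for one individual,
#'   aligned to `map`.
#' @param map Marker map tibble (`chrom`, `marker_id`, `pos_bp`), sorted.
#' @param params A [roh_params()] object.
#' @return Tibble of segments with columns `chrom`, `start_bp`, `end_bp`,
#'   `start_idx`, `end_idx` (map row indices), `n_snps`, `n_het`,
#'   `n_missing`, `length_bp`.
#' @export
call_roh_run_mode <- function(geno_row, map, params = roh_params()) {
  stopifnot(length(geno_row) == nrow(map))
  validate_map_sorted(map)
  chroms <- unique(map$chrom)
  out <- lapply(chroms, function(ch) {
    sel <- which(map$chrom == ch)
    pairs <- run_mode_chrom(geno_row[sel], map$pos_bp[sel], params)
    seg <- segments_from_idx(pairs, geno_row[sel], map$pos_bp[sel], ch)
    seg$start_idx <- seg$start_idx + sel[1] - 1L
    seg$end_idx <- seg$end_idx + sel[1] - 1L
    seg
  })
  dplyr::bind_rows(out)
}

# Window-mode scanner for one chromosome: index pairs of surviving runs.
window_mode_chrom <- function(g, pos, p) {
  n <- length(g)
  if (n == 0) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  if (!any(hom)) return(NULL)
  W <- min(p$window_size, n)
  nw <- n - W + 1L

  csh <- cumsum(het); csm <- cumsum(mis)
  wh <- csh[W:n] - c(0, csh)[1:nw]
  wm <- csm[W:n] - c(0, csm)[1:nw]
  flag <- as.integer(wh <= p$max_het & wm <= p$max_missing)

  lo <- pmax(1L, seq_len(n) - W + 1L)
  hi <- pmin(seq_len(n), nw)
  csf <- c(0L, cumsum(flag))
  n_hom_win <- csf[hi + 1L] - csf[lo]
  n_win <- hi - lo + 1L
  eligible <- n_win > 0 & (n_hom_win / pmax(n_win, 1L)) >= p$window_threshold

  r <- rle(eligible)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  stretches <- cbind(run_start[r$values], run_end[r$values])
  if (nrow(stretches) == 0) return(NULL)

  min_len <- p$min_length_mb * 1e6
  dens_bp <- p$min_density_kb_per_snp * 1e3
  max_gap <- p$max_gap_kb * 1e3

  # het/missing allowances act per window in this mode (the window flags
  # above); surviving stretches are filtered on size, density and gaps only
  sel_i <- integer(0); sel_j <- integer(0)
  for (s in seq_len(nrow(stretches))) {
    a0 <- stretches[s, 1]; b0 <- stretches[s, 2]
    # split at oversized gaps, then trim each piece to homozygous ends
    cuts <- which(diff(pos[a0:b0]) > max_gap) + a0 - 1L
    piece_a <- c(a0, cuts + 1L)
    piece_b <- c(cuts, b0)
    for (k in seq_along(piece_a)) {
      a <- piece_a[k]; b <- piece_b[k]
      hin <- which(hom[a:b]) + a - 1L
      if (length(hin) == 0) next
      a <- hin[1]; b <- hin[length(hin)]
      nn <- b - a + 1L
      sp <- pos[b] - pos[a] + 1
      if (nn >= p$min_snps && sp >= min_len &&
          as.numeric(nn) * dens_bp >= sp) {
        sel_i <- c(sel_i, a); sel_j <- c(sel_j, b)
      }
    }
  }
  if (length(sel_i) == 0) return(NULL)
  cbind(i = sel_i, j = sel_j)
}

#' Call ROH for one individual, sliding-window mode
#'
#' Emulates the PLINK `--homozyg` scanner: windows of `window_size` SNPs
#' are flagged homozygous when they contain at most `max_het` heterozygous
#' and `max_missing` missing calls; each SNP's hit fraction is the share of
#' flagged windows among windows overlapping it; maximal stretches of SNPs
#' with fraction at least `window_threshold` are split at oversized gaps,
#' trimmed to homozygous end SNPs, and kept if they satisfy the run-level
#' length, SNP count, density and het/missing constraints.
#'
#' @inheritParams call_roh_run_mode
#' @return Segment tibble, as [call_roh_run_mode()].
#' @export
call_roh_window_mode <- function(geno_row, map, params = roh_params()) {
  stopifnot(length(geno_row) == nrow(map))
  validate_map_sorted(map)
  if (params$window_size < params$min_snps) {
    warn("window_size is smaller than min_snps; window hits will be permissive")
  }
  chroms <- unique(map$chrom)
  out <- lapply(chroms, function(ch) {
    sel <- which(map$chrom == ch)
    pairs <- window_mode_chrom(geno_row[sel], map$pos_bp[sel], params)
    seg <- segments_from_idx(pairs, geno_row[sel], map$pos_bp[sel], ch)
    seg$start_idx <- seg$start_idx + sel[1] - 1L
    seg$end_idx <- seg$end_idx + sel[1] - 1L
    seg
  })
  dplyr::bind_rows(out)
}

#' Detect runs of homozygosity for every individual
#'
#' Applies [call_roh_run_mode()] (default) or [call_roh_window_mode()] to
#' each individual and pools the calls into a `roh_set` tibble. Individuals
#' without any ROH remain part of the set through the attached sample
#' table, so population summaries keep them in denominators.
#'
#' @param data A [geno_data()] object (typically after [run_qc()]).
#' @param params A [roh_params()] object.
#' @param mode `"run"` for the exhaustive maximal-interval scanner,
#'   `"window"` for the sliding-window emulation.
#' @return A tibble of class `roh_set`: one row per segment with
#'   `sample_id`, `population`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `n_het`, `n_missing`, `length_bp`, `length_mb`; the sample table,
#'   parameters and mode are attached as attributes `samples`, `params`
#'   and `mode`.
#' @export
#' @examples
#' sim <- simulate_goat_cohort(sim_config(n_markers = 2000, n_chromosomes = 2,
#'   chrom_lengths_mb = c(100, 80), pop_sizes = c(A = 4),
#'   target_f = c(A = 0.1)), seed = 1)
#' roh <- detect_roh(sim$data)
#' glance(roh)
detect_roh <- function(data, params = roh_params(), mode = c("run", "window")) {
  stopifnot(inherits(data, "geno_data"))
  mode <- match.arg(mode)
  fun <- if (mode == "run") call_roh_run_mode else call_roh_window_mode
  segs <- lapply(seq_len(nrow(data$geno)), function(i) {
    s <- fun(data$geno[i, ], data$map, params)
    if (nrow(s) > 0) {
      s$sample_id <- data$samples$sample_id[i]
      s$population <- data$samples$population[i]
    }
    s
  })
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0) {
    out <- empty_segments()
    out$sample_id <- character(0)
    out$population <- character(0)
  }
  out$length_mb <- out$length_bp / 1e6
  out <- dplyr::select(out, "sample_id", "population", "chrom", "start_bp",
                       "end_bp", "start_idx", "end_idx", "n_snps", "n_het",
                       "n_missing", "length_bp", "length_mb")
  as_roh_set(out, data$samples, params, mode)
}

as_roh_set <- function(tbl, samples, params, mode = "run") {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "samples") <- tibble::as_tibble(samples)
  attr(tbl, "params") <- params
  attr(tbl, "mode") <- mode
  class(tbl) <- c("roh_set", class(tbl))
  tbl
}

roh_samples <- function(roh, samples = NULL) {
  if (!is.null(samples)) return(tibble::as_tibble(samples))
  s <- attr(roh, "samples")
  if (is.null(s)) {
    s <- dplyr::distinct(tibble::as_tibble(roh[c("sample_id", "population")]))
  }
  s
}

#' Re-validate ROH segments against the constraint set
#'
#' Independent post-hoc checker: recomputes every constraint of each
#' segment directly from the genotype matrix, without reusing any caller
#' internals. Intended for auditing caller output.
#'
#' @param roh A segment tibble (`roh_set` or output of the single-row
#'   callers; must carry `chrom`, `start_bp`, `end_bp`; `sample_id` is
#'   required when `roh` covers several individuals).
#' @param data The [geno_data()] the calls were made from.
#' @param params The [roh_params()] used (default: taken from `roh`).
#' @return Logical vector, one element per segment, `TRUE` when every
#'   constraint holds; failed constraint names are attached as attribute
#'   `"violations"`.
#' @export
validate_roh_segments <- function(roh, data, params = NULL) {
  if (is.null(params)) params <- attr(roh, "params")
  if (is.null(params)) abort("supply `params` (not attached to `roh`)")
  p <- params
  min_len <- p$min_length_mb * 1e6
  dens_bp <- p$min_density_kb_per_snp * 1e3
  max_gap <- p$max_gap_kb * 1e3
  ok <- logical(nrow(roh))
  why <- character(nrow(roh))
  for (k in seq_len(nrow(roh))) {
    row_i <- if ("sample_id" %in% names(roh)) {
      match(roh$sample_id[k], data$samples$sample_id)
    } else 1L
    sel <- which(data$map$chrom == roh$chrom[k] &
                   data$map$pos_bp >= roh$start_bp[k] &
                   data$map$pos_bp <= roh$end_bp[k])
    g <- data$geno[row_i, sel]
    pos <- data$map$pos_bp[sel]
    n <- length(sel)
    span <- roh$end_bp[k] - roh$start_bp[k] + 1
    fails <- c(
      endpoints_hom = !(n > 0 && !is.na(g[1]) && g[1] != 1L &&
                          !is.na(g[n]) && g[n] != 1L &&
                          pos[1] == roh$start_bp[k] && pos[n] == roh$end_bp[k]),
      min_snps = n < p$min_snps,
      min_length = span < min_len,
      max_het = sum(g == 1L, na.rm = TRUE) > p$max_het,
      max_missing = sum(is.na(g)) > p$max_missing,
      density = as.numeric(n) * dens_bp < span,
      max_gap = n > 1 && max(diff(pos)) > max_gap
    )
    ok[k] <- !any(fails)
    why[k] <- paste(names(fails)[fails], collapse = ",")
  }
  # segments of one individual on one chromosome must be pairwise disjoint
  if (nrow(roh) > 1 && "sample_id" %in% names(roh)) {
    key <- paste(roh$sample_id, roh$chrom)
    for (kk in unique(key)) {
      w <- which(key == kk)
      if (length(w) < 2) next
      o <- w[order(roh$start_bp[w])]
      olap <- roh$start_bp[o][-1] <= roh$end_bp[o][-length(o)]
      if (any(olap)) {
        bad <- o[c(FALSE, olap)]
        ok[bad] <- FALSE
        why[bad] <- paste(why[bad], "overlap", sep = ",")
      }
    }
  }
  attr(ok, "violations") <- why
  ok
}

#' One-line summary of a ROH set
#'
#' @param x A `roh_set` from [detect_roh()].
#' @param ... Unused.
#' @return One-row tibble: individuals, individuals without ROH, total
#'   segment count, mean segments per individual (over all individuals and
#'   over ROH-carrying individuals only), mean segment length (Mb) and
#'   longest segment (Mb).
#' @method glance roh_set
#' @export
glance.roh_set <- function(x, ...) {
  samples <- roh_samples(x)
  n_ind <- nrow(samples)
  n_with <- length(unique(x$sample_id))
  tibble::tibble(
    n_individuals = n_ind,
    n_zero_roh = n_ind - n_with,
    n_segments = nrow(x),
    mean_n_per_individual = nrow(x) / n_ind,
    mean_n_per_carrier = if (n_with > 0) nrow(x) / n_with else 0,
    mean_length_mb = if (nrow(x) > 0) mean(x$length_mb) else NA_real_,
    max_length_mb = if (nrow(x) > 0) max(x$length_mb) else NA_real_
  )
}
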