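#' Simulation configuration
#'
#' Describes a synthetic SNP-array cohort with planted autozygous segments.
#' The defaults emulate the scale of a five-breed goat panel typed on a
#' 50K chip: populations of 48/32/59/16/22 individuals, 29 autosomes
#' summing to 2450 Mb, ~48,000 markers on a jittered grid, and
#' per-population autozygosity targets spanning ~0.01 to ~0.13.
#'
#' Autozygosity is planted as explicit intervals: each individual receives
#' non-overlapping segments until the summed length reaches
#' `target_f * genome length` (the last segment may overshoot; the realized
#' fraction is recorded in the truth table). Segment lengths follow a
#' mixture of exponentials with mean `100 / (2g)` Mb, `g` being the number
#' of generations to the common ancestor — the default mix `g = {3, 25}`
#' produces both long (recent) and short (ancient) autozygosity — truncated
#' to `seg_trunc_mb`.
#'
#' @param pop_sizes Named integer vector of individuals per population.
#' @param target_f Named numeric vector (same names) of per-population
#'   autozygosity targets in `[0, 1)`.
#' @param n_chromosomes Number of autosomes.
#' @param chrom_lengths_mb Chromosome lengths in Mb; default: exponentially
#'   decaying lengths summing to `genome_mb`.
#' @param genome_mb Total autosome length when lengths are derived.
#' @param n_markers Total marker count, split across chromosomes
#'   proportionally to length.
#' @param freq_range Range of the uniform ancestral allele-frequency law.
#' @param fst Balding-Nichols differentiation between populations (0 =
#'   identical allele frequencies everywhere).
#' @param gens Generations-to-ancestor values of the segment-length
#'   mixture.
#' @param gens_weights Mixture weights (recycled/normalized).
#' @param seg_trunc_mb Lower/upper truncation of segment lengths in Mb.
#' @param error_rate Probability that a marker inside a planted segment is
#'   flipped to a heterozygous call (genotyping error), in `[0, 0.1]`.
#' @param missing_rate Genome-wide missing-call probability, in `[0, 0.1]`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pop_sizes = c(ARG = 48, DDS = 32, GIR = 59,
                                     MAL = 16, MES = 22),
                       target_f = c(ARG = 0.009, DDS = 0.097, GIR = 0.108,
                                    MAL = 0.125, MES = 0.012),
                       n_chromosomes = 29, chrom_lengths_mb = NULL,
                       genome_mb = 2450, n_markers = 48000,
                       freq_range = c(0.05, 0.5), fst = 0.05,
                       gens = c(3, 25), gens_weights = c(0.5, 0.5),
                       seg_trunc_mb = c(0.5, 150),
                       error_rate = 0.001, missing_rate = 0.001) {
  if (is.null(names(pop_sizes))) {
    names(pop_sizes) <- paste0("P", seq_along(pop_sizes))
  }
  if (is.null(names(target_f)) && length(target_f) == length(pop_sizes)) {
    names(target_f) <- names(pop_sizes)
  }
  missing_f <- setdiff(names(pop_sizes), names(target_f))
  if (length(missing_f) > 0) {
    abort(sprintf("no target_f for population(s): %s",
                  paste(missing_f, collapse = ", ")))
  }
  if (is.null(chrom_lengths_mb)) {
    w <- exp(-0.045 * (seq_len(n_chromosomes) - 1))
    chrom_lengths_mb <- genome_mb * w / sum(w)
  } else {
    n_chromosomes <- length(chrom_lengths_mb)
  }
  stopifnot(all(target_f >= 0), all(target_f < 1),
            error_rate >= 0, error_rate <= 0.1,
            missing_rate >= 0, missing_rate <= 0.1,
            all(chrom_lengths_mb > 0), n_markers >= n_chromosomes,
            length(freq_range) == 2, freq_range[1] > 0, freq_range[2] <= 0.5,
            fst >= 0, fst < 1, length(gens) == length(gens_weights),
            all(gens > 0), all(gens_weights >= 0), sum(gens_weights) > 0,
            length(seg_trunc_mb) == 2, seg_trunc_mb[1] > 0,
            diff(seg_trunc_mb) > 0)
  structure(list(
    pop_sizes = pop_sizes, target_f = target_f[names(pop_sizes)],
    n_chromosomes = n_chromosomes, chrom_lengths_mb = chrom_lengths_mb,
    n_markers = n_markers, freq_range = freq_range, fst = fst,
    gens = gens, gens_weights = gens_weights / sum(gens_weights),
    seg_trunc_mb = seg_trunc_mb, error_rate = error_rate,
    missing_rate = missing_rate
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d individuals in %d populations, %d markers on %d chromosomes (%.0f Mb)\n",
    sum(x$pop_sizes), length(x$pop_sizes), x$n_markers, x$n_chromosomes,
    sum(x$chrom_lengths_mb)))
  cat(sprintf("  target autozygosity: %s\n",
              paste(sprintf("%s %.3f", names(x$target_f), x$target_f),
                    collapse = ", ")))
  invisible(x)
}

# jittered-grid marker positions, strictly increasing
marker_positions <- function(len_bp, n) {
  step <- len_bp / n
  pos <- round((seq_len(n) - 0.5) * step + runif(n, -0.45, 0.45) * step)
  pos <- sort(pmin(pmax(pos, 1), len_bp))
  while (any(d0 <- diff(pos) <= 0)) {
    pos[which(d0) + 1L] <- pos[which(d0)] + 1L
    pos <- sort(pmin(pos, len_bp))
  }
  as.integer(pos)
}

draw_segment_length <- function(cfg) {
  comp <- sample.int(length(cfg$gens), 1, prob = cfg$gens_weights)
  repeat {
    l_mb <- rexp(1, rate = 2 * cfg$gens[comp] / 100)
    if (l_mb >= cfg$seg_trunc_mb[1] && l_mb <= cfg$seg_trunc_mb[2]) {
      return(l_mb * 1e6)
    }
  }
}

# plant non-overlapping autozygous intervals until target mass is reached
plant_segments <- function(cfg, target_bp, chrom_len_bp) {
  segs <- list()
  placed <- lapply(chrom_len_bp, function(...) NULL)
  total <- 0
  attempts <- 0
  while (total < target_bp) {
    attempts <- attempts + 1
    if (attempts > 10000) {
      abort("target autozygosity unattainable under the segment-length truncation")
    }
    l <- draw_segment_length(cfg)
    ch <- sample.int(length(chrom_len_bp), 1, prob = chrom_len_bp)
    if (l >= chrom_len_bp[ch]) next
    s <- floor(runif(1, 1, chrom_len_bp[ch] - l))
    e <- s + l - 1
    prev <- placed[[ch]]
    if (!is.null(prev) && any(s <= prev[, 2] & e >= prev[, 1])) next
    placed[[ch]] <- rbind(prev, c(s, e))
    segs[[length(segs) + 1]] <- c(ch, s, e)
    total <- total + l
  }
  if (length(segs) == 0) {
    return(tibble::tibble(chrom_i = integer(), start_bp = numeric(),
                          end_bp = numeric()))
  }
  m <- do.call(rbind, segs)
  tibble::tibble(chrom_i = as.integer(m[, 1]), start_bp = m[, 2],
                 end_bp = m[, 3])
}

#' Simulate a genotyped cohort with planted autozygous segments
#'
#' Generates diploid genotypes at Hardy-Weinberg equilibrium from
#' per-population allele frequencies (Balding-Nichols differentiation
#' `fst` around a shared ancestral frequency), then overwrites planted
#' autozygous intervals with homozygous genotypes (the allele drawn by its
#' frequency). Genotyping error flips in-segment markers to heterozygous
#' with probability `error_rate`; missing calls are sprinkled genome-wide
#' at `missing_rate`. Fully reproducible given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all randomness.
#' @return A list of class `sim_cohort` with elements `data` (a
#'   [geno_data()]), `truth` (tibble of planted intervals: `sample_id`,
#'   `population`, `chrom`, `start_bp`, `end_bp`, `length_bp`),
#'   `realized_f` (tibble: `sample_id`, `population`, `target_f`,
#'   `realized_f`), `genome_bp` and `config`.
#' @export
#' @examples
#' sim <- simulate_goat_cohort(sim_config(n_markers = 1000,
#'   n_chromosomes = 2, chrom_lengths_mb = c(60, 40),
#'   pop_sizes = c(A = 4), target_f = c(A = 0.05)), seed = 42)
#' sim$realized_f
simulate_goat_cohort <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  chrom_len_bp <- round(cfg$chrom_lengths_mb * 1e6)
  genome_bp <- sum(chrom_len_bp)
  chroms <- as.character(seq_len(cfg$n_chromosomes))

  n_per_chrom <- pmax(1L, round(cfg$n_markers * chrom_len_bp / genome_bp))
  map <- dplyr::bind_rows(lapply(seq_len(cfg$n_chromosomes), function(c) {
    pos <- marker_positions(chrom_len_bp[c], n_per_chrom[c])
    tibble::tibble(chrom = chroms[c], pos_bp = pos)
  }))
  map$marker_id <- sprintf("snp%d_%s", seq_len(nrow(map)), map$chrom)
  map <- map[, c("chrom", "marker_id", "pos_bp")]
  n_mark <- nrow(map)

  p0 <- runif(n_mark, cfg$freq_range[1], cfg$freq_range[2])
  pops <- names(cfg$pop_sizes)
  pop_freq <- lapply(pops, function(pp) {
    if (cfg$fst == 0) return(p0)
    a <- p0 * (1 - cfg$fst) / cfg$fst
    b <- (1 - p0) * (1 - cfg$fst) / cfg$fst
    pmin(pmax(rbeta(n_mark, a, b), 1e-3), 1 - 1e-3)
  })
  names(pop_freq) <- pops

  samples <- tibble::tibble(
    population = rep(pops, cfg$pop_sizes),
    sample_id = unlist(lapply(pops, function(pp) {
      sprintf("%s_%03d", pp, seq_len(cfg$pop_sizes[[pp]]))
    }))
  )[, c("sample_id", "population")]
  n_ind <- nrow(samples)

  chrom_first <- match(chroms, map$chrom)
  geno <- matrix(NA_integer_, n_ind, n_mark)
  truth <- vector("list", n_ind)
  realized <- numeric(n_ind)

  for (i in seq_len(n_ind)) {
    pp <- samples$population[i]
    p <- pop_freq[[pp]]
    g <- rbinom(n_mark, 2L, p)
    segs <- plant_segments(cfg, cfg$target_f[[pp]] * genome_bp, chrom_len_bp)
    in_seg <- logical(n_mark)
    if (nrow(segs) > 0) {
      for (k in seq_len(nrow(segs))) {
        c_i <- segs$chrom_i[k]
        off <- chrom_first[c_i] - 1L
        pos <- map$pos_bp[map$chrom == chroms[c_i]]
        lo <- findInterval(segs$start_bp[k] - 1, pos) + 1L
        hi <- findInterval(segs$end_bp[k], pos)
        if (lo <= hi) in_seg[(off + lo):(off + hi)] <- TRUE
      }
      w <- which(in_seg)
      g[w] <- 2L * rbinom(length(w), 1L, p[w])
      if (cfg$error_rate > 0) {
        flip <- w[runif(length(w)) < cfg$error_rate]
        g[flip] <- 1L
      }
    }
    if (cfg$missing_rate > 0) {
      g[runif(n_mark) < cfg$missing_rate] <- NA_integer_
    }
    geno[i, ] <- g
    realized[i] <- sum(segs$end_bp - segs$start_bp + 1) / genome_bp
    truth[[i]] <- if (nrow(segs) > 0) {
      tibble::tibble(sample_id = samples$sample_id[i], population = pp,
                     chrom = chroms[segs$chrom_i],
                     start_bp = segs$start_bp, end_bp = segs$end_bp,
                     length_bp = segs$end_bp - segs$start_bp + 1)
    } else NULL
  }

  structure(list(
    data = geno_data(geno, map, samples),
    truth = dplyr::bind_rows(truth),
    realized_f = dplyr::bind_cols(
      samples,
      tibble::tibble(target_f = unname(cfg$target_f[samples$population]),
                     realized_f = realized)),
    genome_bp = genome_bp,
    config = cfg
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d individuals, %d markers, %d planted segments\n",
              nrow(x$data$geno), ncol(x$data$geno), nrow(x$truth)))
  invisible(x)
}

segment_overlap_frac <- function(target, calls) {
  # fraction of each target interval covered by the single best-overlapping
  # call on the same chromosome (calls of one individual are disjoint)
  vapply(seq_len(nrow(target)), function(k) {
    same <- calls$chrom == target$chrom[k]
    if (!any(same)) return(0)
    ov <- pmin(calls$end_bp[same], target$end_bp[k]) -
      pmax(calls$start_bp[same], target$start_bp[k]) + 1
    max(0, ov) / (target$end_bp[k] - target$start_bp[k] + 1)
  }, numeric(1))
}

#' Parameter-recovery experiment for the ROH estimator
#'
#' Simulates cohorts, calls ROH, and quantifies how well F_ROH recovers
#' the planted autozygosity and how well individual planted segments are
#' recovered. Sensitivity is the share of planted segments (at least
#' `params$min_length_mb` long, so callable in principle) covered at least
#' `min_overlap` by a single call of the same individual; precision is the
#' mirror image for called segments against planted ones. Both are broken
#' down by length class.
#'
#' @param configs A [sim_config()] or list of them (e.g. a grid over
#'   `target_f`).
#' @param params [roh_params()] for the caller.
#' @param seeds Integer vector; each config is replicated per seed.
#' @param mode Caller mode, see [detect_roh()].
#' @param min_overlap Coverage fraction counting a segment as recovered.
#' @return A tibble with one row per (config, seed, population):
#'   `target_f`, `realized_f_mean`, `froh_mean`, `bias` (vs target),
#'   `rmse` (per-individual, vs target); segment-level class-wise
#'   `sensitivity`/`precision` are attached as attribute
#'   `"segment_recovery"`.
#' @export
recovery_experiment <- function(configs, params = roh_params(), seeds = 1L,
                                mode = "run", min_overlap = 0.9) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  froh_rows <- list()
  seg_rows <- list()
  for (ci in seq_along(configs)) {
    for (sd in seeds) {
      sim <- simulate_goat_cohort(configs[[ci]], seed = sd)
      roh <- detect_roh(sim$data, params, mode = mode)
      fr <- roh_froh(roh, laut_bp = sim$genome_bp) |>
        dplyr::left_join(sim$realized_f[c("sample_id", "target_f",
                                          "realized_f")],
                         by = "sample_id")
      froh_rows[[length(froh_rows) + 1]] <- fr |>
        dplyr::group_by(.data$population) |>
        dplyr::summarise(
          config = ci, seed = sd,
          target_f = .data$target_f[1],
          realized_f_mean = mean(.data$realized_f),
          froh_mean = mean(.data$froh),
          bias = mean(.data$froh - .data$target_f),
          rmse = sqrt(mean((.data$froh - .data$target_f)^2)),
          .groups = "drop")

      callable <- sim$truth[sim$truth$length_bp >=
                              params$min_length_mb * 1e6, ]
      per_ind <- split(tibble::as_tibble(roh), roh$sample_id)
      sens <- numeric(0); sens_class <- character(0)
      if (nrow(callable) > 0) {
        for (id in unique(callable$sample_id)) {
          tg <- callable[callable$sample_id == id, ]
          calls <- per_ind[[id]]
          if (is.null(calls)) calls <- empty_segments()
          sens <- c(sens, segment_overlap_frac(tg, calls) >= min_overlap)
          sens_class <- c(sens_class, as.character(
            roh_length_class(tg$length_bp / 1e6)))
        }
      }
      prec <- numeric(0); prec_class <- character(0)
      if (nrow(roh) > 0) {
        for (id in unique(roh$sample_id)) {
          calls <- per_ind[[id]]
          tg <- sim$truth[sim$truth$sample_id == id, ]
          prec <- c(prec, segment_overlap_frac(calls, tg) >= min_overlap)
          prec_class <- c(prec_class, as.character(
            roh_length_class(calls$length_bp / 1e6)))
        }
      }
      lev <- c(levels(roh_length_class(numeric(0))), "all")
      seg_rows[[length(seg_rows) + 1]] <- dplyr::bind_rows(lapply(
        lev, function(cl) {
          si <- if (cl == "all") rep(TRUE, length(sens)) else sens_class == cl
          pi <- if (cl == "all") rep(TRUE, length(prec)) else prec_class == cl
          tibble::tibble(
            config = ci, seed = sd, class = cl,
            n_planted = sum(si),
            sensitivity = if (any(si)) mean(sens[si]) else NA_real_,
            n_called = sum(pi),
            precision = if (any(pi)) mean(prec[pi]) else NA_real_)
        }))
    }
  }
  out <- dplyr::bind_rows(froh_rows)
  attr(out, "segment_recovery") <- dplyr::bind_rows(seg_rows)
  out
}
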