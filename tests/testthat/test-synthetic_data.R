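test_that("simulation is reproducible under a fixed seed and varies across seeds", {
  cfg <- sim_config(pop_sizes = c(A = 4), target_f = c(A = 0.05),
                    n_chromosomes = 2, chrom_lengths_mb = c(40, 30),
                    n_markers = 700)
  s1 <- simulate_goat_cohort(cfg, seed = 3)
  s2 <- simulate_goat_cohort(cfg, seed = 3)
  s3 <- simulate_goat_cohort(cfg, seed = 4)
  expect_identical(s1$data$geno, s2$data$geno)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$data$geno, s3$data$geno))
})

test_that("background heterozygosity follows Hardy-Weinberg at f = 0", {
  cfg <- sim_config(pop_sizes = c(A = 40), target_f = c(A = 0),
                    n_chromosomes = 2, chrom_lengths_mb = c(40, 30),
                    n_markers = 1200, fst = 0, error_rate = 0,
                    missing_rate = 0)
  sim <- simulate_goat_cohort(cfg, seed = 8)
  # aggregate observed heterozygosity vs its binomial expectation
  p <- colMeans(sim$data$geno) / 2
  exp_het <- mean(2 * p * (1 - p))
  obs_het <- mean(sim$data$geno == 1L)
  n_calls <- length(sim$data$geno)
  se <- sqrt(exp_het * (1 - exp_het) / n_calls)
  expect_lt(abs(obs_het - exp_het), 4 * se + 0.005)
  expect_equal(nrow(sim$truth), 0)
})

test_that("planted segments cover the target fraction and are homozygous", {
  cfg <- sim_config(pop_sizes = c(A = 6), target_f = c(A = 0.1),
                    n_chromosomes = 3, chrom_lengths_mb = c(50, 40, 30),
                    n_markers = 2400, error_rate = 0, missing_rate = 0)
  sim <- simulate_goat_cohort(cfg, seed = 9)
  expect_true(all(sim$realized_f$realized_f >= 0.1))
  expect_true(all(sim$realized_f$realized_f <= 0.1 + 150e6 / sim$genome_bp))

  # fraction of markers inside planted segments tracks the realized fraction
  for (i in seq_len(6)) {
    id <- sim$data$samples$sample_id[i]
    tr <- sim$truth[sim$truth$sample_id == id, ]
    in_seg <- rep(FALSE, nrow(sim$data$map))
    for (k in seq_len(nrow(tr))) {
      in_seg <- in_seg | (sim$data$map$chrom == tr$chrom[k] &
                            sim$data$map$pos_bp >= tr$start_bp[k] &
                            sim$data$map$pos_bp <= tr$end_bp[k])
    }
    expect_lt(abs(mean(in_seg) - sim$realized_f$realized_f[i]), 0.02)
    expect_true(all(sim$data$geno[i, in_seg] %in% c(0L, 2L)))
  }

  # planted intervals are disjoint within a chromosome
  disjoint <- sim$truth |>
    dplyr::group_by(sample_id, chrom) |>
    dplyr::arrange(start_bp, .by_group = TRUE) |>
    dplyr::summarise(ok = all(start_bp[-1] > end_bp[-dplyr::n()]) ||
                       dplyr::n() < 2, .groups = "drop")
  expect_true(all(disjoint$ok))
})

test_that("an unattainable autozygosity target is rejected", {
  cfg <- sim_config(pop_sizes = c(A = 1), target_f = c(A = 0.9),
                    n_chromosomes = 2, chrom_lengths_mb = c(3, 3),
                    n_markers = 100, seg_trunc_mb = c(0.5, 2))
  expect_error(simulate_goat_cohort(cfg, seed = 1), "unattainable")
})

test_that("F_ROH estimates converge to the planted fraction as density grows", {
  res <- lapply(c(600, 1800, 5400), function(nm) {
    cfg <- sim_config(pop_sizes = c(A = 5), target_f = c(A = 0.08),
                      n_chromosomes = 3, chrom_lengths_mb = c(60, 50, 40),
                      n_markers = nm, gens = 3, gens_weights = 1,
                      error_rate = 0, missing_rate = 0)
    sim <- simulate_goat_cohort(cfg, seed = 17)
    roh <- detect_roh(sim$data)
    fr <- roh_froh(roh, laut_bp = sim$genome_bp)
    mean(abs(fr$froh - sim$realized_f$realized_f))
  })
  err <- unlist(res)
  expect_lt(err[3], err[1] + 0.01)   # no blow-up with density
  expect_lt(err[3], 0.02)            # dense map recovers the truth closely
})

test_that("zero autozygosity produces essentially no false-positive calls", {
  cfg <- sim_config(pop_sizes = c(A = 20), target_f = c(A = 0),
                    n_chromosomes = 4, chrom_lengths_mb = c(60, 50, 40, 30),
                    n_markers = 3600, error_rate = 0, missing_rate = 0)
  sim <- simulate_goat_cohort(cfg, seed = 23)
  roh <- detect_roh(sim$data)
  expect_lt(nrow(roh) / 20, 0.01)
})

test_that("recovery experiment reports bias, RMSE and class-wise recovery", {
  cfg <- sim_config(pop_sizes = c(A = 4), target_f = c(A = 0.08),
                    n_chromosomes = 3, chrom_lengths_mb = c(60, 50, 40),
                    n_markers = 3000, gens = 3, gens_weights = 1,
                    error_rate = 0, missing_rate = 0)
  out <- recovery_experiment(cfg, seeds = 41)
  expect_equal(nrow(out), 1)
  expect_equal(out$target_f, 0.08)
  # on a 150-Mb toy genome the last planted segment overshoots the target
  # substantially, so judge the estimator against the realized fraction
  expect_lt(abs(out$froh_mean - out$realized_f_mean), 0.02)
  segrec <- attr(out, "segment_recovery")
  expect_true(all(c("sensitivity", "precision") %in% names(segrec)))
  all_row <- segrec[segrec$class == "all", ]
  expect_gte(all_row$sensitivity, 0.9)
  # noiseless big segments are recovered essentially perfectly
  expect_gte(all_row$n_planted, 1)
})

test_that("genotyping error degrades recovery of the longest segments", {
  base <- function(eps) {
    sim_config(pop_sizes = c(A = 8), target_f = c(A = 0.12),
               n_chromosomes = 3, chrom_lengths_mb = c(90, 70, 60),
               n_markers = 4400, gens = 2, gens_weights = 1,
               error_rate = eps, missing_rate = 0)
  }
  clean <- recovery_experiment(base(0), seeds = 43)
  noisy <- recovery_experiment(base(0.02), seeds = 43)
  s_clean <- attr(clean, "segment_recovery")
  s_noisy <- attr(noisy, "segment_recovery")
  pick <- function(s) s$sensitivity[s$class == ">16"]
  expect_false(is.na(pick(s_clean)))
  expect_gt(pick(s_clean), pick(s_noisy))
})
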