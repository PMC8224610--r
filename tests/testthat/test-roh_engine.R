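test_that("degenerate inputs: all-het and all-missing rows give no calls", {
  map <- make_map(100)
  p <- roh_params()
  expect_equal(nrow(call_roh_run_mode(rep(1L, 100), map, p)), 0)
  expect_equal(nrow(call_roh_window_mode(rep(1L, 100), map, p)), 0)
  expect_equal(nrow(call_roh_run_mode(rep(NA_integer_, 100), map, p)), 0)
})

test_that("an unbroken homozygous chromosome yields one maximal segment", {
  map <- make_map(500, spacing_bp = 1e5)
  seg <- call_roh_run_mode(rep(0L, 500), map, roh_params())
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 500L)
  expect_equal(seg$start_bp, map$pos_bp[1])
  expect_equal(seg$end_bp, map$pos_bp[500])
  expect_equal(seg$length_bp, 499 * 1e5 + 1)  # ~49.9 Mb
})

test_that("an oversized gap splits a run into two qualifying segments", {
  # 30 hom SNPs spanning ~2.9 Mb, a 600-kb gap, then 30 more
  pos <- c(1e6 + (0:29) * 1e5, 1e6 + 29 * 1e5 + 6e5 + (0:29) * 1e5)
  map <- tibble::tibble(chrom = "1", marker_id = paste0("m", seq_along(pos)),
                        pos_bp = as.integer(pos))
  seg <- call_roh_run_mode(rep(2L, 60), map, roh_params())
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_snps, c(30L, 30L))
  expect_true(all(seg$length_bp >= 2e6))
})

test_that("run mode matches the brute-force maximal-interval oracle", {
  set.seed(401)
  n_default <- 0
  for (rep_i in 1:80) {
    inst <- random_roh_instance(300)
    p <- if (rep_i %% 2 == 0) roh_params() else random_roh_params()
    if (rep_i %% 2 == 0) n_default <- n_default + 1
    map <- tibble::tibble(chrom = "1",
                          marker_id = paste0("m", seq_along(inst$pos)),
                          pos_bp = inst$pos)
    got <- call_roh_run_mode(inst$g, map, p)
    want <- oracle_roh(inst$g, inst$pos, p)
    expect_equal(got$start_idx, unname(want[, "i"]),
                 info = sprintf("instance %d (starts)", rep_i))
    expect_equal(got$end_idx, unname(want[, "j"]),
                 info = sprintf("instance %d (ends)", rep_i))
  }
  expect_gte(n_default, 20)
})

test_that("every emitted segment re-validates against the constraint set", {
  sim <- simulate_goat_cohort(
    sim_config(pop_sizes = c(A = 8), target_f = c(A = 0.1),
               n_chromosomes = 4, chrom_lengths_mb = c(80, 60, 50, 40),
               n_markers = 4600, error_rate = 0.002, missing_rate = 0.002),
    seed = 7)
  roh <- detect_roh(sim$data)
  expect_gt(nrow(roh), 0)
  ok <- validate_roh_segments(roh, sim$data)
  expect_true(all(ok), info = paste(attr(ok, "violations")[!ok], collapse = "; "))
})

test_that("relaxing min_length or min_snps never reduces the call count", {
  set.seed(402)
  for (k in 1:20) {
    inst <- random_roh_instance(250)
    map <- tibble::tibble(chrom = "1",
                          marker_id = paste0("m", seq_along(inst$pos)),
                          pos_bp = inst$pos)
    strict <- roh_params(min_length_mb = 2, min_snps = 20)
    lax_len <- roh_params(min_length_mb = 1, min_snps = 20)
    lax_snp <- roh_params(min_length_mb = 2, min_snps = 10)
    n_strict <- nrow(call_roh_run_mode(inst$g, map, strict))
    expect_gte(nrow(call_roh_run_mode(inst$g, map, lax_len)), n_strict)
    expect_gte(nrow(call_roh_run_mode(inst$g, map, lax_snp)), n_strict)
  }
})

test_that("calls are invariant to swapping the allele labels", {
  set.seed(403)
  inst <- random_roh_instance(200)
  map <- tibble::tibble(chrom = "1",
                        marker_id = paste0("m", seq_along(inst$pos)),
                        pos_bp = inst$pos)
  flipped <- inst$g
  flipped[!is.na(flipped) & flipped != 1L] <- 2L - flipped[!is.na(flipped) &
                                                             flipped != 1L]
  p <- roh_params(min_length_mb = 1, min_snps = 10)
  expect_equal(call_roh_run_mode(inst$g, map, p),
               call_roh_run_mode(flipped, map, p))
})

test_that("window mode equals run mode on a noiseless chromosome", {
  map <- make_map(300, spacing_bp = 8e4)
  g <- rep(0L, 300)
  p <- roh_params()
  expect_equal(call_roh_window_mode(g, map, p), call_roh_run_mode(g, map, p))
  expect_warning(call_roh_window_mode(g, map, roh_params(window_size = 10)),
                 "window_size")
})

test_that("window and run mode recover the same planted segments", {
  sim <- simulate_goat_cohort(
    sim_config(pop_sizes = c(A = 6), target_f = c(A = 0.08),
               n_chromosomes = 3, chrom_lengths_mb = c(90, 70, 60),
               n_markers = 4400, gens = 3, gens_weights = 1,
               error_rate = 0, missing_rate = 0),
    seed = 21)
  run <- detect_roh(sim$data, mode = "run")
  win <- detect_roh(sim$data, mode = "window")
  planted <- sim$truth[sim$truth$length_bp >= 2e6, ]
  # run mode recovers every callable planted segment
  coverage <- function(mode_calls, k) {
    calls <- mode_calls[mode_calls$sample_id == planted$sample_id[k] &
                          mode_calls$chrom == planted$chrom[k], ]
    sum(pmax(0, pmin(calls$end_bp, planted$end_bp[k]) -
               pmax(calls$start_bp, planted$start_bp[k]) + 1))
  }
  for (k in seq_len(nrow(planted))) {
    expect_gte(coverage(run, k) / planted$length_bp[k], 0.9)
  }
  # the window scanner cannot flag homozygous windows for runs shorter
  # than the window itself (every window then straddles het-rich flanks),
  # so the modes are only expected to agree on runs well above 50 SNPs
  n_inside <- vapply(seq_len(nrow(planted)), function(k) {
    sum(sim$data$map$chrom == planted$chrom[k] &
          sim$data$map$pos_bp >= planted$start_bp[k] &
          sim$data$map$pos_bp <= planted$end_bp[k])
  }, numeric(1))
  planted <- planted[n_inside >= 60, ]
  expect_gt(nrow(planted), 0)
  for (k in seq_len(nrow(planted))) {
    expect_gte(coverage(win, k) / planted$length_bp[k], 0.9)
  }
  # boundary agreement between modes: both scanners stop within the same
  # heterozygote-bounded flank, so boundaries differ by at most a few SNPs
  for (k in seq_len(nrow(planted))) {
    pick <- function(calls) {
      cand <- calls[calls$sample_id == planted$sample_id[k] &
                      calls$chrom == planted$chrom[k], ]
      ov <- pmin(cand$end_bp, planted$end_bp[k]) -
        pmax(cand$start_bp, planted$start_bp[k])
      cand[which.max(ov), ]
    }
    a <- pick(run); b <- pick(win)
    expect_lte(abs(a$start_idx - b$start_idx), 10)
    expect_lte(abs(a$end_idx - b$end_idx), 10)
  }
})

test_that("cohort-level calling is additive and keeps zero-ROH individuals", {
  sim <- simulate_goat_cohort(
    sim_config(pop_sizes = c(A = 3, B = 2), target_f = c(A = 0.1, B = 0),
               n_chromosomes = 2, chrom_lengths_mb = c(80, 60),
               n_markers = 2800, error_rate = 0, missing_rate = 0),
    seed = 31)
  roh <- detect_roh(sim$data)
  per_ind <- lapply(seq_len(5), function(i) {
    call_roh_run_mode(sim$data$geno[i, ], sim$data$map, roh_params())
  })
  expect_equal(nrow(roh), sum(vapply(per_ind, nrow, integer(1))))
  gl <- glance(roh)
  expect_equal(gl$n_individuals, 5)
  expect_gte(gl$n_zero_roh, 2)  # the B individuals carry no planted segments

  # permuting individuals permutes rows only
  perm <- sim$data[c(3, 1, 2, 5, 4), ]
  roh_p <- detect_roh(perm)
  expect_equal(dplyr::arrange(tibble::as_tibble(roh_p), sample_id, chrom,
                              start_bp),
               dplyr::arrange(tibble::as_tibble(roh), sample_id, chrom,
                              start_bp),
               ignore_attr = TRUE)
})
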