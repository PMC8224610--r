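test_that("incidence counts individuals, not segments, and matches the oracle", {
  map <- make_map(30)
  # one of four individuals covered at SNPs 10..20
  roh <- make_roh_set(setNames(rep(list(numeric(0)), 4), paste0("s", 1:4)),
                      rep("P", 4))
  seg <- tibble::tibble(sample_id = "s1", population = "P", chrom = "1",
                        start_bp = map$pos_bp[10], end_bp = map$pos_bp[20],
                        start_idx = 10L, end_idx = 20L, n_snps = 11L,
                        n_het = 0L, n_missing = 0L,
                        length_bp = map$pos_bp[20] - map$pos_bp[10] + 1,
                        length_mb = NA_real_)
  roh1 <- rohscan:::as_roh_set(seg, attr(roh, "samples"), roh_params())
  tr <- roh_incidence(roh1, map)
  expect_equal(tr$incidence[10:20], rep(0.25, 11))
  expect_equal(tr$incidence[-(10:20)], rep(0, 19))

  # no ROH anywhere -> all zeros
  tr0 <- roh_incidence(roh, map)
  expect_equal(tr0$incidence, rep(0, 30))

  # random instance vs brute-force membership count
  set.seed(99)
  maps <- dplyr::bind_rows(make_map(40, chrom = "1"),
                           make_map(25, chrom = "2"))
  segs <- dplyr::bind_rows(lapply(1:6, function(i) {
    k <- sample(1:3, 1)
    ch <- sample(c("1", "2"), k, replace = TRUE)
    dplyr::bind_rows(lapply(seq_len(k), function(q) {
      pos <- maps$pos_bp[maps$chrom == ch[q]]
      ab <- sort(sample(pos, 2))
      tibble::tibble(sample_id = paste0("i", i), population = "P",
                     chrom = ch[q], start_bp = as.numeric(ab[1]),
                     end_bp = as.numeric(ab[2]))
    }))
  }))
  # drop overlaps within an individual to honour the disjointness invariant
  segs <- segs |>
    dplyr::group_by(sample_id, chrom) |>
    dplyr::arrange(start_bp, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() == 1 |
                    start_bp > dplyr::lag(cummax(end_bp),
                                          default = -Inf)) |>
    dplyr::ungroup()
  smp <- tibble::tibble(sample_id = paste0("i", 1:6), population = "P")
  tr2 <- roh_incidence(segs, maps, n_individuals = 6)
  expect_equal(tr2$incidence, oracle_incidence(segs, maps, 6))

  # invariance under permutation of individuals
  segs_perm <- segs[sample(nrow(segs)), ]
  tr3 <- roh_incidence(segs_perm, maps, n_individuals = 6)
  expect_equal(tr3$incidence, tr2$incidence)
})

test_that("percentile threshold is the linear-interpolation 99.9th percentile", {
  expect_equal(incidence_threshold(rep(0.3, 50)), 0.3)
  # 1000 values, one spike at 0.5: h = 1 + 999 * 0.999 = 999.001, so the
  # interpolated percentile is 0 + 0.001 * (0.5 - 0) = 5e-4 (hand-derived)
  x <- c(rep(0, 999), 0.5)
  expect_equal(incidence_threshold(x), 5e-4)
  set.seed(12)
  y <- runif(5000)
  expect_equal(incidence_threshold(y, q = 0.95),
               sort(y)[ceiling(0.95 * (5000 - 1))] +
                 (0.95 * (5000 - 1) - floor(0.95 * (5000 - 1))) *
                 diff(sort(y)[floor(0.95 * (5000 - 1)) + c(1, 2)]),
               tolerance = 1e-12)
})

test_that("island calling keeps >=min_consecutive runs and reports printed lengths", {
  # an isolated single above-threshold SNP is not an island
  map1 <- make_map(10)
  tr <- tibble::tibble(chrom = "1", marker_id = map1$marker_id,
                       pos_bp = map1$pos_bp,
                       incidence = c(rep(0, 4), 0.9, rep(0, 5)))
  expect_equal(nrow(call_roh_islands(tr, threshold = 0.5)), 0)

  # islands at the coordinates of the goat CHI07 and CHI06 regions
  mk_track <- function(chrom, start, end, n_in) {
    inner <- as.integer(seq(start, end, length.out = n_in))
    pos <- as.integer(c(start - 4e5, start - 2e5, inner, end + 2e5,
                        end + 4e5))
    tibble::tibble(chrom = chrom, marker_id = paste0(chrom, seq_along(pos)),
                   pos_bp = pos,
                   incidence = c(0.05, 0.05, rep(0.2, n_in), 0.05, 0.05))
  }
  track <- dplyr::bind_rows(mk_track("6", 35353261L, 38772649L, 20),
                            mk_track("7", 24117620L, 26089250L, 36))
  isl <- call_roh_islands(track, threshold = 0.16)
  expect_equal(nrow(isl), 2)
  chi7 <- isl[isl$chrom == "7", ]
  expect_equal(chi7$start_bp, 24117620L)
  expect_equal(chi7$end_bp, 26089250L)
  expect_equal(chi7$length_mb, 1.97)
  expect_equal(chi7$n_snps_above, 36L)
  chi6 <- isl[isl$chrom == "6", ]
  expect_equal(chi6$length_mb, 3.42)

  # island members are >= threshold, flanks below
  for (k in 1:2) {
    m <- track[track$chrom == isl$chrom[k], ]
    inside <- m$pos_bp >= isl$start_bp[k] & m$pos_bp <= isl$end_bp[k]
    expect_true(all(m$incidence[inside] >= 0.16))
    expect_true(all(m$incidence[!inside] < 0.16))
  }
})

test_that("raising the threshold never increases total island coverage", {
  set.seed(55)
  map <- make_map(400)
  tr <- tibble::tibble(chrom = "1", marker_id = map$marker_id,
                       pos_bp = map$pos_bp,
                       incidence = pmax(0, cumsum(rnorm(400, 0, 0.05))))
  cov_at <- function(th) {
    isl <- call_roh_islands(tr, threshold = th)
    sum(isl$end_bp - isl$start_bp + 1)
  }
  ths <- sort(runif(6, 0, max(tr$incidence)))
  covs <- vapply(ths, cov_at, numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("gene annotation overlaps by >=1 bp and excludes abutting intervals", {
  isl <- tibble::tibble(chrom = c("5", "7"),
                        start_bp = c(1000L, 5000L),
                        end_bp = c(2000L, 6000L),
                        n_snps_above = c(10L, 10L),
                        peak_incidence = c(0.2, 0.2),
                        length_mb = c(0.001, 0.001))
  ann <- tibble::tibble(
    chrom = c("5", "5", "5", "5", "7"),
    start_bp = c(500L, 1990L, 2001L, 1500L, 100L),
    end_bp = c(1000L, 2100L, 2500L, 1600L, 200L),
    name = c("touch_left", "cross_right", "abut_right", "inside", "elsewhere"))
  out <- annotate_islands(isl, ann)
  expect_equal(out$genes[[1]], c("touch_left", "inside", "cross_right"))
  expect_equal(out$genes[[2]], character(0))
})
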