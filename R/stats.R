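#' ROH length classes
#'
#' Bins segment lengths into the four conventional classes 2 to <=4,
#' 4 to <=8, 8 to <=16 and >16 Mb (left-open, right-closed; a segment of
#' exactly 4 Mb falls in the lower class). Short ROH trace ancient
#' inbreeding, long ROH recent inbreeding.
#'
#' @param length_mb Numeric vector of segment lengths in Mb.
#' @param boundaries Inner class boundaries in Mb (default `c(2, 4, 8, 16)`;
#'   the last class is open-ended).
#' @return Ordered factor with levels like `"2-4"`, `"4-8"`, `"8-16"`,
#'   `">16"`.
#' @export
roh_length_class <- function(length_mb, boundaries = c(2, 4, 8, 16)) {
  stopifnot(length(boundaries) >= 2, all(diff(boundaries) > 0))
  k <- length(boundaries)
  labels <- c(paste(boundaries[-k], boundaries[-1], sep = "-"),
              paste0(">", boundaries[k]))
  cut(length_mb, breaks = c(boundaries, Inf), labels = labels,
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

#' Per-individual genomic inbreeding coefficient F_ROH
#'
#' F_ROH = L_ROH / L_aut: the summed length of an individual's ROH divided
#' by the length of the autosomal genome. Individuals without any ROH are
#' included with F_ROH = 0.
#'
#' @param roh A `roh_set` from [detect_roh()] (or any segment tibble with
#'   `sample_id` and `length_bp`).
#' @param laut_bp Autosomal genome length in bp (default 2.45e9, i.e.
#'   2450 Mb for the goat autosomes).
#' @param samples Optional sample table overriding the one attached to
#'   `roh`; required to account for zero-ROH individuals if `roh` carries
#'   no attached sample table.
#' @return Tibble with one row per individual: `sample_id`, `population`,
#'   `n_segments`, `l_roh_bp`, `froh`.
#' @export
roh_froh <- function(roh, laut_bp = 2.45e9, samples = NULL) {
  stopifnot(laut_bp > 0)
  samples <- roh_samples(roh, samples)
  per <- tibble::as_tibble(roh) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_segments = dplyr::n(),
                     l_roh_bp = sum(.data$length_bp), .groups = "drop")
  samples |>
    dplyr::left_join(per, by = "sample_id") |>
    dplyr::mutate(
      n_segments = dplyr::coalesce(.data$n_segments, 0L),
      l_roh_bp = dplyr::coalesce(.data$l_roh_bp, 0),
      froh = .data$l_roh_bp / laut_bp
    )
}

#' Population-level ROH summary
#'
#' One row per population with the descriptive statistics conventionally
#' reported for SNP-array ROH scans: cohort size, number of individuals
#' without any ROH, total (TN_ROH) and mean (MN_ROH = TN_ROH / n) segment
#' counts, average segment length AL_ROH (mean over all segments pooled
#' within the population; the mean of per-individual averages is also
#' given), and mean and standard deviation of individual F_ROH. Zero-ROH
#' individuals stay in every denominator except the per-carrier average.
#'
#' @inheritParams roh_froh
#' @return Tibble with columns `population`, `n_individuals`, `n_zero_roh`,
#'   `tn_roh`, `mn_roh`, `al_roh_mb`, `al_roh_carrier_mb`, `froh_mean`,
#'   `froh_sd`.
#' @export
roh_population_summary <- function(roh, laut_bp = 2.45e9, samples = NULL) {
  fr <- roh_froh(roh, laut_bp, samples)
  seg <- tibble::as_tibble(roh)
  per_pop_seg <- seg |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(tn_roh = dplyr::n(),
                     al_roh_mb = mean(.data$length_mb), .groups = "drop")
  per_carrier <- seg |>
    dplyr::group_by(.data$population, .data$sample_id) |>
    dplyr::summarise(m = mean(.data$length_mb), .groups = "drop_last") |>
    dplyr::summarise(al_roh_carrier_mb = mean(.data$m), .groups = "drop")
  fr |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      n_zero_roh = sum(.data$n_segments == 0L),
      froh_mean = mean(.data$froh),
      froh_sd = sd(.data$froh),
      .groups = "drop"
    ) |>
    dplyr::left_join(per_pop_seg, by = "population") |>
    dplyr::left_join(per_carrier, by = "population") |>
    dplyr::mutate(
      tn_roh = dplyr::coalesce(.data$tn_roh, 0L),
      mn_roh = .data$tn_roh / .data$n_individuals
    ) |>
    dplyr::select("population", "n_individuals", "n_zero_roh", "tn_roh",
                  "mn_roh", "al_roh_mb", "al_roh_carrier_mb",
                  "froh_mean", "froh_sd")
}

#' Length-class decomposition of ROH counts per population
#'
#' Counts segments per length class within each population, with the
#' within-population frequency (class count / total count). Classes with no
#' segments are kept with zero counts.
#'
#' @inheritParams roh_froh
#' @param boundaries Class boundaries, see [roh_length_class()].
#' @return Tibble: `population`, `class`, `n`, `freq`.
#' @export
roh_length_classes <- function(roh, boundaries = c(2, 4, 8, 16)) {
  seg <- tibble::as_tibble(roh)
  seg$class <- roh_length_class(seg$length_mb, boundaries)
  seg |>
    dplyr::count(.data$population, .data$class, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Mean per-individual ROH coverage by length class
#'
#' For each population and length class: the mean over individuals of the
#' summed length (Mb) of that individual's segments in the class.
#' Individuals without segments in a class contribute zero, so the class
#' means add up to the population's mean total ROH coverage.
#'
#' @inheritParams roh_froh
#' @param boundaries Class boundaries, see [roh_length_class()].
#' @return Tibble: `population`, `class`, `mean_mb`.
#' @export
roh_class_coverage <- function(roh, samples = NULL,
                               boundaries = c(2, 4, 8, 16)) {
  samples <- roh_samples(roh, samples)
  n_pop <- dplyr::count(samples, .data$population, name = "n_individuals")
  seg <- tibble::as_tibble(roh)
  seg$class <- roh_length_class(seg$length_mb, boundaries)
  lev <- levels(roh_length_class(numeric(0), boundaries))
  combos <- tidyr::expand_grid(
    population = n_pop$population,
    class = factor(lev, levels = lev, ordered = TRUE))
  seg |>
    dplyr::group_by(.data$population, .data$class) |>
    dplyr::summarise(total_mb = sum(.data$length_mb), .groups = "drop") |>
    dplyr::right_join(combos, by = c("population", "class")) |>
    dplyr::mutate(total_mb = dplyr::coalesce(.data$total_mb, 0)) |>
    dplyr::inner_join(n_pop, by = "population") |>
    dplyr::mutate(mean_mb = .data$total_mb / .data$n_individuals) |>
    dplyr::arrange(.data$population, .data$class) |>
    dplyr::select("population", "class", "mean_mb")
}

#' Per-individual totals: segment count vs summed length
#'
#' The data behind the classic "number of ROH against total length"
#' scatter. Zero-ROH individuals appear at (0, 0).
#'
#' @inheritParams roh_froh
#' @return Tibble: `sample_id`, `population`, `n_segments`,
#'   `total_length_mb`.
#' @export
roh_individual_totals <- function(roh, samples = NULL) {
  roh_froh(roh, laut_bp = 2.45e9, samples = samples) |>
    dplyr::mutate(total_length_mb = .data$l_roh_bp / 1e6) |>
    dplyr::select("sample_id", "population", "n_segments", "total_length_mb")
}
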