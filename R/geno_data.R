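#' Assemble a genotype dataset
#'
#' Bundles a coded genotype matrix with its marker map and sample table.
#' This is the container every pipeline stage consumes: rows of `geno` are
#' individuals (matching `samples`), columns are markers (matching `map`).
#'
#' Genotypes are coded by the count of the alternate (B) allele:
#' `0` = homozygous A, `1` = heterozygous, `2` = homozygous B, `NA` = missing.
#' Allele letters are deliberately not retained: run-of-homozygosity analysis
#' operates purely on zygosity.
#'
#' @param geno Integer matrix, individuals x markers, values in
#'   \{0, 1, 2, NA\}.
#' @param map Data frame with columns `chrom` (character), `marker_id`
#'   (unique character) and `pos_bp` (positive integer, 1-based), sorted by
#'   chromosome then position, positions strictly increasing within a
#'   chromosome.
#' @param samples Data frame with columns `sample_id` (unique character) and
#'   `population` (character label).
#'
#' @return An object of class `geno_data`: a list with elements `geno`,
#'   `map` (tibble) and `samples` (tibble).
#' @export
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), nrow = 2)
#' map <- data.frame(chrom = "1", marker_id = c("m1", "m2"),
#'                   pos_bp = c(100L, 200L))
#' smp <- data.frame(sample_id = c("s1", "s2"), population = "POP")
#' geno_data(g, map, smp)
geno_data <- function(geno, map, samples) {
  map <- tibble::as_tibble(map)
  samples <- tibble::as_tibble(samples)
  stopifnot(is.matrix(geno))
  storage.mode(geno) <- "integer"
  if (!all(c("chrom", "marker_id", "pos_bp") %in% names(map))) {
    abort("`map` needs columns chrom, marker_id, pos_bp")
  }
  if (!all(c("sample_id", "population") %in% names(samples))) {
    abort("`samples` needs columns sample_id, population")
  }
  map$chrom <- as.character(map$chrom)
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)
  if (nrow(map) != ncol(geno)) {
    abort(sprintf("map has %d markers but genotype matrix has %d columns",
                  nrow(map), ncol(geno)))
  }
  if (nrow(samples) != nrow(geno)) {
    abort(sprintf("sample table has %d rows but genotype matrix has %d rows",
                  nrow(samples), nrow(geno)))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (anyDuplicated(map$marker_id)) abort("duplicate marker_id")
  bad <- !(geno %in% GENO_CODES | is.na(geno))
  if (any(bad)) abort("genotype codes must be 0, 1, 2 or NA")
  validate_map_sorted(map)
  rownames(geno) <- samples$sample_id
  colnames(geno) <- map$marker_id
  structure(list(geno = geno, map = map, samples = samples),
            class = "geno_data")
}

validate_map_sorted <- function(map) {
  if (nrow(map) < 2) return(invisible(TRUE))
  # unknown positions (<= 0) are tolerated pre-QC and ignored here
  known <- map[!is.na(map$pos_bp) & map$pos_bp > 0, ]
  grp <- split(known$pos_bp, factor(known$chrom, levels = unique(known$chrom)))
  ok <- vapply(grp, function(p) all(diff(p) > 0), logical(1))
  if (!all(ok)) {
    abort(sprintf(
      "marker map not sorted: positions not strictly increasing on chromosome %s",
      names(grp)[!ok][1]))
  }
  invisible(TRUE)
}

#' @export
print.geno_data <- function(x, ...) {
  cat(sprintf("<geno_data> %d individuals x %d markers\n",
              nrow(x$geno), ncol(x$geno)))
  cat(sprintf("  chromosomes: %d (%s)\n", length(unique(x$map$chrom)),
              paste(utils::head(unique(x$map$chrom), 5), collapse = ", ")))
  pops <- table(x$samples$population)
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d)", names(pops), pops), collapse = ", ")))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x A [geno_data()] object.
#' @param i Individual (row) index, logical or integer.
#' @param j Marker (column) index, logical or integer.
#' @param ... Unused.
#' @return A `geno_data` with the selected individuals/markers.
#' @export
`[.geno_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  geno_data(x$geno[i, j, drop = FALSE], x$map[j, , drop = FALSE],
            x$samples[i, , drop = FALSE])
}
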