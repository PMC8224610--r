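#' Read genotypes from PED/MAP files
#'
#' Parses a whitespace-delimited PED file (one individual per line: family,
#' individual, father, mother, sex, phenotype, then two allele columns per
#' marker) together with its 4-column MAP file (chromosome, marker id,
#' genetic position, bp position).
#'
#' Alleles are collapsed to zygosity codes at read time. Per marker, the
#' ASCII-larger of the two observed alleles is taken as the alternate (B)
#' allele and counted, so a genotype becomes 0 (hom A), 1 (het) or 2
#' (hom B); the pair `0 0` is a missing call. When a marker shows a single
#' allele across the whole file its homozygotes are coded 0 — for markers
#' whose only calls are the alternate homozygote this flips the (immaterial)
#' allele labels; zygosity, allele frequency and IBS are unaffected.
#'
#' The individual id column becomes `sample_id` and the family id column is
#' used as the `population` label, the usual convention for multi-breed
#' panels.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [geno_data()] object.
#' @seealso [write_ped_map()]
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_raw <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map_raw) != 4) {
    abort(sprintf("MAP file must have 4 columns, found %d", ncol(map_raw)))
  }
  map <- tibble::tibble(
    chrom = map_raw[[1]],
    marker_id = map_raw[[2]],
    pos_bp = as.integer(map_raw[[4]])
  )
  n_mark <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(toks)
  expected <- 6 + 2 * n_mark
  if (any(lens != expected)) {
    bad <- which(lens != expected)[1]
    if (length(unique(lens)) > 1) {
      abort(sprintf("ragged PED file: line %d has %d fields, expected %d",
                    bad, lens[bad], expected))
    }
    abort(sprintf(
      "PED/MAP mismatch: PED lines carry %d allele columns (%d markers), MAP lists %d markers",
      lens[1] - 6, (lens[1] - 6) %/% 2, n_mark))
  }
  ped <- do.call(rbind, toks)
  samples <- tibble::tibble(sample_id = ped[, 2], population = ped[, 1])

  a1 <- ped[, 6 + 2 * seq_len(n_mark) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(n_mark), drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_mark)
  for (j in seq_len(n_mark)) {
    geno[, j] <- code_alleles(a1[, j], a2[, j])
  }
  geno_data(geno, map, samples)
}

# Collapse one marker's allele pairs to 0/1/2/NA. B allele = ASCII-larger
# observed allele; "0" marks a missing allele.
code_alleles <- function(a1, a2) {
  miss <- a1 == "0" | a2 == "0"
  obs <- sort(unique(c(a1[!miss], a2[!miss])))
  if (length(obs) > 2) {
    abort(sprintf("marker with >2 alleles: %s", paste(obs, collapse = "/")))
  }
  b <- if (length(obs) == 2) obs[2] else ""  # never matches
  out <- (a1 == b) + (a2 == b)
  out[miss] <- NA_integer_
  as.integer(out)
}

#' Write genotypes to PED/MAP files
#'
#' Inverse of [read_ped_map()]: code 0 is written as `A A`, 1 as `A B`,
#' 2 as `B B` and missing as `0 0`; the MAP genetic-distance column is 0.
#'
#' @param data A [geno_data()] object.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `data`.
#' @export
write_ped_map <- function(data, ped_path, map_path) {
  stopifnot(inherits(data, "geno_data"))
  map <- data$map
  write.table(
    data.frame(map$chrom, map$marker_id, 0, map$pos_bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)

  pair <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  g <- data$geno
  txt <- matrix("0 0", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  txt[ok] <- pair[as.character(g[ok])]
  lead <- sprintf("%s %s 0 0 0 -9", data$samples$population,
                  data$samples$sample_id)
  writeLines(paste(lead, apply(txt, 1, paste, collapse = " ")), ped_path)
  invisible(data)
}
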