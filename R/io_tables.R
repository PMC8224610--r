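#' Write a ROH segment table
#'
#' Writes segments in a `.hom`-style tab-separated table with columns
#' `sample_id, population, chrom, start_bp, end_bp, n_snps, length_mb`
#' (coordinates 1-based inclusive, `length_mb = (end - start + 1) / 1e6`).
#'
#' @param roh A ROH segment tibble, e.g. from [detect_roh()].
#' @param path Output path.
#' @return Invisibly, the tibble as written.
#' @export
write_roh_table <- function(roh, path) {
  out <- tibble::tibble(
    sample_id = roh$sample_id,
    population = roh$population,
    chrom = roh$chrom,
    start_bp = roh$start_bp,
    end_bp = roh$end_bp,
    n_snps = roh$n_snps,
    length_mb = (roh$end_bp - roh$start_bp + 1) / 1e6
  )
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(out)
}

#' Read a ROH segment table written by [write_roh_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with the seven `.hom`-style columns.
#' @export
read_roh_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(sample_id = "character",
                                   population = "character",
                                   chrom = "character"))
  tibble::as_tibble(tab)
}

#' Write ROH islands as a BED file
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the start is shifted down by one and the end is written unchanged. The
#' BED name column carries the comma-separated gene list (`.` when empty).
#'
#' @param islands Island tibble from [call_roh_islands()] /
#'   [annotate_islands()].
#' @param path Output path.
#' @return Invisibly, `islands`.
#' @export
write_islands_bed <- function(islands, path) {
  if (nrow(islands) > 0) {
    by_chr <- split(islands[order(islands$start_bp), ], islands$chrom)
    for (isl in by_chr) {
      if (nrow(isl) > 1 &&
          any(isl$start_bp[-1] <= isl$end_bp[-nrow(isl)])) {
        abort(sprintf("overlapping islands on chromosome %s", isl$chrom[1]))
      }
    }
  }
  name <- if ("genes" %in% names(islands)) {
    vapply(islands$genes, function(g) {
      if (length(g) == 0) "." else paste(g, collapse = ",")
    }, character(1))
  } else {
    rep(".", nrow(islands))
  }
  bed <- data.frame(chrom = islands$chrom,
                    start = islands$start_bp - 1L,
                    end = islands$end_bp,
                    name = name)
  write.table(bed, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(islands)
}

#' Read a BED file of islands back to 1-based coordinates
#'
#' Exact inverse of [write_islands_bed()] for the coordinate columns.
#'
#' @param path Path to a BED3+ file.
#' @return Tibble with `chrom`, `start_bp`, `end_bp` (1-based inclusive) and
#'   a `genes` list-column parsed from the name field.
#' @export
read_islands_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(chrom = character(), start_bp = integer(),
                          end_bp = integer(), genes = list()))
  }
  bed <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  genes <- if (ncol(bed) >= 4) {
    lapply(strsplit(bed[[4]], ","), function(g) g[g != "."])
  } else {
    rep(list(character()), nrow(bed))
  }
  tibble::tibble(
    chrom = bed[[1]],
    start_bp = as.integer(bed[[2]]) + 1L,
    end_bp = as.integer(bed[[3]]),
    genes = genes
  )
}

#' Read a gene annotation file (BED or GFF3)
#'
#' Loads named genomic intervals for island annotation. BED input (0-based
#' half-open, name in column 4) is shifted to 1-based inclusive; GFF3 input
#' (already 1-based) keeps rows of type `gene` (all rows if none are typed
#' `gene`) and takes the name from the `Name=`, `gene=` or `ID=` attribute.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Tibble with columns `chrom`, `start_bp`, `end_bp`, `name`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    bed <- read.table(path, header = FALSE, sep = "\t",
                      colClasses = "character")
    if (ncol(bed) < 4) abort("annotation BED needs a name column (4 columns)")
    return(tibble::tibble(chrom = bed[[1]],
                          start_bp = as.integer(bed[[2]]) + 1L,
                          end_bp = as.integer(bed[[3]]),
                          name = bed[[4]]))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t")
  keep <- vapply(f, function(x) length(x) >= 9, logical(1))
  f <- f[keep]
  type <- vapply(f, `[[`, character(1), 3)
  if (any(type == "gene")) f <- f[type == "gene"]
  attr_name <- function(attrs) {
    for (key in c("Name=", "gene=", "ID=")) {
      m <- regmatches(attrs, regexpr(paste0(key, "[^;]+"), attrs))
      if (length(m) == 1) return(sub(key, "", m))
    }
    NA_character_
  }
  tibble::tibble(
    chrom = vapply(f, `[[`, character(1), 1),
    start_bp = as.integer(vapply(f, `[[`, character(1), 4)),
    end_bp = as.integer(vapply(f, `[[`, character(1), 5)),
    name = vapply(f, function(x) attr_name(x[[9]]), character(1))
  )
}
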