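#' Run the full homozygosity analysis and write a report bundle
#'
#' One call reproducing the complete workflow on any PED/MAP input or
#' in-memory dataset: quality control, ROH detection, per-population and
#' length-class summaries, per-individual totals, meta-population ROH
#' islands with optional gene annotation, and IBS/MDS coordinates. All
#' outputs are plain-text TSV/JSON files written to `out_dir`:
#'
#' * `qc_report.json` — marker/sample attrition and thresholds
#' * `roh_segments.tsv` — the called segments (`.hom`-style)
#' * `table1.tsv` — population summary (TN_ROH, MN_ROH, AL_ROH, F_ROH)
#' * `table2.tsv` — length-class counts and frequencies
#' * `fig2_data.tsv` — mean ROH coverage per class and population
#' * `fig3_data.tsv` — per-individual count vs total length
#' * `incidence.tsv`, `islands.tsv`, `islands.bed` — island scan
#' * `mds.tsv` — MDS coordinates with population labels
#' * `run_log.txt` — parameters and package version
#'
#' The pipeline is deterministic: rerunning on the same input with the
#' same settings reproduces every file byte for byte.
#'
#' @param data A [geno_data()]; alternatively give `ped_path`/`map_path`.
#' @param ped_path,map_path PED/MAP input, read with [read_ped_map()] when
#'   `data` is not supplied.
#' @param out_dir Output directory (created if needed).
#' @param annotation_path Optional BED/GFF3 gene annotation for island
#'   annotation, see [read_gene_annotation()].
#' @param params [roh_params()] for the caller.
#' @param mode Caller mode, `"run"` or `"window"`.
#' @param laut_bp Autosome length for F_ROH (default 2450 Mb).
#' @param maf_cut,callrate_cut,max_missing QC thresholds, see [run_qc()].
#' @param q Island percentile level (default 0.999).
#' @param island_threshold Fixed island threshold overriding the
#'   percentile-derived one.
#' @param min_consecutive Minimum SNPs per island.
#' @param do_islands,do_mds Stage switches.
#' @return Invisibly, a list with every intermediate result (`qc`, `roh`,
#'   `summary`, `classes`, `coverage`, `totals`, `incidence`, `threshold`,
#'   `islands`, `mds`).
#' @export
run_roh_pipeline <- function(data = NULL, ped_path = NULL, map_path = NULL,
                             out_dir, annotation_path = NULL,
                             params = roh_params(), mode = "run",
                             laut_bp = 2.45e9, maf_cut = 0.02,
                             callrate_cut = 0.98, max_missing = 0.05,
                             q = 0.999, island_threshold = NULL,
                             min_consecutive = 2, do_islands = TRUE,
                             do_mds = TRUE) {
  stage <- "input"
  result <- tryCatch({
    if (is.null(data)) {
      if (is.null(ped_path) || is.null(map_path)) {
        abort("supply `data` or both `ped_path` and `map_path`")
      }
      data <- read_ped_map(ped_path, map_path)
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(x, f) {
      write.table(x, file.path(out_dir, f), quote = FALSE, sep = "\t",
                  row.names = FALSE)
    }

    stage <- "quality control"
    qcd <- run_qc(data, maf_cut, callrate_cut, max_missing)
    write_qc_report(qc_report(qcd), file.path(out_dir, "qc_report.json"))

    stage <- "ROH detection"
    roh <- detect_roh(qcd, params, mode = mode)
    write_roh_table(roh, file.path(out_dir, "roh_segments.tsv"))

    stage <- "summary statistics"
    summary <- roh_population_summary(roh, laut_bp)
    classes <- roh_length_classes(roh)
    coverage <- roh_class_coverage(roh)
    totals <- roh_individual_totals(roh)
    tsv(summary, "table1.tsv")
    tsv(classes, "table2.tsv")
    tsv(coverage, "fig2_data.tsv")
    tsv(totals, "fig3_data.tsv")

    incidence <- NULL; threshold <- NULL; islands <- NULL
    if (do_islands) {
      stage <- "island scan"
      incidence <- roh_incidence(roh, qcd$map)
      threshold <- if (is.null(island_threshold)) {
        incidence_threshold(incidence, q)
      } else island_threshold
      islands <- call_roh_islands(incidence, threshold = threshold,
                                  min_consecutive = min_consecutive)
      if (!is.null(annotation_path)) {
        islands <- annotate_islands(islands,
                                    read_gene_annotation(annotation_path))
      }
      tsv(tibble::as_tibble(incidence), "incidence.tsv")
      isl_flat <- islands
      isl_flat$genes <- NULL
      tsv(isl_flat, "islands.tsv")
      write_islands_bed(islands, file.path(out_dir, "islands.bed"))
    }

    mds <- NULL
    if (do_mds) {
      stage <- "MDS"
      mds <- mds_ibs(qcd, k = 2)
      tsv(tidy(mds), "mds.tsv")
    }

    stage <- "report"
    log_lines <- c(
      sprintf("rohscan %s", as.character(utils::packageVersion("rohscan"))),
      sprintf("individuals in/out: %d/%d", qc_report(qcd)$n_samples_in,
              qc_report(qcd)$n_samples_out),
      sprintf("markers in/out: %d/%d", qc_report(qcd)$n_markers_in,
              qc_report(qcd)$n_markers_out),
      sprintf("mode: %s", mode),
      sprintf("params: min_length_mb=%g min_snps=%d max_het=%d max_missing=%d density=%g gap=%g",
              params$min_length_mb, params$min_snps, params$max_het,
              params$max_missing, params$min_density_kb_per_snp,
              params$max_gap_kb),
      sprintf("laut_bp: %g", laut_bp),
      if (do_islands) sprintf("island threshold: %.6g", threshold)
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))

    list(qc = qc_report(qcd), data = qcd, roh = roh, summary = summary,
         classes = classes, coverage = coverage, totals = totals,
         incidence = incidence, threshold = threshold, islands = islands,
         mds = mds)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
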