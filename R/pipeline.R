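#' @title End-to-end pipeline driver
#'
#' @description
#' Binds the stages (count or load counts, call, classify, annotate) into
#' one reproducible run that writes TSV artifacts plus a JSON manifest
#' recording the package version, seed and thresholds. The command-line
#' wrapper in `inst/cli/mtac.R` is a thin shell over these functions.
#'
#' @name pipeline
NULL

#' Run the single-viewpoint pipeline
#'
#' Stages: load NDRs and counts (or fragments), differential methylation,
#' interaction calling at the double threshold, classification relative to
#' the viewpoint, and (when peaks are given) NPC-style association and
#' enrichment. Artifacts: `volcano.tsv` (per-NDR statistics),
#' `calls.tsv` (classified calls), `enrichment.tsv` (when peaks given),
#' `manifest.json`.
#'
#' @param ndr_bed path to the NDR BED file.
#' @param chrom_sizes_path path to the chromosome sizes TSV.
#' @param counts_path,design_path counts matrix TSV and design TSV (see
#'   [read_counts()]); alternative to `fragments_path`.
#' @param fragments_path 4-column fragment BED (alternative to counts).
#' @param vp optional [viewpoint()] or path to a viewpoint TSV with
#'   columns name, chrom, start, end.
#' @param peaks_path optional peak BED for association annotation.
#' @param out_dir output directory.
#' @param lfc_min,padj_max calling thresholds (defaults 0.7, 0.05).
#' @param far_cis_min far-cis distance threshold (bp).
#' @param seed integer seed recorded in the manifest (the deterministic
#'   stages do not consume it).
#' @return list with elements `results`, `calls`, `enrichment` (or NULL)
#'   and `manifest`, invisibly; artifacts are written to `out_dir`.
#' @export
run_pipeline <- function(ndr_bed, chrom_sizes_path, counts_path = NULL,
                         design_path = NULL, fragments_path = NULL,
                         vp = NULL, peaks_path = NULL, out_dir,
                         lfc_min = 0.7, padj_max = 0.05,
                         far_cis_min = 30000, seed = 1) {
  for (p in c(ndr_bed, chrom_sizes_path, counts_path, design_path,
    fragments_path, peaks_path)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  }
  if (is.null(counts_path) && is.null(fragments_path)) {
    stop("need either counts + design or fragments")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- read_chrom_sizes(chrom_sizes_path)
  ndrs <- read_bed(ndr_bed, sizes, as = "ndr")
  counts <- if (!is.null(counts_path)) {
    if (is.null(design_path)) stop("counts input needs a design TSV")
    read_counts(counts_path, design_path)
  } else {
    count_fragments(read_fragments(fragments_path), ndrs)
  }
  if (is.character(vp)) {
    vtab <- utils::read.table(vp, sep = "\t", header = TRUE,
      stringsAsFactors = FALSE)
    vp <- viewpoint(vtab$name[1L], vtab$chrom[1L], vtab$start[1L],
      vtab$end[1L], sizes)
  }
  results <- diff_methylation(counts, ndrs = ndrs)
  calls <- call_interactions(results, lfc_min = lfc_min,
    padj_max = padj_max, vp = vp, ndrs = ndrs)
  if (!is.null(vp)) {
    calls <- classify_interactions(calls, vp, far_cis_min = far_cis_min)
  }
  utils::write.table(results, file.path(out_dir, "volcano.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(out_dir, "calls.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  enrichment <- NULL
  if (!is.null(peaks_path)) {
    peaks <- read_bed(peaks_path, as = "peaks")
    flags <- associate_by_intersection(ndrs, peaks)
    fg <- calls$ndr_id
    if (!is.null(calls$class)) {
      fg <- calls$ndr_id[calls$class %in% c("far_cis", "trans")]
    }
    enrichment <- enrichment_ztest(sum(flags[fg]), max(length(fg), 1L),
      sum(flags), length(flags))
    utils::write.table(
      data.frame(k_fg = enrichment$k_fg, n_fg = enrichment$n_fg,
        k_bg = enrichment$k_bg, n_bg = enrichment$n_bg,
        fraction_fg = enrichment$fraction_fg,
        fraction_bg = enrichment$fraction_bg,
        z = enrichment$z, pvalue = enrichment$pvalue),
      file.path(out_dir, "enrichment.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  manifest <- list(
    package = "mtacr",
    version = as.character(utils::packageVersion("mtacr")),
    seed = seed,
    thresholds = list(lfc_min = lfc_min, padj_max = padj_max,
      far_cis_min = far_cis_min),
    inputs = list(ndr_bed = ndr_bed, chrom_sizes = chrom_sizes_path,
      counts = counts_path, design = design_path,
      fragments = fragments_path, peaks = peaks_path),
    n_ndrs = nrow(ndrs), n_tested = nrow(results), n_called = nrow(calls),
    status = "ok"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, calls = calls,
    enrichment = enrichment, manifest = manifest))
}
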