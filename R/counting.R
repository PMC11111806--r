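#' Assemble a per-NDR count container
#'
#' Light-weight container (in the spirit of edgeR's `DGEList`) holding the
#' integer fragments-per-NDR matrix, the sample table and per-sample
#' library sizes.
#'
#' @param counts integer matrix, rows = NDR ids (rownames required),
#'   columns = samples.
#' @param group character/factor of length `ncol(counts)` with values
#'   `"targeted"` or `"control"`.
#' @param lib_size per-sample total fragment counts; defaults to column
#'   sums of `counts`.
#' @return list of class `"mtac_counts"` with elements `counts`, `samples`
#'   (data.frame `sample_id`, `group`, `replicate`) and `lib_size`.
#' @export
mtac_counts <- function(counts, group, lib_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have NDR ids as rownames")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  group <- as.character(group)
  if (length(group) != ncol(counts)) {
    stop("group must have one label per sample")
  }
  if (!all(group %in% c("targeted", "control"))) {
    stop("group labels must be 'targeted' or 'control'")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!all(c("targeted", "control") %in% group)) {
    stop("need at least one sample per group")
  }
  replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  samples <- data.frame(sample_id = colnames(counts), group = group,
    replicate = replicate, stringsAsFactors = FALSE)
  lib_size <- as.numeric(lib_size)
  if (length(lib_size) != ncol(counts)) {
    stop("lib_size must have one entry per sample")
  }
  names(lib_size) <- colnames(counts)
  structure(list(counts = counts, samples = samples, lib_size = lib_size),
    class = "mtac_counts")
}

#' @export
print.mtac_counts <- function(x, ...) {
  cat("mtac_counts: ", nrow(x$counts), " NDRs x ", ncol(x$counts),
    " samples (", sum(x$samples$group == "targeted"), " targeted, ",
    sum(x$samples$group == "control"), " control)\n", sep = "")
  invisible(x)
}

#' Count fragments over NDRs
#'
#' Integrates per-fragment methylation evidence over each NDR. A fragment
#' increments the count of *every* NDR it overlaps by at least one base
#' (featureCounts `-O` multi-overlap semantics), and counting is per
#' fragment, not per read (`-p` semantics: each fragment is the outer span
#' of a properly paired mate pair). Library size is the total number of
#' input fragments per sample, including fragments assigned to no NDR.
#'
#' Fragments on chromosomes absent from the annotation are counted toward
#' the library size, warned about, and assigned to no NDR.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`,
#'   `sample` (0-based half-open outer spans).
#' @param ndrs an [ndr_annotation()].
#' @param group named vector mapping sample id to `"targeted"`/`"control"`;
#'   when `NULL`, sample ids starting with `"targeted"`/`"control"` are
#'   used directly.
#' @return [mtac_counts()] object.
#' @export
count_fragments <- function(fragments, ndrs, group = NULL) {
  validate_intervals(fragments, what = "fragment")
  if (is.null(fragments$sample)) stop("fragments need a 'sample' column")
  samples <- unique(as.character(fragments$sample))
  lib_size <- table(factor(fragments$sample, levels = samples))
  known <- fragments$chrom %in% unique(ndrs$chrom)
  if (!all(known)) {
    warning(sum(!known), " fragment(s) on chromosomes absent from the ",
      "NDR annotation; counted toward library size only")
  }
  fr <- fragments[known, , drop = FALSE]
  counts <- matrix(0L, nrow = nrow(ndrs), ncol = length(samples),
    dimnames = list(ndrs$ndr_id, samples))
  if (nrow(fr) > 0L) {
    hits <- GenomicRanges::findOverlaps(.as_granges(fr), .as_granges(ndrs),
      minoverlap = 1L)
    if (length(hits) > 0L) {
      tab <- table(
        factor(ndrs$ndr_id[S4Vectors::subjectHits(hits)],
          levels = ndrs$ndr_id),
        factor(as.character(fr$sample)[S4Vectors::queryHits(hits)],
          levels = samples)
      )
      counts <- counts + unclass(tab)
    }
  }
  if (is.null(group)) {
    group <- ifelse(grepl("^targeted", samples), "targeted",
      ifelse(grepl("^control", samples), "control", NA_character_))
    if (anyNA(group)) {
      stop("cannot infer group from sample ids; supply 'group'")
    }
    names(group) <- samples
  }
  mtac_counts(counts, group = unname(group[samples]),
    lib_size = as.numeric(lib_size))
}

#' Counts per million
#'
#' Depth-normalizes a count matrix: `counts[i, j] * 1e6 / lib_size[j]`.
#'
#' @param x an [mtac_counts()] object.
#' @return numeric matrix of the same dimensions.
#' @export
cpm <- function(x) {
  stopifnot(inherits(x, "mtac_counts"))
  if (any(x$lib_size <= 0)) stop("zero library size")
  sweep(x$counts, 2, x$lib_size, "/") * 1e6
}

#' Read a fragment BED file
#'
#' Four-column fragment format: chrom, start, end, sample id.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `sample`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
    stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("fragment BED needs 4 columns (chrom, start, end, sample)")
  out <- data.frame(chrom = as.character(tab[[1L]]),
    start = as.numeric(tab[[2L]]), end = as.numeric(tab[[3L]]),
    sample = as.character(tab[[4L]]), stringsAsFactors = FALSE)
  validate_intervals(out, what = "fragment")
  out
}

#' Write a counts TSV (NDR rows, sample columns)
#' @param x an [mtac_counts()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "mtac_counts"))
  df <- data.frame(ndr_id = rownames(x$counts), x$counts,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV plus a design table
#'
#' @param counts_path TSV with an `ndr_id` column and one integer column
#'   per sample.
#' @param design_path TSV with columns `sample_id` and `group`
#'   (targeted/control); optional `lib_size`.
#' @return [mtac_counts()] object.
#' @export
read_counts <- function(counts_path, design_path) {
  tab <- utils::read.table(counts_path, sep = "\t", header = TRUE,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!"ndr_id" %in% names(tab)) stop("counts TSV needs an 'ndr_id' column")
  design <- utils::read.table(design_path, sep = "\t", header = TRUE,
    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design TSV needs 'sample_id' and 'group' columns")
  }
  m <- as.matrix(tab[, design$sample_id, drop = FALSE])
  rownames(m) <- tab$ndr_id
  ls <- if ("lib_size" %in% names(design)) design$lib_size else colSums(m)
  mtac_counts(m, group = design$group, lib_size = ls)
}

#' Write per-sample CPM bedGraph tracks
#'
#' One bedGraph per sample, named `<prefix>.<sample>.bedGraph`, with the
#' NDR intervals as features.
#'
#' @param x an [mtac_counts()] object.
#' @param ndrs the matching [ndr_annotation()].
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
write_cpm_bedgraph <- function(x, ndrs, prefix) {
  stopifnot(identical(rownames(x$counts), ndrs$ndr_id))
  mat <- cpm(x)
  files <- character(0)
  for (s in colnames(mat)) {
    f <- paste0(prefix, ".", s, ".bedGraph")
    writeLines(paste(ndrs$chrom,
      format(ndrs$start, scientific = FALSE, trim = TRUE),
      format(ndrs$end, scientific = FALSE, trim = TRUE),
      format(mat[, s], digits = 6, scientific = FALSE, trim = TRUE),
      sep = "\t"), f)
    files <- c(files, f)
  }
  invisible(files)
}
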