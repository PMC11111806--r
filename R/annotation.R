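#' @title Feature association and enrichment of interaction calls
#'
#' @description
#' Annotates NDRs against feature sets (NPC-proximity peaks, transcription
#' factor peaks, centromeres) and quantifies whether interaction calls are
#' enriched for a feature, by a two-proportions z-test on association
#' fractions and by a permutation test drawing random NDR sets from the
#' annotation universe.
#'
#' @name annotation
NULL

#' Flag NDRs intersecting a peak set
#'
#' TRUE for every NDR overlapping at least one peak by >= 1 bp (half-open
#' adjacency is no overlap).
#'
#' @param ndrs an [ndr_annotation()].
#' @param peaks interval data.frame.
#' @return named logical vector over all NDR ids.
#' @export
associate_by_intersection <- function(ndrs, peaks) {
  flags <- rep(FALSE, nrow(ndrs))
  names(flags) <- ndrs$ndr_id
  if (nrow(peaks) > 0L) {
    hits <- GenomicRanges::findOverlaps(.as_granges(ndrs),
      .as_granges(peaks), minoverlap = 1L)
    flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  flags
}

#' Flag NDRs proximal to a peak set
#'
#' TRUE when the gap distance to the nearest same-chromosome peak is at
#' most `max_gap` (default 1 kb, sub-NDR-spacing scale). `max_gap = 0`
#' flags overlap or book-ended adjacency.
#'
#' @param ndrs an [ndr_annotation()].
#' @param peaks interval data.frame.
#' @param max_gap maximal gap (bp).
#' @return named logical vector over all NDR ids.
#' @export
proximity_flags <- function(ndrs, peaks, max_gap = 1000) {
  d <- nearest_distances(ndrs, peaks)
  # NDRs on chromosomes without any peak (infinite sentinel) are never
  # proximal, whatever the threshold
  flags <- is.finite(d) & d <= max_gap
  names(flags) <- ndrs$ndr_id
  flags
}

#' Two-proportions z-test for feature enrichment
#'
#' Compares the feature-associated fraction among calls (`k_fg / n_fg`)
#' with a background fraction (`k_bg / n_bg`) using the pooled-proportion
#' z statistic and a two-sided normal p-value.
#'
#' @param k_fg,n_fg associated and total counts in the foreground.
#' @param k_bg,n_bg associated and total counts in the background.
#' @return list of class `"enrichment_result"`: counts, `fraction_fg` and
#'   `fraction_bg` (percent), `z`, `pvalue`.
#' @export
enrichment_ztest <- function(k_fg, n_fg, k_bg, n_bg) {
  if (n_fg <= 0 || n_bg <= 0) stop("group sizes must be positive")
  if (k_fg < 0 || k_bg < 0 || k_fg > n_fg || k_bg > n_bg) {
    stop("need 0 <= k <= n in both groups")
  }
  p1 <- k_fg / n_fg
  p2 <- k_bg / n_bg
  pool <- (k_fg + k_bg) / (n_fg + n_bg)
  se <- sqrt(pool * (1 - pool) * (1 / n_fg + 1 / n_bg))
  z <- if (se > 0) (p1 - p2) / se else 0
  structure(list(k_fg = k_fg, n_fg = n_fg, k_bg = k_bg, n_bg = n_bg,
    fraction_fg = 100 * p1, fraction_bg = 100 * p2, z = z,
    pvalue = 2 * stats::pnorm(-abs(z))), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d (%.1f%%) vs %d/%d (%.1f%%), z = %.3f, p = %.3g\n",
    x$k_fg, x$n_fg, x$fraction_fg, x$k_bg, x$n_bg, x$fraction_bg,
    x$z, x$pvalue))
  invisible(x)
}

#' Permutation test for call/feature overlap
#'
#' Null model: draw `|calls|` NDRs uniformly without replacement from the
#' annotation universe and count how many are feature-flagged. The
#' p-value uses the add-one convention,
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never exactly 0.
#'
#' @param call_ids character vector of called NDR ids.
#' @param flags named logical vector over the universe (see
#'   [associate_by_intersection()]).
#' @param universe an [ndr_annotation()] (or character vector of ids).
#' @param n_perm number of permutations (default 100000).
#' @param seed integer seed.
#' @return list of class `"permutation_result"`: `observed`, `null_mean`,
#'   `n_perm`, `pvalue`, `seed`.
#' @export
permutation_overlap_test <- function(call_ids, flags, universe,
                                     n_perm = 100000, seed = 1) {
  ids <- if (is.data.frame(universe)) universe$ndr_id else universe
  if (!all(call_ids %in% ids)) stop("calls must be a subset of the universe")
  if (length(call_ids) > length(ids)) stop("more calls than universe NDRs")
  f <- flags[ids]
  if (anyNA(f)) stop("flags must cover every universe NDR")
  observed <- sum(flags[call_ids])
  k <- length(call_ids)
  n <- length(ids)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    sum(f[sample.int(n, k)])
  }, numeric(1))
  structure(list(observed = observed, null_mean = mean(null),
    n_perm = n_perm, pvalue = (1 + sum(null >= observed)) / (1 + n_perm),
    seed = seed), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed %d (null mean %.2f), p = %.3g (%d perms)\n",
    x$observed, x$null_mean, x$pvalue, x$n_perm))
  invisible(x)
}

#' Nearest-feature distance summary
#'
#' Per-interval gap distances to the nearest same-chromosome feature, the
#' median, and (optionally) a two-sample comparison of distances between
#' two interval sets, by default a two-sided rank-sum test (medians are
#' the reported summary), with Welch's t-test behind a flag.
#'
#' @param x interval data.frame (e.g. interacting NDRs).
#' @param peaks feature interval data.frame.
#' @param compare optional second interval data.frame.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return list: `distances`, `median`, and when `compare` is given also
#'   `distances2`, `median2`, `pvalue`, `test`.
#' @export
distance_summary <- function(x, peaks, compare = NULL,
                             test = c("wilcox", "t")) {
  test <- match.arg(test)
  if (nrow(x) == 0L) stop("empty interval set")
  d1 <- nearest_distances(x, peaks)
  out <- list(distances = d1, median = stats::median(d1))
  if (!is.null(compare)) {
    d2 <- nearest_distances(compare, peaks)
    out$distances2 <- d2
    out$median2 <- stats::median(d2)
    f1 <- d1[is.finite(d1)]
    f2 <- d2[is.finite(d2)]
    out$pvalue <- if (test == "wilcox") {
      stats::wilcox.test(f1, f2)$p.value
    } else {
      stats::t.test(f1, f2)$p.value
    }
    out$test <- test
  }
  out
}

#' Motif presence per NDR from a genome FASTA
#'
#' Self-contained sequence utility: for each NDR, whether its sequence
#' contains each motif (fixed patterns, e.g. "GC", "GATC"). Requires the
#' Biostrings package.
#'
#' @param fasta path to a genome FASTA whose sequence names match the NDR
#'   chromosomes.
#' @param ndrs an [ndr_annotation()].
#' @param motifs character vector of motifs.
#' @return logical matrix, NDRs x motifs.
#' @export
motif_presence <- function(fasta, ndrs, motifs = c("GC", "GATC")) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("motif_presence requires the Biostrings package")
  }
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(ndrs$chrom), names(genome))
  if (length(missing) > 0L) {
    stop("chromosome(s) absent from FASTA: ", paste(missing, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(genome[ndrs$chrom],
    start = ndrs$start + 1, end = ndrs$end)
  out <- vapply(motifs, function(m) {
    Biostrings::vcountPattern(m, seqs, fixed = TRUE) > 0
  }, logical(nrow(ndrs)))
  rownames(out) <- ndrs$ndr_id
  out
}
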