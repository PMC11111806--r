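#' @title Genomic interval tables
#'
#' @description
#' All coordinates in this package are 0-based half-open (BED convention):
#' an interval covers bases `start, start+1, ..., end-1`. Intervals are
#' carried as plain data frames with columns `chrom`, `start`, `end` and,
#' for NDR annotations, a leading `ndr_id` column. One-based inputs must be
#' converted at the boundary by the caller.
#'
#' @name intervals
NULL

#' Validate an interval table
#'
#' Checks the invariants every interval table must satisfy: non-empty
#' chromosome names, `0 <= start < end`, and (when `chrom_sizes` is given)
#' `end` within the chromosome length.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param chrom_sizes optional named vector of chromosome lengths (bp).
#' @param what label used in error messages.
#' @return `x`, invisibly, with `start`/`end` coerced to integer-valued
#'   numerics.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0L) return(invisible(x))
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop(what, ": empty chromosome name")
  }
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
    x$start < 0 | x$start >= x$end)
  if (length(bad) > 0L) {
    stop(
      what, ": invalid interval at row ", bad[1L], " (",
      x$chrom[bad[1L]], ":", x$start[bad[1L]], "-", x$end[bad[1L]],
      "); need 0 <= start < end"
    )
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown) > 0L) {
      stop(what, ": chromosome(s) absent from sizes: ",
        paste(unknown, collapse = ", "))
    }
    over <- which(x$end > chrom_sizes[x$chrom])
    if (length(over) > 0L) {
      stop(
        what, ": interval exceeds chromosome length at row ", over[1L],
        " (", x$chrom[over[1L]], ":", x$start[over[1L]], "-",
        x$end[over[1L]], ")"
      )
    }
  }
  invisible(x)
}

#' Construct an NDR annotation
#'
#' An NDR annotation is the ordered universe of signal-integration
#' intervals: a data frame with columns `ndr_id`, `chrom`, `start`, `end`,
#' sorted by (chrom, start), with unique ids. Overlapping intervals on the
#' same chromosome violate the NDR model and raise a warning (not an
#' error).
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `ndr_id`; missing ids are auto-generated as `"chrom:start-end"`.
#' @param chrom_sizes optional named vector of chromosome lengths used for
#'   bounds checking.
#' @return data.frame of class `c("ndr_annotation", "data.frame")`.
#' @export
ndr_annotation <- function(x, chrom_sizes = NULL) {
  x <- as.data.frame(x)
  validate_intervals(x, chrom_sizes, what = "NDR")
  if (is.null(x$ndr_id)) {
    x$ndr_id <- paste0(x$chrom, ":", x$start, "-", x$end)
  }
  x$ndr_id <- as.character(x$ndr_id)
  x <- x[order(x$chrom, x$start, x$end), c("ndr_id", "chrom", "start", "end"),
    drop = FALSE]
  rownames(x) <- NULL
  if (anyDuplicated(x$ndr_id)) {
    stop("duplicate NDR ids: ",
      paste(unique(x$ndr_id[duplicated(x$ndr_id)])[1:3], collapse = ", "))
  }
  if (nrow(x) > 1L) {
    same <- x$chrom[-1L] == x$chrom[-nrow(x)]
    olap <- same & (x$start[-1L] < x$end[-nrow(x)])
    if (any(olap)) {
      warning(sum(olap), " overlapping NDR pair(s) on the same chromosome")
    }
  }
  class(x) <- c("ndr_annotation", "data.frame")
  x
}

#' Read a BED file
#'
#' Parses BED3/BED4/BED6 (and MACS2 narrowPeak, of which only the first
#' columns are used). Intervals are taken as 0-based half-open. Column 4,
#' when present, supplies ids; column 5 a numeric score.
#'
#' @param path file path.
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   given, intervals exceeding their chromosome raise an error.
#' @param as one of `"ndr"` (returns a sorted [ndr_annotation()]) or
#'   `"peaks"` (returns a sorted peak table with optional `name`/`score`).
#' @return data.frame; see `as`.
#' @export
read_bed <- function(path, chrom_sizes = NULL, as = c("ndr", "peaks")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    empty <- data.frame(chrom = character(), start = numeric(),
      end = numeric(), stringsAsFactors = FALSE)
    return(if (as == "ndr") ndr_annotation(empty) else empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], " in ", path,
      ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], " in ", path,
      ": non-numeric coordinates")
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], " in ", path,
      ": need 0 <= start < end")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) {
    nm <- vapply(fields, `[[`, "", 4L)
    if (as == "ndr") out$ndr_id <- nm else out$name <- nm
  }
  if (as == "peaks" && all(nf >= 5L)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  validate_intervals(out, chrom_sizes, what = basename(path))
  if (as == "ndr") {
    ndr_annotation(out, chrom_sizes)
  } else {
    out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Write an interval table as BED
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` and, when
#' present, the id/name column, tab-separated without header.
#'
#' @param x interval data.frame (`ndr_id` or `name` becomes BED column 4).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, what = "BED output")
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
    format(x$end, scientific = FALSE, trim = TRUE))
  nm <- if (!is.null(x$ndr_id)) x$ndr_id else x$name
  if (!is.null(nm)) cols <- c(cols, list(nm))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name and length (bp).
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, col.names = c("chrom", "length"))
  sizes <- as.numeric(tab$length)
  if (any(is.na(sizes) | sizes <= 0)) stop("chromosome lengths must be > 0")
  names(sizes) <- as.character(tab$chrom)
  if (anyDuplicated(names(sizes))) stop("duplicate chromosome names")
  sizes
}

#' Write a chromosome-sizes table
#' @param sizes named numeric vector of lengths.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes),
    format(sizes, scientific = FALSE, trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Define a viewpoint
#'
#' A viewpoint is the locus carrying the operator array to which the
#' methyltransferase fusion is recruited; interactions are called relative
#' to it.
#'
#' @param name viewpoint name.
#' @param chrom,start,end insertion interval (0-based half-open).
#' @param chrom_sizes optional named vector for bounds checking.
#' @return list of class `"viewpoint"` with elements `name`, `chrom`,
#'   `start`, `end`.
#' @export
viewpoint <- function(name, chrom, start, end, chrom_sizes = NULL) {
  iv <- data.frame(chrom = chrom, start = start, end = end,
    stringsAsFactors = FALSE)
  validate_intervals(iv, chrom_sizes, what = "viewpoint")
  structure(list(name = as.character(name), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end)), class = "viewpoint")
}

.mid <- function(start, end) floor((start + end) / 2)

.same_chrom_or_stop <- function(ca, cb) {
  if (any(ca != cb)) {
    stop("intervals on different chromosomes; handle trans separately")
  }
}

#' Gap distance between two intervals
#'
#' 0 if the intervals share at least one base (or are book-ended with a
#' shared bp, i.e. overlap); otherwise the number of bases strictly between
#' them. Vectorized over rows.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end` (recycled to
#'   a common length).
#' @return numeric vector of distances in bp.
#' @export
gap_distance <- function(a, b) {
  .same_chrom_or_stop(a$chrom, b$chrom)
  pmax(pmax(a$start, b$start) - pmin(a$end, b$end), 0)
}

#' Midpoint distance between two intervals
#'
#' Absolute difference of the interval midpoints, `floor((start+end)/2)`.
#' This is the distance used for viewpoint-to-NDR classification and decay
#' profiles.
#'
#' @inheritParams gap_distance
#' @return numeric vector of distances in bp.
#' @export
midpoint_distance <- function(a, b) {
  .same_chrom_or_stop(a$chrom, b$chrom)
  abs(.mid(a$start, a$end) - .mid(b$start, b$end))
}

#' Nearest feature to a query interval
#'
#' Scans a feature (peak) set for the same-chromosome feature with the
#' smallest [gap_distance()] to the query; ties go to the leftmost feature
#' (smallest start, then smallest row index). With no same-chromosome
#' feature the distance is `Inf` and the index `NA`.
#'
#' @param query single-row interval data.frame (or list with `chrom`,
#'   `start`, `end`).
#' @param features interval data.frame (rows indexed as returned).
#' @return list with `index` (row in `features`) and `distance` (bp).
#' @export
nearest_feature <- function(query, features) {
  on_chrom <- which(features$chrom == query$chrom[1L])
  if (length(on_chrom) == 0L) {
    return(list(index = NA_integer_, distance = Inf))
  }
  f <- features[on_chrom, , drop = FALSE]
  d <- pmax(pmax(query$start[1L], f$start) - pmin(query$end[1L], f$end), 0)
  best <- d == min(d)
  pick <- on_chrom[best][order(f$start[best], on_chrom[best])][1L]
  list(index = pick, distance = min(d))
}

#' Distances to the nearest feature for every query interval
#'
#' Vectorized wrapper around the [nearest_feature()] contract; returns only
#' the distances (`Inf` where the query's chromosome has no feature).
#'
#' @param queries,features interval data.frames.
#' @return numeric vector, one distance per query row.
#' @export
nearest_distances <- function(queries, features) {
  vapply(seq_len(nrow(queries)), function(i) {
    nearest_feature(queries[i, , drop = FALSE], features)$distance
  }, numeric(1))
}

#' Distance to the nearest chromosome end
#'
#' `min(start, length - end)`: 0 for an interval touching either telomere.
#'
#' @param a interval data.frame.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return numeric vector of distances in bp.
#' @export
end_distance <- function(a, chrom_sizes) {
  unknown <- setdiff(unique(a$chrom), names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop("chromosome(s) absent from sizes: ", paste(unknown, collapse = ", "))
  }
  pmin(a$start, chrom_sizes[a$chrom] - a$end)
}

#' Is an interval subtelomeric?
#'
#' TRUE when the interval lies within `max_end_distance` (default 10 kb) of
#' either chromosome end.
#'
#' @inheritParams end_distance
#' @param max_end_distance bp threshold (default 10000).
#' @return logical vector.
#' @export
is_subtelomeric <- function(a, chrom_sizes, max_end_distance = 10000) {
  unname(end_distance(a, chrom_sizes) < max_end_distance)
}

# Internal: interval data.frame -> GRanges (1-based closed, for overlap ops)
.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
    IRanges::IRanges(start = x$start + 1, end = x$end))
}
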