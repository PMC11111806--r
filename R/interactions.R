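#' @title Interaction classification and distance decay
#'
#' @description
#' Called NDRs are classified relative to the viewpoint: `trans` on a
#' different chromosome, `far_cis` on the viewpoint chromosome with
#' midpoint distance over 30 kb, `local` otherwise. The classes are
#' exhaustive and mutually exclusive. Signal decay with distance is
#' modeled as a base-2 exponential so the fitted scale is literally the
#' half-distance.
#'
#' @name interactions
NULL

#' Classify intervals relative to a viewpoint
#'
#' @param x interval data.frame (e.g. called NDRs with coordinates).
#' @param vp a [viewpoint()].
#' @param far_cis_min minimal midpoint distance (bp) for `far_cis`;
#'   default 30000. The inequality is strict (`> far_cis_min`).
#' @return data.frame `x` plus columns `class` (factor local/far_cis/
#'   trans) and `distance` (midpoint distance to the viewpoint, `NA` for
#'   trans).
#' @export
classify_interactions <- function(x, vp, far_cis_min = 30000) {
  validate_intervals(x, what = "call")
  mid <- .mid(x$start, x$end)
  vmid <- .mid(vp$start, vp$end)
  cis <- x$chrom == vp$chrom
  distance <- ifelse(cis, abs(mid - vmid), NA_real_)
  cls <- ifelse(!cis, "trans",
    ifelse(distance > far_cis_min, "far_cis", "local"))
  x$class <- factor(cls, levels = c("local", "far_cis", "trans"))
  x$distance <- distance
  x
}

#' Fit an exponential distance decay
#'
#' Least-squares fit of `log2(signal) = log2(A) - d/h`, linear in the
#' distance `d`; `h` is the half-distance in bp. Signals must be positive
#' and distances must vary; a non-negative slope (no decay) is an error.
#'
#' @param distance distances in bp.
#' @param signal positive signal values (e.g. fold enrichment).
#' @return list of class `"decay_fit"`: `amplitude` (signal at d = 0),
#'   `half_distance` (bp), `residual_rms` (log2 scale), `n`.
#' @export
fit_exponential_decay <- function(distance, signal) {
  ok <- is.finite(distance) & is.finite(signal)
  distance <- distance[ok]
  signal <- signal[ok]
  if (length(distance) < 4L) stop("decay fit needs >= 4 points")
  if (any(signal <= 0)) {
    stop("signals must be positive; subtract or offset background first")
  }
  if (stats::var(distance) == 0) stop("distances have zero variance")
  fit <- stats::lm(log2(signal) ~ distance)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("no decay detected (non-negative slope)")
  structure(list(
    amplitude = unname(2^stats::coef(fit)[1L]),
    half_distance = -1 / slope,
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    n = length(distance)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("decay_fit: amplitude ", signif(x$amplitude, 4), ", half-distance ",
    round(x$half_distance), " bp (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Signal profile around called interaction centers
#'
#' For every NDR other than the centers themselves whose midpoint lies
#' within `max_d` of the center of a same-chromosome called NDR, collects
#' (distance to the nearest such center, log2FC) and averages the signal
#' in distance bins of width `bin`. Neighbors are included whether or not
#' they were themselves called: the decay of signal around true contact
#' centers extends above the calling threshold, and excluding called
#' neighbors would truncate the profile at that threshold.
#' The binned profile feeds [fit_exponential_decay()];
#' the `fold_excess` column (`2^signal - 1`) is the natural scale for
#' fitting since the planted enrichment is multiplicative above a
#' background of fold 1.
#'
#' @param calls data.frame of called NDRs with coordinates (e.g. a
#'   long-distance subset of [classify_interactions()] output).
#' @param results full `diff_result` with per-NDR `log2FC`.
#' @param ndrs the [ndr_annotation()].
#' @param max_d maximal distance (bp), default 3000.
#' @param bin bin width (bp), default 200.
#' @param centers `"summits"` (default) aligns on local signal maxima: a
#'   called NDR is a center only if no stronger call lies within `max_d`
#'   on its chromosome, so the decaying flank of one contact is not
#'   mistaken for a second center. `"all"` uses every call as a center.
#' @return data.frame with one row per non-empty bin: `distance` (mean
#'   within bin), `signal` (mean log2FC), `fold_excess`, `n`.
#' @export
neighbor_decay_profile <- function(calls, results, ndrs, max_d = 3000,
                                   bin = 200,
                                   centers = c("summits", "all")) {
  centers_mode <- match.arg(centers)
  if (nrow(calls) == 0L) stop("need >= 1 called NDR")
  if (centers_mode == "summits") {
    lfc <- results$log2FC[match(calls$ndr_id, results$ndr_id)]
    cmid <- .mid(calls$start, calls$end)
    keep <- vapply(seq_len(nrow(calls)), function(i) {
      near <- calls$chrom == calls$chrom[i] & abs(cmid - cmid[i]) <= max_d
      lfc[i] >= max(lfc[near])
    }, logical(1))
    calls <- calls[keep, , drop = FALSE]
  }
  centers <- data.frame(chrom = calls$chrom,
    mid = .mid(calls$start, calls$end), stringsAsFactors = FALSE)
  others <- ndrs[!(ndrs$ndr_id %in% calls$ndr_id), , drop = FALSE]
  omid <- .mid(others$start, others$end)
  d <- vapply(seq_len(nrow(others)), function(i) {
    on <- centers$chrom == others$chrom[i]
    if (!any(on)) return(Inf)
    min(abs(centers$mid[on] - omid[i]))
  }, numeric(1))
  keep <- d <= max_d
  if (!any(keep)) {
    return(data.frame(distance = numeric(0), signal = numeric(0),
      fold_excess = numeric(0), n = integer(0)))
  }
  lfc <- results$log2FC[match(others$ndr_id[keep], results$ndr_id)]
  dd <- d[keep]
  ok <- !is.na(lfc)
  dd <- dd[ok]
  lfc <- lfc[ok]
  b <- floor(dd / bin)
  agg <- data.frame(
    distance = as.numeric(tapply(dd, b, mean)),
    signal = as.numeric(tapply(lfc, b, mean)),
    n = as.integer(tapply(lfc, b, length))
  )
  agg$fold_excess <- 2^agg$signal - 1
  agg <- agg[order(agg$distance), c("distance", "signal", "fold_excess", "n")]
  rownames(agg) <- NULL
  agg
}
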