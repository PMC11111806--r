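#' @title Multi-viewpoint correlation clustering of NDRs
#'
#' @description
#' NDRs that were called interacting with at least one viewpoint carry a
#' signal (log2FC) in every viewpoint's differential result. Correlating
#' these per-NDR signal vectors and clustering the correlation matrix
#' hierarchically groups NDRs that occupy similar nuclear space.
#'
#' @name multivp
NULL

#' Build the NDR x viewpoint signal matrix
#'
#' Rows are the union of NDRs called by at least one viewpoint; the value
#' in column v is that viewpoint's log2FC for the NDR, whether or not the
#' NDR was called there. Every viewpoint's differential result must cover
#' every row (shared NDR universe).
#'
#' @param results_by_vp named list of `diff_result` data.frames.
#' @param calls_by_vp named list of call sets ([call_interactions()]
#'   output or character id vectors), same names as `results_by_vp`.
#' @return numeric matrix (NDR ids x viewpoint names).
#' @export
build_signal_matrix <- function(results_by_vp, calls_by_vp) {
  stopifnot(length(results_by_vp) >= 1L,
    identical(sort(names(results_by_vp)), sort(names(calls_by_vp))))
  ids_of <- function(x) if (is.data.frame(x)) x$ndr_id else as.character(x)
  rows <- sort(unique(unlist(lapply(calls_by_vp, ids_of))))
  if (length(rows) == 0L) stop("no called NDR in any viewpoint")
  vps <- names(results_by_vp)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(vps),
    dimnames = list(rows, vps))
  for (v in vps) {
    res <- results_by_vp[[v]]
    idx <- match(rows, res$ndr_id)
    if (anyNA(idx)) {
      stop("viewpoint ", v, " lacks results for ", sum(is.na(idx)),
        " NDR(s) of the union: universe mismatch")
    }
    m[, v] <- res$log2FC[idx]
  }
  if (anyNA(m)) stop("missing log2FC values in the signal matrix")
  m
}

#' Pairwise Pearson correlation of NDR signal vectors
#'
#' Correlates rows (NDRs) of the signal matrix across viewpoints.
#' Zero-variance rows have undefined correlation and are dropped with a
#' warning. The result is exactly symmetric with a unit diagonal.
#'
#' @param m signal matrix from [build_signal_matrix()] (>= 2 columns).
#' @return square correlation matrix over the retained NDRs.
#' @export
correlation_matrix <- function(m) {
  if (ncol(m) < 2L) stop("correlation needs >= 2 viewpoints")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance NDR row(s) dropped")
    m <- m[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(m))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Ward hierarchical clustering of the correlation matrix
#'
#' Clusters NDRs by Ward's minimum-variance linkage on Euclidean
#' distances between rows of the correlation matrix (each NDR represented
#' by its correlation profile). The tree is cut to exactly `k` clusters
#' and labels are renumbered by decreasing cluster size. With
#' `representation = "dissimilarity"` the alternative of treating
#' `1 - r` as the pairwise dissimilarity is used instead.
#'
#' @param r correlation matrix from [correlation_matrix()].
#' @param k number of clusters (`2 <= k <= nrow(r)`).
#' @param representation `"profile"` (default; Euclidean distance between
#'   correlation rows) or `"dissimilarity"` (`1 - r`).
#' @return list of class `"cluster_assignment"`: `labels` (named integer,
#'   1..k, numbered by decreasing size), `tree` (an [stats::hclust()]
#'   object), `k`.
#' @export
hierarchical_cluster <- function(r, k,
                                 representation = c("profile",
                                   "dissimilarity")) {
  representation <- match.arg(representation)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(r)) stop("k exceeds the number of NDRs")
  d <- if (representation == "profile") {
    stats::dist(r)
  } else {
    stats::as.dist(1 - r)
  }
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  remap <- integer(length(sizes))
  remap[as.integer(names(sort(sizes, decreasing = TRUE)))] <-
    seq_along(sizes)
  labels <- remap[raw]
  names(labels) <- names(raw)
  structure(list(labels = labels, tree = tree, k = k,
    representation = representation), class = "cluster_assignment")
}

#' Summarize clusters
#'
#' Per-cluster composition: size; chromosome composition (percent);
#' interaction-type composition under the precedence local > far_cis >
#' trans across all viewpoints that called the NDR; feature-associated
#' fraction; interacting-viewpoints-per-NDR distribution; and distance to
#' the nearest centromere (midpoint distance, same chromosome).
#'
#' @param assignment a [hierarchical_cluster()] result.
#' @param classified_by_vp named list of [classify_interactions()] outputs
#'   (the called NDRs of each viewpoint with their class).
#' @param ndrs the [ndr_annotation()].
#' @param npc_flags optional named logical vector (e.g. from
#'   [associate_by_intersection()]).
#' @param centromeres optional interval data.frame of centromere
#'   positions.
#' @return list of class `"cluster_summary"`: `per_ndr` (data.frame with
#'   cluster, interaction type, n viewpoints, flags, distances) and
#'   `per_cluster` (list of composition tables).
#' @export
summarize_clusters <- function(assignment, classified_by_vp, ndrs,
                               npc_flags = NULL, centromeres = NULL) {
  ids <- names(assignment$labels)
  idx <- match(ids, ndrs$ndr_id)
  if (anyNA(idx)) stop("cluster rows missing from the NDR annotation")
  type_rank <- c(local = 1, far_cis = 2, trans = 3)
  per_type <- rep(NA_character_, length(ids))
  n_vps <- integer(length(ids))
  for (cl in classified_by_vp) {
    m <- match(ids, cl$ndr_id)
    hit <- !is.na(m)
    n_vps[hit] <- n_vps[hit] + 1L
    cls <- as.character(cl$class[m[hit]])
    cur <- per_type[hit]
    better <- is.na(cur) | type_rank[cls] < type_rank[cur]
    cur[better] <- cls[better]
    per_type[hit] <- cur
  }
  per_ndr <- data.frame(
    ndr_id = ids,
    cluster = unname(assignment$labels),
    chrom = ndrs$chrom[idx],
    interaction_type = factor(per_type,
      levels = c("local", "far_cis", "trans")),
    n_vps = n_vps,
    stringsAsFactors = FALSE
  )
  if (!is.null(npc_flags)) per_ndr$npc <- unname(npc_flags[ids])
  if (!is.null(centromeres)) {
    mid <- .mid(ndrs$start[idx], ndrs$end[idx])
    per_ndr$centromere_distance <- vapply(seq_along(ids), function(i) {
      on <- centromeres$chrom == per_ndr$chrom[i]
      if (!any(on)) return(NA_real_)
      cmid <- .mid(centromeres$start[on], centromeres$end[on])
      min(abs(cmid - mid[i]))
    }, numeric(1))
  }
  pct <- function(x) 100 * table(x) / length(x)
  per_cluster <- lapply(split(per_ndr, per_ndr$cluster), function(d) {
    out <- list(size = nrow(d), chrom_pct = pct(d$chrom),
      type_pct = pct(d$interaction_type),
      vps_per_ndr = table(d$n_vps))
    if (!is.null(d$npc)) out$npc_fraction <- mean(d$npc)
    if (!is.null(d$centromere_distance)) {
      out$centromere_distance_median <-
        stats::median(d$centromere_distance, na.rm = TRUE)
    }
    out
  })
  structure(list(per_ndr = per_ndr, per_cluster = per_cluster),
    class = "cluster_summary")
}
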