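# Independent oracles and fixture generators shared across test files.
# Each oracle is written from the definition of the quantity it checks and
# must stay independent of the package code paths it validates.

# Random non-overlapping interval annotation on a small genome.
rand_annotation <- function(n, chroms = c("chrA", "chrB"),
                            chrom_len = 100000, width = 50:200) {
  rows <- lapply(chroms, function(ch) {
    k <- ceiling(n / length(chroms))
    starts <- sort(sample.int(chrom_len - max(width) - 1L, k))
    w <- sample(width, k, replace = TRUE)
    ends <- pmin(starts + w, chrom_len)
    # enforce non-overlap by clipping each end to the next start
    if (k > 1L) ends[-k] <- pmin(ends[-k], starts[-1L])
    keep <- ends > starts
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$ndr_id <- sprintf("iv%04d", seq_len(nrow(df)))
  ndr_annotation(df)
}

# Brute-force gap distance: the number of bases strictly between the two
# closest bases of the intervals (min pointwise |i - j| minus one), 0 when
# they share a base or are book-ended.
bf_gap <- function(a1, a2, b1, b2) {
  pa <- a1:(a2 - 1L)
  pb <- b1:(b2 - 1L)
  max(min(abs(outer(pa, pb, "-"))) - 1L, 0L)
}

# Quadratic all-pairs overlap counter (counting-module oracle).
quad_count <- function(fragments, ndrs) {
  samples <- unique(fragments$sample)
  m <- matrix(0L, nrow(ndrs), length(samples),
    dimnames = list(ndrs$ndr_id, samples))
  for (f in seq_len(nrow(fragments))) {
    for (i in seq_len(nrow(ndrs))) {
      if (fragments$chrom[f] == ndrs$chrom[i] &&
          fragments$start[f] < ndrs$end[i] &&
          fragments$end[f] > ndrs$start[i]) {
        m[i, fragments$sample[f]] <- m[i, fragments$sample[f]] + 1L
      }
    }
  }
  m
}

# Benjamini-Hochberg from the definition: padj_i = min_{k: p_(k) >= p_i
# in rank order} m * p_(k) / k, with the step-up monotonicity.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(m * ranked[i:m] / (i:m))
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# NB profile-likelihood maximizer over the group log2 fold change by grid +
# golden-section search; the inner intercept is itself profiled out by
# golden-section. Independent of the package's Fisher-scoring path.
bf_nb_mle <- function(y, sf, alpha, group) {
  it <- group == "targeted"
  ll <- function(mc, mt) {
    mu <- sf * ifelse(it, mt, mc)
    sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  prof <- function(l2fc) {
    f <- function(lmc) ll(exp(lmc), exp(lmc) * 2^l2fc)
    stats::optimize(f, c(-15, 15), maximum = TRUE, tol = 1e-9)$objective
  }
  grid <- seq(-10, 10, by = 0.5)
  vals <- vapply(grid, prof, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
}

# Naive O(n^3) agglomerative Ward clustering on the rows of a matrix.
# At each step merges the pair of clusters with the smallest increase in
# total within-cluster sum of squares. Returns the sequence of partitions
# (as canonical membership vectors) and the k-cluster labels.
naive_ward <- function(x, k) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  delta_sse <- function(a, b) {
    na <- length(a)
    nb <- length(b)
    ca <- colMeans(x[a, , drop = FALSE])
    cb <- colMeans(x[b, , drop = FALSE])
    (na * nb) / (na + nb) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- delta_sse(clusters[[i]], clusters[[j]])
        if (d < best[1L]) best <- c(d, i, j)
      }
    }
    merged <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters <- clusters[-c(best[2L], best[3L])]
    clusters[[length(clusters) + 1L]] <- merged
    memb <- integer(n)
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- canonical_labels(memb)
  }
  partitions
}

# Relabel a membership vector by first appearance so two partitions can be
# compared irrespective of arbitrary label numbering.
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}
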