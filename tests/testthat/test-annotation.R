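test_that("intersection flags require a shared base; adjacency is no overlap", {
  ndrs <- ndr_annotation(data.frame(chrom = "c", start = c(100, 500),
    end = c(250, 600), ndr_id = c("n1", "n2")))
  peaks <- data.frame(chrom = "c", start = 240, end = 400)
  flags <- associate_by_intersection(ndrs, peaks)
  expect_true(flags[["n1"]])   # 10 bp overlap
  expect_false(flags[["n2"]])
  peaks2 <- data.frame(chrom = "c", start = 250, end = 400)
  flags2 <- associate_by_intersection(ndrs, peaks2)
  expect_false(flags2[["n1"]]) # half-open adjacency

  # random sets vs quadratic scan
  set.seed(17)
  ann <- rand_annotation(60)
  pk <- data.frame(chrom = sample(c("chrA", "chrB"), 40, TRUE),
    start = sample.int(99000, 40))
  pk$end <- pk$start + sample.int(500, 40, replace = TRUE)
  got <- associate_by_intersection(ann, pk)
  want <- vapply(seq_len(nrow(ann)), function(i) {
    any(pk$chrom == ann$chrom[i] & pk$start < ann$end[i] &
      pk$end > ann$start[i])
  }, logical(1))
  expect_equal(unname(got), want)
})

test_that("proximity flags use the gap distance with a configurable threshold", {
  ndrs <- ndr_annotation(data.frame(chrom = "c", start = c(1000, 9000),
    end = c(1150, 9150), ndr_id = c("near", "far")))
  peaks <- data.frame(chrom = "c", start = 1650, end = 1800)
  flags <- proximity_flags(ndrs, peaks, max_gap = 1000)
  expect_true(flags[["near"]])  # 500 bp gap
  expect_false(flags[["far"]])  # 7200 bp gap

  # max_gap = 0 reduces to intersection-or-adjacency
  set.seed(23)
  ann <- rand_annotation(50)
  pk <- data.frame(chrom = sample(c("chrA", "chrB"), 30, TRUE),
    start = sample.int(99000, 30))
  pk$end <- pk$start + sample.int(400, 30, replace = TRUE)
  prox0 <- proximity_flags(ann, pk, max_gap = 0)
  inter_or_adj <- vapply(seq_len(nrow(ann)), function(i) {
    any(pk$chrom == ann$chrom[i] & pk$start <= ann$end[i] &
      pk$end >= ann$start[i])
  }, logical(1))
  expect_equal(unname(prox0), inter_or_adj)

  # infinite threshold flags everything on chromosomes that have peaks
  prox_inf <- proximity_flags(ann, pk[pk$chrom == "chrA", ],
    max_gap = Inf)
  expect_equal(unname(prox_inf), ann$chrom == "chrA")
})

test_that("two-proportions z-test reproduces the worked fractions", {
  far_cis <- enrichment_ztest(14, 22, 546, 4829)
  expect_equal(round(far_cis$fraction_fg, 1), 63.6)
  expect_equal(round(far_cis$fraction_bg, 1), 11.3)
  expect_lt(far_cis$pvalue, 1e-10)
  trans <- enrichment_ztest(57, 89, 546, 4829)
  expect_equal(round(trans$fraction_fg, 1), 64.0)

  eq <- enrichment_ztest(5, 10, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$pvalue, 1)

  # closed-form oracle computed independently: 8/10 vs 2/10
  p1 <- 0.8; p2 <- 0.2; pool <- 0.5
  z_want <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / 10 + 1 / 10))
  got <- enrichment_ztest(8, 10, 2, 10)
  expect_equal(got$z, z_want, tolerance = 1e-12)

  # antisymmetry: swapping groups negates z, keeps p
  sw <- enrichment_ztest(2, 10, 8, 10)
  expect_equal(sw$z, -got$z)
  expect_equal(sw$pvalue, got$pvalue)

  expect_error(enrichment_ztest(5, 0, 1, 10), "positive")
  expect_error(enrichment_ztest(11, 10, 1, 10), "0 <= k <= n")
})

test_that("permutation overlap test: degenerate cases and hypergeometric oracle", {
  ids <- sprintf("n%03d", 1:60)
  all_flags <- setNames(rep(TRUE, 60), ids)
  res <- permutation_overlap_test(ids[1:10], all_flags, ids, n_perm = 200,
    seed = 1)
  expect_equal(res$pvalue, 1)

  # maximal observed overlap with rare flags -> the +1 lower bound
  rare <- setNames(c(rep(TRUE, 5), rep(FALSE, 55)), ids)
  res2 <- permutation_overlap_test(ids[1:5], rare, ids, n_perm = 500,
    seed = 2)
  expect_gte(res2$pvalue, 1 / 501)
  expect_lt(res2$pvalue, 0.05)

  # exchangeable null agrees with the hypergeometric tail within MC error
  set.seed(3)
  flags <- setNames(seq_along(ids) %in% sample.int(60, 20), ids)
  calls <- ids[sample.int(60, 15)]
  obs <- sum(flags[calls])
  perm <- permutation_overlap_test(calls, flags, ids, n_perm = 100000,
    seed = 4)
  p_exact <- stats::phyper(obs - 1, 20, 40, 15, lower.tail = FALSE)
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 100000)
  expect_lt(abs(perm$pvalue - p_exact), 3 * mc_sd + 2 / 100001)

  expect_error(permutation_overlap_test(c("nope"), flags, ids), "subset")
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(99)
  n_univ <- 5000
  ids <- sprintf("n%04d", seq_len(n_univ))
  flags <- setNames(runif(n_univ) < 0.25, ids)
  ps <- vapply(1:500, function(i) {
    calls <- sample(ids, 200)
    permutation_overlap_test(calls, flags, ids, n_perm = 400,
      seed = 1000 + i)$pvalue
  }, numeric(1))
  ks <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lte(ks, 0.05)
})

test_that("distance summaries match exhaustive scans and compare groups", {
  # all NDRs overlap peaks -> all distances zero
  ndrs <- ndr_annotation(data.frame(chrom = "c", start = c(0, 1000),
    end = c(150, 1150), ndr_id = c("a", "b")))
  pk <- data.frame(chrom = "c", start = c(100, 1100), end = c(200, 1200))
  ds <- distance_summary(ndrs, pk)
  expect_equal(unname(ds$distances), c(0, 0))
  expect_equal(ds$median, 0)

  # random instance vs exhaustive scan
  set.seed(29)
  ann <- rand_annotation(40)
  pk2 <- data.frame(chrom = sample(c("chrA", "chrB"), 25, TRUE),
    start = sample.int(99000, 25))
  pk2$end <- pk2$start + sample.int(300, 25, replace = TRUE)
  got <- distance_summary(ann, pk2)$distances
  want <- vapply(seq_len(nrow(ann)), function(i) {
    d <- Inf
    for (j in seq_len(nrow(pk2))) {
      if (pk2$chrom[j] != ann$chrom[i]) next
      d <- min(d, max(max(ann$start[i], pk2$start[j]) -
        min(ann$end[i], pk2$end[j]), 0))
    }
    d
  }, numeric(1))
  expect_equal(unname(got), want)

  # two planted groups: medians and a rank-sum comparison
  near <- ndr_annotation(data.frame(chrom = "c",
    start = seq(200, 2000, by = 200), end = seq(200, 2000, by = 200) + 50))
  farr <- ndr_annotation(data.frame(chrom = "c",
    start = seq(50000, 59000, by = 1000),
    end = seq(50000, 59000, by = 1000) + 50))
  pk3 <- data.frame(chrom = "c", start = 0, end = 100)
  cmp <- distance_summary(near, pk3, compare = farr)
  expect_lt(cmp$median, cmp$median2)
  expect_lt(cmp$pvalue, 0.01)
  expect_equal(cmp$test, "wilcox")
})

test_that("motif presence scans NDR sequences from a FASTA", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", "AAAAGCAAAAGATCAAAATTTT"), fa)
  #            0123456789...
  ndrs <- ndr_annotation(data.frame(chrom = "chrT",
    start = c(0, 8, 16), end = c(8, 16, 22),
    ndr_id = c("has_gc", "has_gatc", "neither")))
  pres <- motif_presence(fa, ndrs, motifs = c("GC", "GATC"))
  expect_equal(unname(pres[, "GC"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(pres[, "GATC"]), c(FALSE, TRUE, FALSE))
})
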