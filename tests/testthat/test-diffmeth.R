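make_counts <- function(m, n_t = 2, n_c = ncol(m) - n_t) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("n%03d", seq_len(nrow(m)))
  colnames(m) <- c(paste0("targeted_", seq_len(n_t)),
    paste0("control_", seq_len(n_c)))
  mtac_counts(m, rep(c("targeted", "control"), c(n_t, n_c)))
}

test_that("median-of-ratios size factors: identity, scale equivariance, oracle", {
  m <- matrix(rep(c(10L, 20L, 30L), 2), 3, 2)
  cm <- make_counts(m, 1, 1)
  expect_equal(unname(size_factors_median_of_ratios(cm)), c(1, 1))

  # sample 2 = 2 x sample 1 -> factor ratio exactly 2
  m2 <- cbind(m[, 1], m[, 1] * 2L)
  sf <- size_factors_median_of_ratios(make_counts(m2, 1, 1))
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  # 3x4 toy vs spreadsheet-style hand computation
  toy <- matrix(c(
    10L, 20L, 5L, 40L,
    100L, 200L, 50L, 400L,
    12L, 30L, 6L, 44L), nrow = 3, byrow = TRUE)
  cm3 <- make_counts(toy, 2, 2)
  sf3 <- size_factors_median_of_ratios(cm3)
  geo <- apply(toy, 1, function(r) prod(r)^(1 / length(r)))
  raw <- apply(sweep(toy, 1, geo, "/"), 2, median)
  expect_equal(unname(sf3), unname(raw / exp(mean(log(raw)))),
    tolerance = 1e-12)

  # all-zero-containing rows cannot support normalization
  z <- matrix(c(0L, 5L, 3L, 0L), 2, 2)
  expect_error(size_factors_median_of_ratios(make_counts(z, 1, 1)),
    "positive counts")
})

test_that("size factors agree with an established median-of-ratios implementation", {
  set.seed(31)
  m <- matrix(rnbinom(400 * 4, mu = 50, size = 10), 400, 4)
  m <- sweep(m, 2, c(1, 2, 0.5, 1.5), "*")
  storage.mode(m) <- "integer"
  cm <- make_counts(m)
  sf <- size_factors_median_of_ratios(cm)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("dispersion estimation: constants get the trend, simulations recover truth", {
  # constant counts within both groups -> raw dispersion 0 -> trend value
  m <- matrix(rep(c(50L, 50L, 20L, 20L), 25), 25, 4, byrow = TRUE)
  m[1:10, ] <- matrix(rnbinom(40, mu = 100, size = 5), 10, 4) # trend support
  cm <- make_counts(m)
  dm <- estimate_dispersions(cm, sf = rep(1, 4))
  const_rows <- 11:25
  expect_true(all(dm$alpha_raw[const_rows] == 0))
  atr <- dm$trend[["a0"]] + dm$trend[["a1"]] / dm$mu[const_rows]
  expect_equal(unname(dm$alpha[const_rows]), unname(atr))

  # Poisson data: median final dispersion is near zero
  set.seed(55)
  mp <- matrix(rpois(5000 * 4, 50), 5000, 4)
  dmp <- estimate_dispersions(make_counts(mp), sf = rep(1, 4))
  expect_lte(median(dmp$alpha), 0.02)

  # NB alpha = 0.1 at mean 100: median final dispersion within 20%
  set.seed(56)
  mn <- matrix(rnbinom(5000 * 4, mu = 100, size = 10), 5000, 4)
  dmn <- estimate_dispersions(make_counts(mn), sf = rep(1, 4))
  expect_lt(abs(median(dmn$alpha) - 0.1) / 0.1, 0.2)
})

test_that("NB Wald test: symmetric null, exact fourfold, flags", {
  grp <- rep(c("targeted", "control"), each = 2)
  r0 <- nb_wald_test(c(30L, 30L, 30L, 30L), rep(1, 4), 0.05, grp)
  expect_equal(r0$log2FC, 0)
  expect_equal(r0$pvalue, 1)

  r4 <- nb_wald_test(c(40L, 40L, 10L, 10L), rep(1, 4), 1e-8, grp)
  expect_equal(r4$log2FC, 2, tolerance = 1e-3)
  expect_lt(r4$pvalue, 1e-6)

  rz <- nb_wald_test(c(20L, 25L, 0L, 0L), rep(1, 4), 0.05, grp)
  expect_equal(rz$flag, "zero_group")
  expect_true(is.finite(rz$log2FC))
})

test_that("Wald MLE matches a grid + golden-section likelihood maximizer", {
  set.seed(77)
  grp <- rep(c("targeted", "control"), each = 2)
  for (i in 1:50) {
    alpha <- runif(1, 0.01, 0.5)
    sf <- exp(runif(4, -0.3, 0.3))
    mu <- runif(1, 5, 200)
    fold <- exp(runif(1, -1.5, 1.5))
    y <- rnbinom(4, mu = sf * mu * ifelse(grp == "targeted", fold, 1),
      size = 1 / alpha)
    if (all(y[grp == "targeted"] == 0) || all(y[grp == "control"] == 0)) next
    got <- nb_wald_test(y, sf, alpha, grp)
    want <- bf_nb_mle(y, sf, alpha, grp)
    expect_equal(got$log2FC, want, tolerance = 1e-4)
  }
})

test_that("BH adjustment equals the brute-force definition and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # exhaustive over a p-grid for lengths 1..4
  grid <- c(0.001, 0.04, 0.2, 1)
  for (len in 1:4) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    for (r in seq_len(nrow(combos))) {
      p <- unname(combos[r, ])
      expect_equal(bh_adjust(p), bf_bh(p))
    }
  }
  # random longer vectors and the elementwise/monotonicity properties
  set.seed(5)
  for (i in 1:200) {
    p <- runif(sample(5:8, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bf_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  # NaN propagates without perturbing the rest of the universe
  p <- c(0.01, NaN, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bf_bh(p[c(1, 3)]))
  expect_error(bh_adjust(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("interaction calling uses strict thresholds and excludes the VP locus", {
  res <- data.frame(
    ndr_id = c("a", "b", "c", "d"),
    baseMean = 50, log2FC = c(2.0, 0.7, 1.5, 3.0), SE = 0.2, stat = 5,
    pvalue = c(1e-8, 0.001, 0.002, 1e-9),
    padj = c(1e-6, 0.01, 0.05, 1e-7),
    flag = FALSE, stringsAsFactors = FALSE
  )
  calls <- call_interactions(res)
  # b fails log2FC > 0.7 (boundary exclusive); c fails padj < 0.05
  expect_setequal(calls$ndr_id, c("a", "d"))

  ndrs <- ndr_annotation(data.frame(chrom = "c",
    start = c(0, 1000, 2000, 3000), end = c(100, 1100, 2100, 3100),
    ndr_id = c("a", "b", "c", "d")))
  vp <- viewpoint("v", "c", 3050, 4050)
  calls2 <- call_interactions(res, vp = vp, ndrs = ndrs)
  expect_setequal(calls2$ndr_id, "a")
  expect_equal(attr(calls2, "vp_locus"), "d")
})

test_that("scaling one sample scales its size factor and preserves the test", {
  set.seed(91)
  m <- matrix(rnbinom(200 * 4, mu = 80, size = 10), 200, 4)
  storage.mode(m) <- "integer"
  cm <- make_counts(m)
  sf1 <- size_factors_median_of_ratios(cm)
  m2 <- m
  m2[, 1] <- m2[, 1] * 3L
  cm2 <- make_counts(m2)
  sf2 <- size_factors_median_of_ratios(cm2)
  expect_equal(unname(sf2[1] / sf2[2]), unname(3 * sf1[1] / sf1[2]),
    tolerance = 1e-12)
  # scaling every sample by the same factor leaves the size factors and
  # (at near-Poisson dispersion) the whole test invariant
  m3 <- m * 3L
  cm3 <- make_counts(m3)
  sf3 <- size_factors_median_of_ratios(cm3)
  expect_equal(unname(sf3), unname(sf1), tolerance = 1e-12)
  grp <- cm$samples$group
  for (i in c(1, 50, 200)) {
    a <- nb_wald_test(m[i, ], sf1, 1e-8, grp)
    b <- nb_wald_test(m3[i, ], sf3, 1e-8, grp)
    expect_equal(a$log2FC, b$log2FC, tolerance = 1e-6)
  }
})

test_that("log2FC is consistent for the true fold at high depth", {
  set.seed(303)
  n <- 800
  m <- cbind(
    matrix(rnbinom(n * 2, mu = 40000, size = 20), n, 2),
    matrix(rnbinom(n * 2, mu = 10000, size = 20), n, 2)
  )
  storage.mode(m) <- "integer"
  # unit size factors: every row carries the fold, so normalization must
  # not be allowed to absorb it
  res <- diff_methylation(make_counts(m), sf = rep(1, 4))
  expect_equal(mean(res$log2FC), 2, tolerance = 0.02)
})

test_that("zero rows are dropped before testing and padj dominates p", {
  m <- matrix(c(0L, 0L, 0L, 0L,
                30L, 35L, 10L, 12L,
                50L, 45L, 48L, 52L), 3, 4, byrow = TRUE)
  rownames(m) <- c("zero", "up", "flat")
  res <- diff_methylation(make_counts(m))
  expect_false("zero" %in% res$ndr_id)
  expect_true(all(res$padj >= res$pvalue - 1e-15))
  expect_true(all(res$padj <= 1))
})
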