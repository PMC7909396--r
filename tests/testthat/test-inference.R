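# Permutation inference, FDR control, and DEG calling.

test_that("small designs switch to exhaustive enumeration with a notice", {
  x <- rand_lem(5, n1 = 3, n0 = 3, seed = 20)
  expect_message(pr <- permutation_null(x, "student_t", B = 1000, seed = 1),
                 "exhaustively")
  expect_true(pr$exhaustive)
  expect_equal(pr$B, choose(6, 3))        # 20 distinct assignments
  expect_equal(nrow(pr$null_scores), 20)
  expect_equal(ncol(pr$null_scores), 5)
})

test_that("per-gene permutation p-values equal the exhaustive enumeration oracle", {
  for (method in c("student_t", "half_t", "sam", "half_sam")) {
    c0 <- if (method %in% c("sam", "half_sam")) 0.5 else 0
    x <- rand_lem(5, n1 = 3, n0 = 3, seed = 21, shift = 1)
    pr <- suppressMessages(
      permutation_null(x, method, B = 1e6, c0 = if (c0 > 0) c0 else NULL))
    expect_equal(unname(pr$pvalues), oracle_exhaustive_p(x, method, c0),
                 info = method)
  }
  # also on an unbalanced design with n1 + n0 = 8
  x <- rand_lem(4, n1 = 5, n0 = 3, seed = 22, shift = 2)
  pr <- suppressMessages(permutation_null(x, "half_t", B = 1e6))
  expect_equal(pr$B, choose(8, 5))
  expect_equal(unname(pr$pvalues), oracle_exhaustive_p(x, "half_t"))
})

test_that("permutation runs are reproducible and p-values respect their bounds", {
  x <- rand_lem(30, n1 = 6, n0 = 6, seed = 23)
  a <- permutation_null(x, "half_sam", B = 99, seed = 7)
  b <- permutation_null(x, "half_sam", B = 99, seed = 7)
  expect_identical(a$null_scores, b$null_scores)
  expect_identical(a$pvalues, b$pvalues)
  expect_true(all(a$pvalues >= 1 / (a$B + 1)))
  expect_true(all(a$pvalues <= 1))
  # different seed, different draws
  d <- permutation_null(x, "half_sam", B = 99, seed = 8)
  expect_false(identical(a$null_scores, d$null_scores))
})

test_that("a constant matrix yields only zero or undefined permuted scores", {
  x <- labeled_matrix(matrix(5, 3, 8), labels = rep(c(1L, 0L), each = 4))
  suppressWarnings(suppressMessages({
    pr_t <- permutation_null(x, "student_t", B = 50, seed = 1)
    pr_s <- permutation_null(x, "sam", B = 50, seed = 1, c0 = 1)
  }))
  expect_true(all(is.na(pr_t$null_scores)))
  expect_true(all(is.na(pr_t$pvalues)))
  expect_true(all(pr_s$null_scores == 0))
})

test_that("pooled p-values match a direct cross-gene count", {
  x <- rand_lem(12, n1 = 5, n0 = 5, seed = 24, shift = 0.5)
  pr <- permutation_null(x, "half_t", B = 40, seed = 2)
  p <- permutation_pvalues(pr, pooled = TRUE)
  nullv <- abs(as.vector(pr$null_scores))
  manual <- vapply(abs(pr$observed$scores), function(o) {
    (1 + sum(nullv >= o)) / (1 + length(nullv))
  }, numeric(1))
  expect_equal(unname(p), unname(manual))
  expect_gte(min(p), 1 / (1 + length(nullv)))
})

test_that("per-gene permutation p-values are super-uniform under a true null", {
  x <- rand_lem(400, n1 = 8, n0 = 8, seed = 25)
  pr <- permutation_null(x, "half_sam", B = 99, seed = 3)
  for (thr in c(0.05, 0.2, 0.5)) {
    frac <- mean(pr$pvalues <= thr)
    expect_lte(frac, thr + 3 * sqrt(thr * (1 - thr) / 400))
  }
})

test_that("the bootstrap resampling mode produces a valid centred null", {
  x <- rand_lem(100, n1 = 6, n0 = 6, seed = 26, shift = 5)
  pr <- permutation_null(x, "half_t", B = 200, seed = 4, resample = "bootstrap")
  expect_equal(nrow(pr$null_scores), 200)
  # resampled null is centred even though the data carry a large shift
  expect_lt(abs(median(pr$null_scores)), 0.2)
  expect_true(all(pr$pvalues >= 1 / 201 & pr$pvalues <= 1))
  # the big planted shift is detected against the bootstrap null
  expect_gt(mean(pr$pvalues <= 0.05), 0.5)
})

test_that("re-estimating c0 within permutations is available and consistent", {
  x <- rand_lem(60, n1 = 5, n0 = 5, seed = 27)
  pr <- permutation_null(x, "half_sam", B = 25, seed = 5, recompute_c0 = TRUE)
  expect_equal(dim(pr$null_scores), c(25, 60))
  expect_true(all(is.finite(pr$null_scores)))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  out <- bh_fdr(c(0.01, 0.02, 0.03), q = 0.05)
  expect_true(all(out$significant))                 # step-up forces i = 3
  out1 <- bh_fdr(rep(1, 5), q = 0.05)
  expect_false(any(out1$significant))
  expect_equal(unname(out1$adjusted), rep(1, 5))
  expect_length(bh_fdr(numeric(0))$adjusted, 0)

  set.seed(30)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    res <- bh_fdr(p, q)
    expect_identical(res$significant, oracle_bh_flags(p, q))
    # adjusted p monotone in raw-p rank
    expect_true(all(diff(res$adjusted[order(p)]) >= -1e-15))
  }
})

test_that("detect_degs recovers planted genes and respects the threshold semantics", {
  set.seed(31)
  G <- 300
  vals <- matrix(rnorm(G * 12), G)
  planted <- 1:15
  vals[planted, 1:6] <- vals[planted, 1:6] + 6   # huge shift
  x <- labeled_matrix(vals, labels = rep(c(1L, 0L), each = 6))

  tab <- detect_degs(x, "half_sam", threshold_type = "alpha", level = 0.01,
                     B = 400, seed = 9)
  hits <- which(tab$significant)
  expect_true(all(planted %in% hits))
  expect_gte(mean(hits %in% planted), 0.8)
  expect_identical(tab$significant, !is.na(tab$pvalue) & tab$pvalue <= 0.01)

  # FDR mode with a pooled null under the same data
  tabf <- detect_degs(x, "half_sam", threshold_type = "fdr", level = 0.05,
                      B = 400, seed = 9, null = "pooled")
  expect_identical(tabf$significant,
                   !is.na(tabf$padj) & tabf$padj <= 0.05)
  expect_gte(sum(tabf$significant[planted]), 14)
})

test_that("lowering the level never adds DEGs", {
  x <- rand_lem(150, n1 = 6, n0 = 6, seed = 32, shift = 1)
  lv <- c(0.2, 0.05, 0.01)
  tabs <- lapply(lv, function(l)
    detect_degs(x, "student_t", threshold_type = "alpha", level = l,
                B = 200, seed = 10))
  for (i in 2:3) {
    expect_true(all(which(tabs[[i]]$significant) %in%
                      which(tabs[[i - 1]]$significant)))
  }
})

test_that("a global-null matrix produces (almost) no FDR discoveries", {
  x <- rand_lem(500, n1 = 6, n0 = 6, seed = 33)
  tab <- detect_degs(x, "half_sam", threshold_type = "fdr", level = 0.05,
                     B = 200, seed = 11, null = "pooled")
  expect_lte(sum(tab$significant), 2)
})

test_that("level must be explicit and per-gene FDR granularity warns", {
  x <- rand_lem(50, n1 = 5, n0 = 5, seed = 34)
  expect_error(detect_degs(x, "half_t", threshold_type = "alpha", B = 10),
               "level")
  expect_warning(
    detect_degs(x, "half_t", threshold_type = "fdr", level = 0.05,
                B = 30, seed = 1),
    "floor")
})
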