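# Synthetic data generation and the Monte Carlo engine.

test_that("draw_group is moment-matched for every distribution", {
  set.seed(40)
  n <- 1e6
  for (dist in c("normal", "uniform", "gamma_right", "gamma_left")) {
    xs <- draw_group(dist, n, mean = 50, sd = 15, shape = 4)
    expect_lt(abs(mean(xs) - 50), 4 * 15 / sqrt(n))
    expect_lt(abs(sd(xs) - 15) / 15, 0.01)
    skew <- mean((xs - mean(xs))^3) / sd(xs)^3
    if (dist == "gamma_right") expect_gt(skew, 0.5)
    if (dist == "gamma_left") expect_lt(skew, -0.5)
    if (dist %in% c("normal", "uniform")) expect_lt(abs(skew), 0.05)
  }
  # uniform support is mean +/- sqrt(3) sd
  u <- draw_group("uniform", 1e5, mean = 0, sd = 15)
  expect_gte(min(u), -15 * sqrt(3))
  expect_lte(max(u), 15 * sqrt(3))
  expect_lt(abs(min(u) + 15 * sqrt(3)), 0.05)
  expect_error(draw_group("cauchy", 10), "unknown distribution")
})

test_that("scenario validation names the offending field", {
  expect_error(sim_config(r = 0), "`r`")
  expect_error(sim_config(s0 = -1), "`s0`")
  expect_error(sim_config(n0 = 1), "`n0`")
  expect_error(sim_config(distribution = "mixture",
                          mixture_spec = list(weights = c(0.7, 0.6),
                                              mean_shifts = c(0, 2),
                                              sd_scales = c(1, 1))),
               "sum to 1")
})

test_that("simulate_dataset honours shape, labels, and the seed contract", {
  cfg <- sim_config(n0 = 10, n1 = 10, md = 10, n_genes = 200, seed = 41)
  x <- simulate_dataset(cfg)
  expect_equal(dim(x$values), c(200, 20))
  expect_equal(sum(x$labels == 1L), 10)
  expect_identical(x$values, simulate_dataset(cfg)$values)
  expect_true(all(attr(x, "nonnull")))

  cfg2 <- sim_config(md = 10, n_genes = 200, nonnull_fraction = 0.1, seed = 42)
  x2 <- simulate_dataset(cfg2)
  expect_equal(sum(attr(x2, "nonnull")), 20)
  # planted genes carry the shift, the rest do not
  s <- summarize_groups(x2)
  expect_gt(mean(s$mean1[1:20] - s$mean0[1:20]), 5)
  expect_lt(abs(mean(s$mean1[-(1:20)] - s$mean0[-(1:20)])), 3)
})

test_that("md = 0, r = 1 makes case and control draws exchangeable", {
  x <- simulate_dataset(sim_config(md = 0, r = 1, n_genes = 500, seed = 43))
  ks <- suppressWarnings(
    stats::ks.test(as.vector(x$values[, x$labels == 1L]),
                   as.vector(x$values[, x$labels == 0L])))
  expect_gt(ks$p.value, 1e-4)
})

test_that("the mixture case group has the intended marginal mean shift and inflated variance", {
  cfg <- sim_config(md = 10, distribution = "mixture", n_genes = 2000,
                    n1 = 10, n0 = 10, seed = 44)
  x <- simulate_dataset(cfg)
  case <- as.vector(x$values[, x$labels == 1L])
  ctrl <- as.vector(x$values[, x$labels == 0L])
  expect_lt(abs(mean(case) - mean(ctrl) - 10), 0.5)   # marginal shift = md
  # theoretical case variance: s0^2 + md^2 = 225 + 100 (equal-weight components
  # separated by 2 md)
  expect_lt(abs(var(case) - 325) / 325, 0.1)
  expect_gt(var(case), 1.3 * var(ctrl))
})

test_that("the half-t null rejection rate sits at its nominal level", {
  cfg <- sim_config(md = 0, r = 1, reps = 2e4, n_genes = 2000, seed = 45)
  res <- estimate_type1_power(cfg, methods = "half_t")
  expect_equal(res$metric, "type1_error")
  expect_lt(abs(res$rejection_rate - 0.05), 3 * res$mc_se + 1e-3)
  expect_equal(res$mc_se,
               sqrt(res$rejection_rate * (1 - res$rejection_rate) / res$reps))
})

test_that("power grows with md and shrinks with r for the pooled-SD t", {
  rates <- vapply(c(0, 10, 15), function(md) {
    estimate_type1_power(sim_config(md = md, r = 1, reps = 2e4,
                                    n_genes = 2000, seed = 46),
                         methods = "student_t")$rejection_rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  r_rates <- vapply(c(1, 2), function(r) {
    estimate_type1_power(sim_config(md = 10, r = r, reps = 2e4,
                                    n_genes = 2000, seed = 47),
                         methods = "student_t")$rejection_rate
  }, numeric(1))
  expect_gt(r_rates[1], r_rates[2] + 0.03)
})

test_that("estimates do not depend on the control mean mu0", {
  res <- lapply(c(0, 100), function(mu0) {
    estimate_type1_power(
      sim_config(md = 10, mu0 = mu0, reps = 2000, n_genes = 500,
                 B = 50, seed = 48),
      methods = c("student_t", "half_sam"))
  })
  # location invariance is exact: same seed, same draws up to the shift
  expect_identical(res[[1]]$rejection_rate, res[[2]]$rejection_rate)
})

test_that("reps below the minimum are rejected", {
  expect_error(estimate_type1_power(sim_config(reps = 500)), "reps")
})

test_that("FDR-controlled power saturates for huge planted effects and stays near zero under the null", {
  cfg <- sim_config(md = 60, nonnull_fraction = 0.05, reps = 2000,
                    n_genes = 500, B = 100, seed = 49)
  res <- fdr_power_comparison(cfg, methods = c("student_t", "half_sam"))
  expect_true(all(res$power > 0.95))
  expect_true(all(res$mean_fdp < 0.2))

  null_cfg <- sim_config(md = 0, reps = 4000, n_genes = 500, B = 100, seed = 50)
  res0 <- fdr_power_comparison(null_cfg, methods = "half_sam")
  expect_true(is.na(res0$power))
  expect_lte(res0$any_discovery_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / res0$datasets) + 0.05)
})

test_that("scenario grids parse, validate, and run tidily", {
  f <- tempfile(fileext = ".ini")
  writeLines(c("# grid", "[null]", "md = 0", "r = 1",
               "[shift]", "md = 10", "r = 1.5", "distribution = uniform"), f)
  sc <- read_scenario_grid(f, defaults = list(reps = 2000, n_genes = 500,
                                              B = 50, seed = 51))
  expect_named(sc, c("null", "shift"))
  expect_equal(sc$shift$r, 1.5)
  expect_equal(sc$shift$distribution, "uniform")

  res <- run_scenario_grid(sc, methods = c("student_t", "half_t"))
  expect_equal(nrow(res), 4)
  expect_named(res, c("scenario", "method", "metric", "estimate", "mc_se"))
  expect_setequal(unique(res$metric), c("type1_error", "power"))

  writeLines(c("[bad]", "r = -2"), f)
  expect_error(read_scenario_grid(f), "`r`")
  writeLines(c("[bad]", "nosuchfield = 3"), f)
  expect_error(read_scenario_grid(f), "unknown scenario field")
})
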