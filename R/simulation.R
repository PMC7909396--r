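# Monte Carlo engine: synthetic expression data under normal / uniform /
# skewed-gamma / mixture models, and type-I-error / power estimation for the
# four statistics.
#
# The generative model for one scenario: G independent genes; control
# samples drawn with mean mu0 and SD s0; case samples with mean mu0 + md and
# SD r * s0 (r is the case/control SD ratio; heterogeneous case groups have
# r > 1).  All distributions are moment-matched so their population mean and
# SD equal the requested (mean, sd).

#' Simulation scenario configuration
#'
#' @param n0,n1 control / case sample sizes (>= 2 each).
#' @param md mean difference, case minus control.
#' @param r case/control SD ratio (> 0).
#' @param s0 control SD (> 0).
#' @param mu0 control mean.  Every statistic is location invariant, so this
#'   is immaterial; the default 100 resembles intensity-scale data.
#' @param distribution `"normal"`, `"uniform"` (symmetric non-normal),
#'   `"gamma_right"` (right-skewed), `"gamma_left"` (reflected gamma,
#'   left-skewed) or `"mixture"` (heterogeneous case group; see
#'   `mixture_spec`).
#' @param gamma_shape gamma shape parameter (skewness `2/sqrt(shape)`).
#' @param mixture_spec for `distribution = "mixture"`: list with `weights`
#'   (summing to 1), `mean_shifts` (case component mean = `mu0 +
#'   mean_shift * md`) and `sd_scales` (component SD = `sd_scale * s0`).
#'   The default `0.5 N(mu0, s0) + 0.5 N(mu0 + 2 md, s0)` gives a marginal
#'   case mean shift of exactly `md`, modelling a case group in which only a
#'   patient subgroup responds.  Controls are always `N(mu0, s0)` under the
#'   mixture model.
#' @param n_genes genes per simulated dataset.
#' @param reps total simulated gene-level tests (datasets = `reps/n_genes`).
#' @param alpha significance level for per-gene rejection.
#' @param B permutations per dataset for the SAM-variant rejection rule.
#' @param seed optional integer seed.
#' @param nonnull_fraction fraction of genes carrying the mean shift `md`
#'   (the rest get md = 0).  1 reproduces the single-cell-of-the-grid
#'   design; use e.g. 0.05 for planted-truth FDR studies.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' sim_config(md = 10, r = 2, reps = 2000)
sim_config <- function(n0 = 10, n1 = 10, md = 0, r = 1, s0 = 15, mu0 = 100,
                       distribution = c("normal", "uniform", "gamma_right",
                                        "gamma_left", "mixture"),
                       gamma_shape = 4, mixture_spec = NULL,
                       n_genes = 1000, reps = 1e5, alpha = 0.05, B = 200,
                       seed = NULL, nonnull_fraction = 1) {
  distribution <- match.arg(distribution)
  chk <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid scenario: `%s` %s", field, what), call. = FALSE)
  }
  chk(is.numeric(n0) && n0 >= 2, "n0", "must be >= 2")
  chk(is.numeric(n1) && n1 >= 2, "n1", "must be >= 2")
  chk(is.numeric(r) && r > 0, "r", "must be > 0")
  chk(is.numeric(s0) && s0 > 0, "s0", "must be > 0")
  chk(is.numeric(md), "md", "must be numeric")
  chk(is.numeric(gamma_shape) && gamma_shape > 0, "gamma_shape", "must be > 0")
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes", "must be >= 1")
  chk(is.numeric(reps) && reps >= 1, "reps", "must be >= 1")
  chk(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha", "must be in (0, 1)")
  chk(is.numeric(B) && B >= 1, "B", "must be >= 1")
  chk(is.numeric(nonnull_fraction) && nonnull_fraction >= 0 &&
        nonnull_fraction <= 1, "nonnull_fraction", "must be in [0, 1]")
  if (distribution == "mixture") {
    if (is.null(mixture_spec)) {
      mixture_spec <- list(weights = c(0.5, 0.5), mean_shifts = c(0, 2),
                           sd_scales = c(1, 1))
    }
    chk(abs(sum(mixture_spec$weights) - 1) < 1e-8, "mixture_spec",
        "weights must sum to 1")
    chk(length(mixture_spec$weights) == length(mixture_spec$mean_shifts) &&
          length(mixture_spec$weights) == length(mixture_spec$sd_scales),
        "mixture_spec", "weights/mean_shifts/sd_scales must align")
  }
  structure(
    list(n0 = as.integer(n0), n1 = as.integer(n1), md = md, r = r, s0 = s0,
         mu0 = mu0, distribution = distribution, gamma_shape = gamma_shape,
         mixture_spec = mixture_spec, n_genes = as.integer(n_genes),
         reps = reps, alpha = alpha, B = as.integer(B), seed = seed,
         nonnull_fraction = nonnull_fraction),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %s, n1 = %d, n0 = %d, md = %g, r = %g, s0 = %g, %d genes x %g reps\n",
    x$distribution, x$n1, x$n0, x$md, x$r, x$s0, x$n_genes, x$reps))
  invisible(x)
}

#' Draw one group's expression values
#'
#' Moment-matched draws: whatever the shape, the population mean and SD of
#' the construction equal `mean` and `sd`.  `"uniform"` uses
#' `U(mean - sqrt(3) sd, mean + sqrt(3) sd)`; `"gamma_right"` is
#' `Gamma(shape, scale = sd/sqrt(shape))` shifted to the target mean;
#' `"gamma_left"` reflects a gamma draw X as `2 E[X] - X` (flipping the
#' skew) before the same mean alignment.  `mean` may be a vector (recycled
#' over draws), which is how per-gene mean shifts are generated.
#'
#' @param distribution one of `"normal"`, `"uniform"`, `"gamma_right"`,
#'   `"gamma_left"`.
#' @param n number of draws.
#' @param mean target mean (scalar or vector).
#' @param sd target SD (> 0).
#' @param shape gamma shape parameter.
#' @return Numeric vector of length `n`.  Uses the current RNG stream.
#' @export
draw_group <- function(distribution, n, mean = 0, sd = 1, shape = 4) {
  if (!is.numeric(sd) || any(sd <= 0)) stop("`sd` must be > 0", call. = FALSE)
  switch(distribution,
    normal = rnorm(n, mean, sd),
    uniform = runif(n, mean - sqrt(3) * sd, mean + sqrt(3) * sd),
    gamma_right = {
      scale <- sd / sqrt(shape)
      rgamma(n, shape = shape, scale = scale) - shape * scale + mean
    },
    gamma_left = {
      scale <- sd / sqrt(shape)
      shape * scale - rgamma(n, shape = shape, scale = scale) + mean
    },
    stop(sprintf("unknown distribution '%s'", distribution), call. = FALSE)
  )
}

# Raw value matrix for one dataset: G x (n1 + n0), case columns first.
# Consumes the current RNG stream (seeding is the caller's business).
.simulate_values <- function(config) {
  G <- config$n_genes
  md_gene <- rep(0, G)
  k <- round(config$nonnull_fraction * G)
  if (k > 0) md_gene[seq_len(k)] <- config$md

  if (config$distribution == "mixture") {
    ms <- config$mixture_spec
    ncase <- G * config$n1
    comp <- sample.int(length(ms$weights), ncase, replace = TRUE,
                       prob = ms$weights)
    case <- rnorm(ncase,
                  mean = config$mu0 + ms$mean_shifts[comp] * md_gene,
                  sd = ms$sd_scales[comp] * config$s0)
    control <- rnorm(G * config$n0, config$mu0, config$s0)
  } else {
    case <- draw_group(config$distribution, G * config$n1,
                       mean = config$mu0 + md_gene, sd = config$r * config$s0,
                       shape = config$gamma_shape)
    control <- draw_group(config$distribution, G * config$n0,
                          mean = config$mu0, sd = config$s0,
                          shape = config$gamma_shape)
  }
  values <- cbind(matrix(case, G, config$n1), matrix(control, G, config$n0))
  attr(values, "nonnull") <- md_gene != 0
  values
}

#' Simulate one labeled expression dataset
#'
#' @param config a [sim_config()].  When `config$seed` is set the dataset is
#'   reproducible (and the caller's RNG stream is left untouched).
#' @return A [labeled_matrix] with case columns first; the attribute
#'   `nonnull` marks the genes carrying the planted mean shift.
#' @export
#' @examples
#' x <- simulate_dataset(sim_config(md = 10, n_genes = 50, seed = 1))
#' x
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  values <- .with_seed(config$seed, .simulate_values(config))
  x <- labeled_matrix(values,
                      labels = rep(c(1L, 0L), c(config$n1, config$n0)))
  attr(x, "nonnull") <- attr(values, "nonnull")
  x
}

# Shared per-dataset rejection machinery.  Given raw values, computes for
# each requested method either the parametric rejection (t variants:
# |score| > two-sided critical value) or the permutation p-values (SAM
# variants and, when `force_permutation`, all methods).  Returns a list
# with per-method logical rejection vectors or p-value vectors.
.dataset_pvalues <- function(values, config, methods, null,
                             force_permutation = FALSE, want = c("reject", "p")) {
  want <- match.arg(want)
  n1 <- config$n1; n0 <- config$n0; n <- n1 + n0
  fac <- sqrt(1 / n1 + 1 / n0)
  G <- nrow(values)
  labels <- rep(c(1L, 0L), c(n1, n0))
  vals <- values - rowMeans(values)
  obs <- .group_components(vals, cbind(as.numeric(labels == 1L)), n1, n0)

  perm_methods <- if (force_permutation) methods
                  else methods[vapply(methods, .is_sam_method, TRUE)]
  comp_perm <- NULL
  if (length(perm_methods) > 0) {
    case <- vapply(seq_len(config$B), function(b) as.numeric(sample(labels) == 1L),
                   numeric(n))
    comp_perm <- .group_components(vals, case, n1, n0)
  }

  out <- vector("list", length(methods))
  names(out) <- methods
  for (m in methods) {
    c0 <- 0
    if (.is_sam_method(m)) {
      c0 <- estimate_fudge_factor(
        as.vector(obs$num), as.vector(.scatter_matrix(obs, m, fac)))$c0
    }
    score <- as.vector(.score_matrix(obs, m, fac, c0))
    if (m %in% perm_methods) {
      nul <- abs(.score_matrix(comp_perm, m, fac, c0))   # G x B
      ao <- abs(score)
      if (null == "pooled") {
        nullv <- sort(nul[is.finite(nul)])
        cnt <- length(nullv) - findInterval(ao, nullv, left.open = TRUE)
        p <- (1 + cnt) / (1 + length(nullv))
      } else {
        cnt <- rowSums(nul >= ao, na.rm = TRUE)
        Bg <- rowSums(!is.na(nul))
        p <- (1 + cnt) / (1 + Bg)
      }
      p[!is.finite(ao)] <- NA_real_
      out[[m]] <- if (want == "reject") !is.na(p) & p <= config$alpha else p
    } else {
      df <- if (m == "student_t") n1 + n0 - 2 else n0 - 1
      if (want == "reject") {
        crit <- qt(1 - config$alpha / 2, df)
        out[[m]] <- !is.na(score) & abs(score) > crit
      } else {
        out[[m]] <- 2 * stats::pt(abs(score), df, lower.tail = FALSE)
      }
    }
  }
  out
}

#' Monte Carlo type I error and power
#'
#' Repeatedly simulates datasets under `config` and applies each statistic
#' with its per-gene rejection rule: the t variants reject when the absolute
#' score exceeds the two-sided Student-t critical value at `config$alpha`
#' (df = n1+n0-2 for the pooled t, n0-1 for the half t); the SAM variants,
#' whose null is not a t distribution, reject when the label-permutation
#' p-value (B = `config$B` relabelings, c0 frozen at its observed-data
#' estimate) is at most `config$alpha`.  With `md = 0` the rejection rate is
#' the type I error; with `md > 0` it is power.
#'
#' @param config a [sim_config()] with `reps >= 1000` total gene-tests.
#' @param methods statistics to evaluate.
#' @param null permutation p-value convention for the SAM variants.
#' @return A data frame of class `power_estimate`: one row per method with
#'   `metric` (`"type1_error"` or `"power"`), `rejection_rate`,
#'   `mc_se = sqrt(p(1-p)/reps)`, `reps`, and the scenario descriptors.
#' @export
#' @examples
#' estimate_type1_power(sim_config(md = 10, reps = 2000, seed = 1),
#'                      methods = c("student_t", "half_t"))
estimate_type1_power <- function(config,
                                 methods = HALF_SAM_METHODS,
                                 null = c("pergene", "pooled")) {
  stopifnot(inherits(config, "sim_config"))
  null <- match.arg(null)
  methods <- vapply(methods, .match_method, character(1))
  if (config$reps < 1000) {
    stop("invalid scenario: `reps` must be at least 1000", call. = FALSE)
  }
  ndat <- ceiling(config$reps / config$n_genes)

  .with_seed(config$seed, {
    hits <- stats::setNames(numeric(length(methods)), methods)
    total <- stats::setNames(numeric(length(methods)), methods)
    for (d in seq_len(ndat)) {
      values <- .simulate_values(config)
      keep <- if (config$md != 0 && config$nonnull_fraction < 1) {
        attr(values, "nonnull")
      } else rep(TRUE, nrow(values))
      rej <- .dataset_pvalues(values, config, methods, null, want = "reject")
      for (m in methods) {
        hits[m] <- hits[m] + sum(rej[[m]][keep])
        total[m] <- total[m] + sum(keep)
      }
    }
  })

  rate <- hits / total
  out <- data.frame(
    method = methods,
    metric = if (config$md == 0 || config$nonnull_fraction == 0)
      "type1_error" else "power",
    rejection_rate = unname(rate),
    mc_se = unname(sqrt(rate * (1 - rate) / total)),
    reps = unname(total),
    distribution = config$distribution,
    n1 = config$n1, n0 = config$n0,
    md = config$md, r = config$r, s0 = config$s0,
    alpha = config$alpha, B = config$B,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("power_estimate", "data.frame")
  out
}

#' Power after Benjamini-Hochberg FDR control
#'
#' For each simulated dataset, computes permutation p-values for every
#' requested statistic (t variants included, for a like-for-like
#' comparison), applies BH at level `q`, and records the true-positive rate
#' over the planted non-null genes.  Under an all-null configuration the
#' true-positive rate is undefined and the at-least-one-discovery rate is
#' the quantity of interest.
#'
#' The pooled permutation null is the default here: per-gene p-values are
#' bounded below by `1/(B+1)`, which BH at level `q` over `G` genes can
#' essentially never clear unless `B` is of order `G/q` (see
#' [detect_degs()]).
#'
#' @param config a [sim_config()]; plant non-nulls via `nonnull_fraction < 1`
#'   (or use `md > 0` with fraction 1).
#' @param methods statistics to evaluate.
#' @param q BH FDR level.
#' @param null permutation p-value convention.
#' @return A data frame of class `fdr_power`: per method, `power` (mean TPR
#'   over datasets, `NA` under the global null), `mc_se` (SE of that mean),
#'   `any_discovery_rate`, `mean_fdp` (mean false-discovery proportion) and
#'   `datasets`.
#' @export
fdr_power_comparison <- function(config,
                                 methods = HALF_SAM_METHODS,
                                 q = 0.05,
                                 null = c("pooled", "pergene")) {
  stopifnot(inherits(config, "sim_config"))
  null <- match.arg(null)
  methods <- vapply(methods, .match_method, character(1))
  ndat <- max(1L, as.integer(ceiling(config$reps / config$n_genes)))

  tpr <- matrix(NA_real_, ndat, length(methods),
                dimnames = list(NULL, methods))
  fdp <- matrix(NA_real_, ndat, length(methods),
                dimnames = list(NULL, methods))
  anyd <- matrix(FALSE, ndat, length(methods),
                 dimnames = list(NULL, methods))

  .with_seed(config$seed, {
    for (d in seq_len(ndat)) {
      values <- .simulate_values(config)
      truth <- attr(values, "nonnull")
      ps <- .dataset_pvalues(values, config, methods, null,
                             force_permutation = TRUE, want = "p")
      for (m in methods) {
        sig <- bh_fdr(ps[[m]], q = q)$significant
        anyd[d, m] <- any(sig)
        if (any(truth)) tpr[d, m] <- mean(sig[truth])
        fdp[d, m] <- if (any(sig)) mean(!truth[sig]) else 0
      }
    }
  })

  out <- data.frame(
    method = methods,
    power = colMeans(tpr),
    mc_se = apply(tpr, 2, sd) / sqrt(ndat),
    any_discovery_rate = colMeans(anyd),
    mean_fdp = colMeans(fdp),
    datasets = ndat, q = q,
    distribution = config$distribution, md = config$md, r = config$r,
    nonnull_fraction = config$nonnull_fraction,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("fdr_power", "data.frame")
  out
}
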