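# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (loops, stats::sd) so they never share code paths with
# the package internals they check.

# One-gene labeled matrix from explicit case/control values.
lem1 <- function(case, control, ...) {
  lem_genes(list(case), list(control), ...)
}

# Multi-gene labeled matrix from lists of per-gene case/control values.
lem_genes <- function(case_list, control_list, gene_ids = NULL) {
  stopifnot(length(case_list) == length(control_list))
  values <- t(mapply(c, case_list, control_list))
  n1 <- length(case_list[[1]])
  n0 <- length(control_list[[1]])
  labeled_matrix(matrix(values, nrow = length(case_list)),
                 labels = rep(c(1L, 0L), c(n1, n0)), gene_ids = gene_ids)
}

rand_lem <- function(G, n1, n0, seed, shift = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(G * (n1 + n0), sd = 2), G)
  vals[, seq_len(n1)] <- vals[, seq_len(n1)] + shift
  labeled_matrix(vals, labels = rep(c(1L, 0L), c(n1, n0)))
}

# Textbook statistic for one gene, straight from the formulas.
oracle_stat <- function(case, control, method, c0 = 0) {
  n1 <- length(case)
  n0 <- length(control)
  num <- mean(case) - mean(control)
  fac <- sqrt(1 / n1 + 1 / n0)
  sp <- sqrt(((n1 - 1) * stats::var(case) + (n0 - 1) * stats::var(control)) /
               (n1 + n0 - 2))
  den <- switch(method,
                student_t = sp * fac,
                half_t = stats::sd(control) * fac,
                sam = sp * fac + c0,
                half_sam = stats::sd(control) * fac + c0)
  if (den == 0) NA_real_ else num / den
}

# Exhaustive enumeration of every label assignment (including the observed
# one) for a small matrix; returns per-gene two-sided p-values under the
# add-one convention used by the package.
oracle_exhaustive_p <- function(x, method, c0 = 0) {
  n <- length(x$labels)
  n1 <- sum(x$labels == 1L)
  assigns <- utils::combn(n, n1)
  B <- ncol(assigns)
  G <- nrow(x$values)
  obs <- vapply(seq_len(G), function(g) {
    oracle_stat(x$values[g, x$labels == 1L], x$values[g, x$labels == 0L],
                method, c0)
  }, numeric(1))
  p <- numeric(G)
  for (g in seq_len(G)) {
    cnt <- 0L
    defined <- 0L
    for (b in seq_len(B)) {
      idx <- assigns[, b]
      s <- oracle_stat(x$values[g, idx], x$values[g, -idx], method, c0)
      if (!is.na(s)) {
        defined <- defined + 1L
        if (abs(s) >= abs(obs[g])) cnt <- cnt + 1L
      }
    }
    p[g] <- if (is.na(obs[g])) NA_real_ else (1 + cnt) / (1 + defined)
  }
  p
}

# Benjamini-Hochberg step-up significance flags by scanning every rank
# threshold explicitly.
oracle_bh_flags <- function(p, q) {
  n <- length(p)
  o <- order(p)
  k <- 0L
  for (i in seq_len(n)) if (p[o[i]] <= q * i / n) k <- i
  flags <- rep(FALSE, n)
  if (k > 0) flags[o[seq_len(k)]] <- TRUE
  flags
}

# Naive re-evaluation of the fudge-factor criterion over the full grid.
oracle_fudge <- function(num, sca, percentiles = seq(0, 100, 5), n_windows = 100) {
  cand <- quantile(sca, percentiles / 100, names = FALSE)
  breaks <- unique(quantile(sca, seq(0, 1, length.out = n_windows + 1),
                            names = FALSE))
  win <- cut(sca, breaks, include.lowest = TRUE)
  best <- NULL
  best_cv <- Inf
  for (i in seq_along(cand)) {
    d <- num / (sca + cand[i])
    mads <- c()
    for (lev in levels(win)) {
      dd <- d[win == lev & is.finite(d)]
      if (length(dd) > 0) mads <- c(mads, stats::mad(dd))
    }
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2 || mean(mads) == 0) next
    cv <- stats::sd(mads) / mean(mads)
    if (cv < best_cv) {
      best_cv <- cv
      best <- list(c0 = cand[i], percentile = percentiles[i])
    }
  }
  best
}
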