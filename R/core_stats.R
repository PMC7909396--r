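# Core per-gene statistics: group summaries, the four scores, and the
# fudge-factor (c0) estimator.
#
# All four scores share the numerator X1bar - X0bar and differ only in the
# denominator scatter:
#   ts   = num / (sp * sqrt(1/n1 + 1/n0))          pooled SD, df = n1+n0-2
#   th   = num / (s0 * sqrt(1/n1 + 1/n0))          control SD only, df = n0-1
#   dSAM = num / (sp * sqrt(1/n1 + 1/n0) + c0)     moderated
#   dh   = num / (s0 * sqrt(1/n1 + 1/n0) + c0)     moderated, control SD only

# Vectorised group moments for one or many case/control assignments.
# `values` is the G x n data matrix (callers should row-centre it first so
# the computation is exactly location invariant); `case` is an n x B 0/1
# matrix, one assignment per column.  Returns G x B matrices.
.group_components <- function(values, case, n1, n0) {
  s1 <- values %*% case
  s0 <- rowSums(values) - s1
  sq <- values^2
  q1 <- sq %*% case
  q0 <- rowSums(sq) - q1
  m1 <- s1 / n1
  m0 <- s0 / n0
  # clamp tiny negative round-off in the sums-of-squares form
  v1 <- pmax((q1 - n1 * m1^2) / (n1 - 1), 0)
  v0 <- pmax((q0 - n0 * m0^2) / (n0 - 1), 0)
  list(
    num = m1 - m0,
    mean1 = m1, mean0 = m0,
    sd1 = sqrt(v1), sd0 = sqrt(v0),
    sp = sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  )
}

# Denominator scatter (without c0) for a method, as a G x B matrix.
.scatter_matrix <- function(comp, method, fac) {
  switch(method,
    student_t = ,
    sam = comp$sp * fac,
    half_t = ,
    half_sam = comp$sd0 * fac
  )
}

# Scores for a method given components; zero denominators give NA.
.score_matrix <- function(comp, method, fac, c0 = 0) {
  den <- .scatter_matrix(comp, method, fac) + c0
  s <- comp$num / den
  s[den == 0] <- NA_real_
  s
}

#' Per-gene group summaries
#'
#' Computes, for every gene, the case/control sample sizes, means, standard
#' deviations (denominator n - 1) and the pooled standard deviation
#' `sp = sqrt(((n1-1) s1^2 + (n0-1) s0^2) / (n1 + n0 - 2))`.
#'
#' @param x a [labeled_matrix].
#' @return A data frame of class `group_summary` with columns `gene_id`,
#'   `n1`, `n0`, `mean1`, `mean0`, `sd1`, `sd0`, `sp`.
#' @export
#' @examples
#' x <- labeled_matrix(rbind(g1 = c(2, 2, 4, 4, 0, 0, 2, 2)),
#'                     labels = c(1, 1, 1, 1, 0, 0, 0, 0))
#' summarize_groups(x)
summarize_groups <- function(x) {
  .assert_labeled_matrix(x)
  n1 <- sum(x$labels == 1L)
  n0 <- sum(x$labels == 0L)
  ctr <- rowMeans(x$values)
  comp <- .group_components(x$values - ctr, cbind(as.numeric(x$labels == 1L)),
                            n1, n0)
  out <- data.frame(
    gene_id = x$gene_ids,
    n1 = n1, n0 = n0,
    mean1 = as.vector(comp$mean1) + ctr,
    mean0 = as.vector(comp$mean0) + ctr,
    sd1 = as.vector(comp$sd1),
    sd0 = as.vector(comp$sd0),
    sp = as.vector(comp$sp),
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_summary", "data.frame")
  out
}

.assert_group_summary <- function(s) {
  if (!inherits(s, "group_summary")) {
    stop("expected a `group_summary`; see ?summarize_groups", call. = FALSE)
  }
  invisible(s)
}

.summary_fac <- function(s) sqrt(1 / s$n1[1] + 1 / s$n0[1])

# Assemble a score_vector object and warn once about undefined genes.
.make_score_vector <- function(method, scores, gene_ids, df = NULL, c0 = NULL) {
  undefined <- is.na(scores)
  if (any(undefined)) {
    warning(sprintf("%d gene(s) with zero denominator flagged undefined for %s",
                    sum(undefined), method), call. = FALSE)
  }
  names(scores) <- gene_ids
  structure(
    list(method = method, scores = scores, df = df, c0 = c0,
         undefined = undefined),
    class = "score_vector"
  )
}

#' @export
print.score_vector <- function(x, ...) {
  extra <- if (!is.null(x$df)) sprintf(", df = %g", x$df)
           else sprintf(", c0 = %.4g", x$c0)
  cat(sprintf("score_vector: %s, %d genes%s, %d undefined\n",
              x$method, length(x$scores), extra, sum(x$undefined)))
  invisible(x)
}

#' The four differential-expression scores
#'
#' `student_t_scores()` is the pooled two-sample t statistic
#' (df = n1 + n0 - 2); `half_t_scores()` replaces the pooled SD with the
#' control-group SD `s0` (df = n0 - 1, valid when only the control group is
#' homogeneous); `sam_scores()` adds the fudge factor `c0` to the pooled
#' scatter (the SAM moderated score); `half_sam_scores()` adds `c0` to the
#' control-only scatter -- the half-SAM score, aimed at case groups with
#' inflated variance.  Genes whose denominator is exactly zero are flagged
#' undefined (`NA` score) and excluded from downstream calls.
#'
#' @param summary a [summarize_groups()] result.
#' @param c0 fudge factor: a non-negative number or a
#'   [estimate_fudge_factor()] result.
#' @return A `score_vector`: list with `method`, per-gene `scores`, `df` (t
#'   variants) or `c0` (SAM variants), and an `undefined` flag vector.
#' @seealso [estimate_fudge_factor()], [detect_degs()]
#' @export
#' @examples
#' x <- labeled_matrix(rbind(g1 = c(2, 2, 4, 4, 0, 0, 2, 2)),
#'                     labels = c(1, 1, 1, 1, 0, 0, 0, 0))
#' s <- summarize_groups(x)
#' student_t_scores(s)$scores  # sqrt(6)
#' half_sam_scores(s, c0 = 1)$scores
student_t_scores <- function(summary) {
  .assert_group_summary(summary)
  den <- summary$sp * .summary_fac(summary)
  scores <- ifelse(den == 0, NA_real_, (summary$mean1 - summary$mean0) / den)
  .make_score_vector("student_t", scores, summary$gene_id,
                     df = summary$n1[1] + summary$n0[1] - 2)
}

#' @rdname student_t_scores
#' @export
half_t_scores <- function(summary) {
  .assert_group_summary(summary)
  den <- summary$sd0 * .summary_fac(summary)
  scores <- ifelse(den == 0, NA_real_, (summary$mean1 - summary$mean0) / den)
  .make_score_vector("half_t", scores, summary$gene_id,
                     df = summary$n0[1] - 1)
}

.c0_value <- function(c0) {
  if (inherits(c0, "fudge_factor")) c0 <- c0$c0
  if (!is.numeric(c0) || length(c0) != 1 || is.na(c0) || c0 < 0) {
    stop("`c0` must be a single non-negative number", call. = FALSE)
  }
  c0
}

#' @rdname student_t_scores
#' @export
sam_scores <- function(summary, c0) {
  .assert_group_summary(summary)
  c0 <- .c0_value(c0)
  den <- summary$sp * .summary_fac(summary) + c0
  scores <- ifelse(den == 0, NA_real_, (summary$mean1 - summary$mean0) / den)
  .make_score_vector("sam", scores, summary$gene_id, c0 = c0)
}

#' @rdname student_t_scores
#' @export
half_sam_scores <- function(summary, c0) {
  .assert_group_summary(summary)
  c0 <- .c0_value(c0)
  den <- summary$sd0 * .summary_fac(summary) + c0
  scores <- ifelse(den == 0, NA_real_, (summary$mean1 - summary$mean0) / den)
  .make_score_vector("half_sam", scores, summary$gene_id, c0 = c0)
}

# Score a summary by method name, estimating c0 from the summary itself
# when a SAM variant is requested and c0 is NULL.
.score_summary <- function(summary, method, c0 = NULL) {
  method <- .match_method(method)
  if (!.is_sam_method(method)) {
    return(switch(method,
                  student_t = student_t_scores(summary),
                  half_t = half_t_scores(summary)))
  }
  if (is.null(c0)) {
    scatter <- .scatter_matrix(list(sp = summary$sp, sd0 = summary$sd0),
                               method, .summary_fac(summary))
    c0 <- estimate_fudge_factor(summary$mean1 - summary$mean0, scatter)
  }
  switch(method,
         sam = sam_scores(summary, c0),
         half_sam = half_sam_scores(summary, c0))
}

#' Estimate the SAM fudge factor c0
#'
#' Chooses the additive denominator constant `c0` that stabilises the
#' moderated score across the spread of per-gene scatters.  Candidates are
#' percentiles (default 0, 5, ..., 100) of the per-gene scatter; for each
#' candidate the genes are partitioned into `n_windows` scatter-quantile
#' windows, the median absolute deviation (MAD) of the candidate scores is
#' taken within each window, and the candidate minimising the coefficient of
#' variation of these MADs is selected.  Ties (including a completely flat
#' profile, e.g. when every gene has the same scatter) break to the lowest
#' percentile.
#'
#' For the half-SAM score the scatter to pass is the control-only
#' denominator `s0 * sqrt(1/n1 + 1/n0)`, mirroring the `dh` denominator; for
#' SAM it is the pooled `sp * sqrt(1/n1 + 1/n0)`.
#'
#' @param numerators per-gene mean differences (case - control).
#' @param scatters per-gene non-negative denominator scatters, same length
#'   (at least 20 genes).
#' @param percentiles candidate grid, percent scale in `[0, 100]`.
#' @param n_windows number of scatter-quantile windows for the MAD profile.
#' @return An object of class `fudge_factor`: list with `c0`, the chosen
#'   `percentile`, and the full `cv_profile` (named by percentile) for audit.
#' @export
#' @examples
#' set.seed(1)
#' num <- rnorm(500)
#' sca <- rlnorm(500, sdlog = 0.5)
#' estimate_fudge_factor(num, sca)
estimate_fudge_factor <- function(numerators, scatters,
                                  percentiles = seq(0, 100, by = 5),
                                  n_windows = 100) {
  numerators <- as.numeric(numerators)
  scatters <- as.numeric(scatters)
  if (length(numerators) != length(scatters)) {
    stop("`numerators` and `scatters` must have the same length", call. = FALSE)
  }
  if (length(scatters) < 20) {
    stop("fudge-factor estimation needs at least 20 genes", call. = FALSE)
  }
  if (anyNA(scatters) || any(scatters < 0)) {
    stop("`scatters` must be non-negative and complete", call. = FALSE)
  }
  if (all(scatters == 0)) {
    stop("invalid input: all scatters are zero; c0 is unidentifiable", call. = FALSE)
  }
  if (any(percentiles < 0 | percentiles > 100)) {
    stop("`percentiles` must lie in [0, 100]", call. = FALSE)
  }
  percentiles <- sort(percentiles)
  cand <- quantile(scatters, percentiles / 100, names = FALSE)

  breaks <- unique(quantile(scatters, seq(0, 1, length.out = n_windows + 1),
                            names = FALSE))
  window <- if (length(breaks) >= 3) {
    cut(scatters, breaks = breaks, include.lowest = TRUE)
  } else {
    factor(rep(1L, length(scatters)))
  }

  cv_profile <- vapply(cand, function(c0) {
    d <- numerators / (scatters + c0)
    d[!is.finite(d)] <- NA_real_
    mads <- tapply(d, window, mad, na.rm = TRUE)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2 || mean(mads) == 0) return(NA_real_)
    sd(mads) / mean(mads)
  }, numeric(1))
  names(cv_profile) <- percentiles

  pick <- if (all(!is.finite(cv_profile))) 1L else which.min(cv_profile)
  structure(
    list(c0 = cand[pick], percentile = percentiles[pick],
         cv_profile = cv_profile),
    class = "fudge_factor"
  )
}

#' @export
print.fudge_factor <- function(x, ...) {
  cat(sprintf("fudge_factor: c0 = %.6g (percentile %g of the scatter)\n",
              x$c0, x$percentile))
  invisible(x)
}
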