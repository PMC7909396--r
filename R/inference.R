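# Permutation inference and DEG calling.
#
# The SAM family has no usable parametric null (the fudge factor breaks the
# t distribution), so significance comes from relabeling the samples: for
# each of B relabelings that preserve the group sizes, the full statistic is
# recomputed -- including the control SD from the permuted control group.
# The fudge factor c0 is frozen at its observed-data estimate by default.

#' Permutation null distribution of a score
#'
#' Recomputes the chosen statistic under `B` random relabelings of the
#' sample labels (group sizes preserved).  When `B` is at least the number
#' of distinct label assignments `choose(n, n1)`, all assignments are
#' enumerated instead (exhaustive mode, with a notice).  A bootstrap
#' alternative resamples within groups with replacement after centring each
#' gene's groups on their means (so the resampled null has no mean shift).
#'
#' @param x a [labeled_matrix].
#' @param method one of `"student_t"`, `"half_t"`, `"sam"`, `"half_sam"`.
#' @param B number of relabelings (>= 1).
#' @param seed optional integer seed; the global RNG stream is restored
#'   afterwards.
#' @param resample `"permutation"` (default) or `"bootstrap"`.
#' @param c0 fudge factor for SAM variants; estimated from the observed data
#'   with [estimate_fudge_factor()] when `NULL`.
#' @param recompute_c0 if `TRUE`, re-estimate c0 within every relabeling
#'   instead of freezing the observed-data value (slower; provided for
#'   sensitivity checks).
#' @return An object of class `perm_result`: list with `method`, `observed`
#'   (a `score_vector`), `null_scores` (B x genes matrix), `B`, `seed`,
#'   `exhaustive`, `resample`, `c0`, and per-gene `pvalues` (the default,
#'   non-pooled convention; see [permutation_pvalues()]).
#' @seealso [permutation_pvalues()], [detect_degs()]
#' @export
permutation_null <- function(x, method, B = 1000, seed = NULL,
                             resample = c("permutation", "bootstrap"),
                             c0 = NULL, recompute_c0 = FALSE) {
  .assert_labeled_matrix(x)
  method <- .match_method(method)
  resample <- match.arg(resample)
  if (!is.numeric(B) || length(B) != 1 || B < 1) {
    stop("`B` must be a positive count", call. = FALSE)
  }
  B <- as.integer(B)

  n <- length(x$labels)
  n1 <- sum(x$labels == 1L)
  n0 <- n - n1
  fac <- sqrt(1 / n1 + 1 / n0)
  G <- nrow(x$values)
  vals <- x$values - rowMeans(x$values)  # exact location invariance

  obs_comp <- .group_components(vals, cbind(as.numeric(x$labels == 1L)), n1, n0)
  if (.is_sam_method(method) && is.null(c0)) {
    c0 <- estimate_fudge_factor(
      as.vector(obs_comp$num),
      as.vector(.scatter_matrix(obs_comp, method, fac))
    )
  }
  c0v <- if (.is_sam_method(method)) .c0_value(c0) else 0
  observed <- .make_score_vector(
    method, as.vector(.score_matrix(obs_comp, method, fac, c0v)),
    x$gene_ids,
    df = switch(method, student_t = n1 + n0 - 2, half_t = n0 - 1),
    c0 = if (.is_sam_method(method)) c0v
  )

  exhaustive <- FALSE
  .with_seed(seed, {
    if (resample == "permutation") {
      n_assign <- choose(n, n1)
      if (B >= n_assign) {
        message(sprintf(
          "B = %d >= %d distinct label assignments; enumerating exhaustively",
          B, n_assign))
        exhaustive <- TRUE
        B <- as.integer(n_assign)
        case <- matrix(0, n, B)
        case[cbind(as.vector(combn(n, n1)), rep(seq_len(B), each = n1))] <- 1
      } else {
        case <- vapply(seq_len(B), function(b) as.numeric(sample(x$labels) == 1L),
                       numeric(n))
      }
      comp <- .group_components(vals, case, n1, n0)
    } else {
      # bootstrap null: centre each group on its per-gene mean, then draw
      # samples with replacement within each group
      centred <- vals
      centred[, x$labels == 1L] <- vals[, x$labels == 1L] - as.vector(obs_comp$mean1)
      centred[, x$labels == 0L] <- vals[, x$labels == 0L] - as.vector(obs_comp$mean0)
      idx1 <- which(x$labels == 1L)
      idx0 <- which(x$labels == 0L)
      cnt1 <- vapply(seq_len(B), function(b)
        tabulate(sample(idx1, n1, replace = TRUE), nbins = n), numeric(n))
      cnt0 <- vapply(seq_len(B), function(b)
        tabulate(sample(idx0, n0, replace = TRUE), nbins = n), numeric(n))
      comp <- .bootstrap_components(centred, cnt1, cnt0, n1, n0)
    }

    if (.is_sam_method(method) && isTRUE(recompute_c0)) {
      scat <- .scatter_matrix(comp, method, fac)
      null_scores <- vapply(seq_len(B), function(b) {
        cb <- estimate_fudge_factor(comp$num[, b], scat[, b])$c0
        s <- comp$num[, b] / (scat[, b] + cb)
        s[scat[, b] + cb == 0] <- NA_real_
        s
      }, numeric(G))
      null_scores <- matrix(null_scores, G, B)
    } else {
      null_scores <- .score_matrix(comp, method, fac, c0v)
    }
  })

  res <- structure(
    list(method = method, observed = observed,
         null_scores = t(null_scores), B = B, seed = seed,
         exhaustive = exhaustive, resample = resample,
         c0 = if (.is_sam_method(method)) c0v),
    class = "perm_result"
  )
  res$pvalues <- permutation_pvalues(res)
  res
}

# Moments from within-group bootstrap count matrices (n x B, column sums n1
# and n0).  Sample variance of a multiset works through the weighted
# sums-of-squares identity.
.bootstrap_components <- function(values, cnt1, cnt0, n1, n0) {
  sq <- values^2
  m1 <- (values %*% cnt1) / n1
  m0 <- (values %*% cnt0) / n0
  v1 <- pmax(((sq %*% cnt1) - n1 * m1^2) / (n1 - 1), 0)
  v0 <- pmax(((sq %*% cnt0) - n0 * m0^2) / (n0 - 1), 0)
  list(num = m1 - m0, mean1 = m1, mean0 = m0,
       sd1 = sqrt(v1), sd0 = sqrt(v0),
       sp = sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)))
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("perm_result: %s, %d genes, B = %d%s (%s)\n",
              x$method, length(x$observed$scores), x$B,
              if (x$exhaustive) " [exhaustive]" else "", x$resample))
  invisible(x)
}

#' Two-sided permutation p-values
#'
#' With the default per-gene convention, each gene's p-value is
#' `(1 + #\{|null_b| >= |observed|\}) / (B + 1)` over that gene's own B
#' permuted scores (the add-one estimator never returns 0).  The pooled
#' convention emulates SAM's cross-gene null: every gene is compared against
#' the permuted scores of all genes pooled, `(1 + count) / (1 + B * G)`.
#' Undefined observed scores give `NA`.
#'
#' @param result a [permutation_null()] result.
#' @param pooled use the pooled cross-gene null instead of the per-gene null.
#' @return Named per-gene p-value vector.
#' @export
permutation_pvalues <- function(result, pooled = FALSE) {
  if (!inherits(result, "perm_result")) {
    stop("expected a `perm_result`; see ?permutation_null", call. = FALSE)
  }
  an <- abs(result$null_scores)                 # B x G
  ao <- abs(result$observed$scores)
  G <- length(ao)
  if (pooled) {
    nullv <- sort(an[is.finite(an)])
    cnt <- length(nullv) - findInterval(ao, nullv, left.open = TRUE)
    p <- (1 + cnt) / (1 + length(nullv))
  } else {
    cnt <- colSums(an >= matrix(ao, nrow(an), G, byrow = TRUE), na.rm = TRUE)
    Bg <- colSums(!is.na(an))
    p <- (1 + cnt) / (1 + Bg)
  }
  p[!is.finite(ao)] <- NA_real_
  names(p) <- names(ao)
  p
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment of raw p-values; a gene is significant when its
#' adjusted p-value is at most `q`.  `NA` p-values (undefined genes) are
#' excluded from the adjustment and never significant.
#'
#' @param pvalues raw p-values in `[0, 1]` (may contain `NA`).
#' @param q FDR level.
#' @return List with `adjusted` (same length/names as `pvalues`) and
#'   `significant` (logical).
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03), q = 0.05)
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) {
    return(list(adjusted = numeric(0), significant = logical(0)))
  }
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adjusted <- rep(NA_real_, length(pvalues))
  adjusted[ok] <- p.adjust(pvalues[ok], method = "BH")
  names(adjusted) <- names(pvalues)
  list(adjusted = adjusted,
       significant = !is.na(adjusted) & adjusted <= q)
}

#' Call differentially expressed genes
#'
#' The full workflow: per-gene group summaries, fudge-factor estimation (SAM
#' variants), scoring, permutation p-values, and thresholding either on the
#' raw p-value (`threshold_type = "alpha"`) or on the Benjamini-Hochberg
#' adjusted p-value (`threshold_type = "fdr"`).  Undefined genes (zero
#' denominator) are retained in the table with `NA` score/p-value and are
#' never called significant.
#'
#' Note on granularity: per-gene p-values cannot fall below `1/(B+1)`, so
#' FDR calling in `null = "pergene"` mode needs `B` large relative to the
#' gene count (roughly `B >= G/level`); the pooled null has floor
#' `1/(B*G+1)` and is the practical choice for FDR pipelines.
#'
#' @inheritParams permutation_null
#' @param threshold_type `"fdr"` (BH-adjusted) or `"alpha"` (raw p-value
#'   cut-off).  No default level: `level` must be given explicitly.
#' @param level the FDR level or significance level.
#' @param null p-value convention: `"pergene"` (default) or `"pooled"`.
#' @return A data frame of class `deg_table` with columns `gene_id`,
#'   `method`, `score`, `pvalue`, `padj`, `significant`, and attributes
#'   `threshold_type`, `level`, `B`, `seed`, `null`, `c0`/`df`.
#' @seealso [write_results()]
#' @export
#' @examples
#' set.seed(42)
#' x <- labeled_matrix(matrix(rnorm(50 * 12), 50), labels = rep(c(1, 0), each = 6))
#' tab <- detect_degs(x, "half_sam", threshold_type = "alpha", level = 0.05,
#'                    B = 100, seed = 1)
#' head(tab)
detect_degs <- function(x, method, threshold_type = c("fdr", "alpha"), level,
                        B = 1000, seed = NULL,
                        null = c("pergene", "pooled"),
                        resample = c("permutation", "bootstrap"),
                        c0 = NULL, recompute_c0 = FALSE) {
  .assert_labeled_matrix(x)
  method <- .match_method(method)
  threshold_type <- match.arg(threshold_type)
  null <- match.arg(null)
  if (missing(level) || !is.numeric(level) || length(level) != 1 ||
      level <= 0 || level >= 1) {
    stop("`level` must be given explicitly, in (0, 1)", call. = FALSE)
  }

  pr <- permutation_null(x, method, B = B, seed = seed,
                         resample = match.arg(resample),
                         c0 = c0, recompute_c0 = recompute_c0)
  p <- if (null == "pooled") permutation_pvalues(pr, pooled = TRUE) else pr$pvalues

  G <- length(p)
  if (threshold_type == "fdr") {
    if (null == "pergene" && (pr$B + 1) < G / level) {
      warning(sprintf(
        paste("per-gene p-value floor 1/(B+1) = %.3g is coarse for BH at level %g",
              "over %d genes; consider null = \"pooled\" or a larger B"),
        1 / (pr$B + 1), level, G), call. = FALSE)
    }
    bh <- bh_fdr(p, q = level)
    padj <- bh$adjusted
    significant <- bh$significant
  } else {
    padj <- rep(NA_real_, G)
    significant <- !is.na(p) & p <= level
  }

  out <- data.frame(
    gene_id = x$gene_ids, method = method,
    score = unname(pr$observed$scores),
    pvalue = unname(p), padj = unname(padj),
    significant = unname(significant),
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("deg_table", "data.frame"),
            threshold_type = threshold_type, level = level,
            B = pr$B, seed = seed, null = null,
            c0 = pr$c0, df = pr$observed$df)
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("deg_table: %s, %d genes, %d significant (%s %g, B = %d, %s null)\n",
              x$method[1], nrow(x), sum(x$significant),
              attr(x, "threshold_type"), attr(x, "level"),
              attr(x, "B"), attr(x, "null")))
  NextMethod()
}
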