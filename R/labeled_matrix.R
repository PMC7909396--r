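#' Labeled expression matrix
#'
#' The basic input container: a numeric genes x samples matrix with a binary
#' case/control label per sample.  Values may be intensities or counts, on
#' the original or log scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns; no
#'   missing values.
#' @param labels per-sample group membership: case = 1, control = 0 (a
#'   numeric/integer vector, or a logical vector with `TRUE` = case).  Each
#'   group needs at least 2 samples.
#' @param gene_ids character vector of row identifiers; defaults to the
#'   rownames of `values`, or `gene_0001`-style ids.
#'
#' @return An object of class `labeled_matrix`: a list with elements
#'   `values`, `labels` (integer 0/1) and `gene_ids`, plus a `log2_transformed`
#'   flag used by [log_transform()].
#' @seealso [summarize_groups()], [detect_degs()], [read_expression_matrix()]
#' @export
#' @examples
#' x <- labeled_matrix(matrix(rnorm(40), 10, 4), labels = c(1, 1, 0, 0))
#' x
labeled_matrix <- function(values, labels, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain missing values", call. = FALSE)
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be binary: case = 1, control = 0", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(values)) {
    stop(sprintf("%d labels for %d sample columns", length(labels), ncol(values)),
         call. = FALSE)
  }
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("invalid design: each group needs at least 2 samples", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) {
    stop(sprintf("%d gene ids for %d rows", length(gene_ids), nrow(values)),
         call. = FALSE)
  }
  rownames(values) <- gene_ids
  structure(
    list(values = values, labels = labels, gene_ids = gene_ids,
         log2_transformed = FALSE),
    class = "labeled_matrix"
  )
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf(
    "labeled_matrix: %d genes x %d samples (%d case / %d control)%s\n",
    nrow(x$values), ncol(x$values), sum(x$labels == 1L), sum(x$labels == 0L),
    if (isTRUE(x$log2_transformed)) ", log2 scale" else ""
  ))
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

.assert_labeled_matrix <- function(x) {
  if (!inherits(x, "labeled_matrix")) {
    stop("expected a `labeled_matrix`; see ?labeled_matrix", call. = FALSE)
  }
  invisible(x)
}
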