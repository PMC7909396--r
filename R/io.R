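# File formats: tab-delimited expression matrices (including the Alon
# colon-cancer label dialect), count-matrix filtering, log transform, and
# DEG-table round-tripping.

#' Read a tab-delimited expression matrix with group labels
#'
#' The matrix file is genes x samples: first row sample ids, first column
#' gene ids, tab separated, numeric cells.  The label file holds one entry
#' per sample (whitespace/line separated).  Two dialects:
#' \describe{
#'   \item{alon}{signed sample identifiers as distributed with the colon
#'     adenocarcinoma dataset of Alon and colleagues: a positive id marks a
#'     tumour (case) sample, a negative id a normal (control) sample.}
#'   \item{generic}{explicit tokens per sample: `case`/`control` (also
#'     accepted: `1`/`0`, `tumor`/`normal`).}
#' }
#' `dialect = "auto"` picks `alon` when every entry parses as a number.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param labels_path path to the label file.
#' @param dialect `"auto"`, `"alon"` or `"generic"`.
#' @return A [labeled_matrix].
#' @export
read_expression_matrix <- function(matrix_path, labels_path,
                                   dialect = c("auto", "alon", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(matrix_path)) stop(sprintf("no such file: %s", matrix_path),
                                      call. = FALSE)
  if (!file.exists(labels_path)) stop(sprintf("no such file: %s", labels_path),
                                      call. = FALSE)

  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character",
                    row.names = NULL)
  if (ncol(raw) < 2) stop("format error: matrix needs a gene-id column plus samples",
                          call. = FALSE)
  gene_ids <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells),
                                    dimnames = dimnames(cells)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("format error: non-numeric cell at gene '%s', sample '%s'",
                 gene_ids[bad[1]], colnames(cells)[bad[2]]), call. = FALSE)
  }

  tokens <- scan(labels_path, what = character(), quiet = TRUE)
  if (length(tokens) != ncol(values)) {
    stop(sprintf("format error: %d label entries for %d sample columns",
                 length(tokens), ncol(values)), call. = FALSE)
  }
  nums <- suppressWarnings(as.numeric(tokens))
  if (dialect == "auto") dialect <- if (!anyNA(nums) && any(nums < 0)) "alon"
                                    else if (!anyNA(nums) && all(nums %in% c(0, 1))) "generic"
                                    else if (!anyNA(nums)) "alon" else "generic"
  labels <- if (dialect == "alon") {
    if (anyNA(nums)) stop("format error: alon labels must be signed numbers",
                          call. = FALSE)
    as.integer(nums > 0)  # positive id = tumour/case, negative = normal/control
  } else {
    tok <- tolower(tokens)
    map <- c(case = 1L, tumor = 1L, tumour = 1L, "1" = 1L,
             control = 0L, normal = 0L, "0" = 0L)
    if (!all(tok %in% names(map))) {
      stop(sprintf("format error: unrecognised label token '%s'",
                   tok[!tok %in% names(map)][1]), call. = FALSE)
    }
    unname(map[tok])
  }
  labeled_matrix(values, labels = labels, gene_ids = gene_ids)
}

#' Raw count matrix
#'
#' Non-negative integer counts, genes x samples, as produced by an upstream
#' RNA-seq quantification.
#'
#' @param counts non-negative integral matrix.
#' @param gene_ids,sample_ids identifiers; default to dimnames.
#' @return An object of class `raw_count_matrix`.
#' @export
raw_count_matrix <- function(counts, gene_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("`counts` must be a non-negative integral matrix", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- colnames(counts)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(counts = counts, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "raw_count_matrix")
}

#' @export
print.raw_count_matrix <- function(x, ...) {
  cat(sprintf("raw_count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Keep genes with a positive total count
#'
#' Retains exactly the genes whose count sum across the selected samples is
#' greater than zero, preserving order -- the usual pre-filter before
#' differential expression on RNA-seq counts.
#'
#' @param counts a [raw_count_matrix()].
#' @param samples optional sample ids (or column indices) over which to take
#'   the row sums; defaults to all samples.
#' @return A filtered `raw_count_matrix`.
#' @export
filter_positive_total_counts <- function(counts, samples = NULL) {
  stopifnot(inherits(counts, "raw_count_matrix"))
  sel <- if (is.null(samples)) seq_len(ncol(counts$counts)) else samples
  keep <- rowSums(counts$counts[, sel, drop = FALSE]) > 0
  raw_count_matrix(counts$counts[keep, , drop = FALSE],
                   gene_ids = counts$gene_ids[keep],
                   sample_ids = counts$sample_ids)
}

#' Log2 transform of an expression matrix
#'
#' Elementwise `log2(x + pseudocount)`.  Count data conventionally uses
#' `pseudocount = 1`; intensity data already bounded away from zero can use
#' 0.  The transform is recorded on the object and applying it twice is an
#' error.
#'
#' @param x a [labeled_matrix].
#' @param pseudocount added before taking logs; every `value + pseudocount`
#'   must be strictly positive.
#' @return The transformed [labeled_matrix] with `log2_transformed = TRUE`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  .assert_labeled_matrix(x)
  if (isTRUE(x$log2_transformed)) {
    stop("matrix is already log2 transformed", call. = FALSE)
  }
  shifted <- x$values + pseudocount
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "log transform undefined at gene '%s', sample column %d (value %g + pseudocount %g <= 0)",
      x$gene_ids[bad[1]], bad[2], x$values[bad[1], bad[2]], pseudocount),
      call. = FALSE)
  }
  x$values <- log2(shifted)
  x$log2_transformed <- TRUE
  x
}

#' Write / read a DEG table
#'
#' Tab-separated with header `gene_id, method, score, pvalue, padj,
#' significant`, in stable column order; `write_results()` followed by
#' `read_results()` round-trips the table.
#'
#' @param table a [detect_degs()] result (or any data frame with those
#'   columns).
#' @param path output file.
#' @export
write_results <- function(table, path) {
  cols <- c("gene_id", "method", "score", "pvalue", "padj", "significant")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    stop(sprintf("table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  ok <- tryCatch({
    write.table(as.data.frame(table)[, cols], file = path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("cannot write results to '%s': %s",
                                path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
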