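#' Expression set container
#'
#' Bundles a genes x samples matrix of log-scale expression intensities with
#' the per-sample condition labels.  Rows are genes, columns are samples;
#' labels are stored as a factor whose levels define the condition order used
#' everywhere else in the package (condition k = level k).
#'
#' @param x numeric matrix, genes in rows, samples in columns.  Row and column
#'   names are kept if present, otherwise `gene1..geneG` / `sample1..samplen`
#'   are assigned.
#' @param labels vector of condition labels, one per column of `x`.  Coerced
#'   to a factor; at least two conditions with at least two samples each are
#'   required by the estimators downstream.
#' @return An object of class `expr_set`: a list with elements `x` (the
#'   matrix) and `labels` (factor of length `ncol(x)`).
#' @examples
#' es <- expression_set(matrix(rnorm(40), 4, 10), rep(c("a", "b"), each = 5))
#' es
#' @export
expression_set <- function(x, labels) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop("expression matrix must be numeric", call. = FALSE)
  }
  if (length(labels) != ncol(x)) {
    stop("need one condition label per sample (column): got ", length(labels),
         " labels for ", ncol(x), " columns", call. = FALSE)
  }
  if (anyNA(x)) stop("expression matrix contains missing values", call. = FALSE)
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(as.character(labels)))
  if (nlevels(labels) < 2) {
    stop("at least two conditions are required", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifiers", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("sample", seq_len(ncol(x)))
  structure(list(x = x, labels = labels), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$x), "genes x", ncol(x$x), "samples,",
      nlevels(x$labels), "conditions (",
      paste(sprintf("%s: n=%d", levels(x$labels), tabulate(x$labels)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$x)

# samples of each condition as a list of column indices, in level order
condition_index <- function(labels) {
  split(seq_along(labels), labels)
}

# per-condition sample counts in level order
condition_counts <- function(labels) {
  as.integer(tabulate(labels, nbins = nlevels(labels)))
}

check_group_sizes <- function(labels, min_n = 2L) {
  nk <- condition_counts(labels)
  if (any(nk < min_n)) {
    stop("insufficient data: every condition needs at least ", min_n,
         " samples (got ", paste(nk, collapse = ", "), ")", call. = FALSE)
  }
  invisible(nk)
}

#' Read an expression matrix with condition labels from delimited text
#'
#' The matrix file is TSV or CSV (chosen by the `.csv` extension), genes as
#' rows, a header row of sample identifiers, and the gene identifier in the
#' first column.  Labels come either from a two-column file (sample id,
#' condition) or directly as a vector.
#'
#' @param path path to the matrix file.
#' @param labels either a path to a two-column label file (with or without a
#'   header) or a vector of labels in column order.
#' @return an [expression_set()].
#' @export
read_expression <- function(path, labels) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))
    stop("non-numeric expression column(s): ",
         paste(colnames(tab)[-1][bad], collapse = ", "), call. = FALSE)
  }
  rownames(mat) <- ids
  if (length(labels) == 1 && is.character(labels) && file.exists(labels)) {
    lab <- utils::read.table(labels, header = FALSE, sep = sep,
                             stringsAsFactors = FALSE, quote = "")
    if (nrow(lab) == ncol(mat) + 1L && !lab[1, 1] %in% colnames(mat)) {
      lab <- lab[-1, , drop = FALSE]  # tolerate a header line
    }
    if (ncol(lab) < 2 || nrow(lab) != ncol(mat)) {
      stop("label file must have one (sample id, condition) row per sample",
           call. = FALSE)
    }
    m <- match(colnames(mat), as.character(lab[[1]]))
    if (anyNA(m)) {
      stop("label file is missing samples: ",
           paste(colnames(mat)[is.na(m)], collapse = ", "), call. = FALSE)
    }
    labels <- as.character(lab[[2]])[m]
  }
  expression_set(mat, labels)
}

#' Write an expression set as delimited text
#'
#' Inverse of [read_expression()]: writes the matrix with gene ids in the
#' first column (named `gene`), plus a sidecar two-column label file when
#' `labels_path` is given.  Values are written at full precision so that a
#' read/write round trip is lossless.
#'
#' @param es an [expression_set()].
#' @param path output matrix path (`.csv` switches to comma separation).
#' @param labels_path optional output path for the (sample, condition) table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(es, path, labels_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(gene = rownames(es$x), es$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample = colnames(es$x), condition = as.character(es$labels)),
      labels_path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
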