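#' Expression matrix container
#'
#' Lightweight S3 container for a genes-by-samples expression matrix.
#' Rows are genes, columns are samples.  Optional two-class sample labels
#' (integer 1/2) may be attached; they are used only for external
#' evaluation and for signal-to-noise computation after unsupervised
#' pre-clustering.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; must
#'   carry unique rownames (gene IDs) and colnames (sample IDs).
#' @param class_labels Optional integer vector in `{1, 2}`, one per sample.
#' @return An object of class `expr_matrix` with elements `values`,
#'   `gene_ids`, `sample_ids` and `class_labels`.
#' @export
expr_matrix <- function(values, class_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (anyNA(values))
    stop("missing values in expression matrix")
  if (!is.null(class_labels)) {
    class_labels <- as.integer(class_labels)
    if (length(class_labels) != ncol(values))
      stop("class_labels length must equal the number of samples")
    if (!all(class_labels %in% c(1L, 2L)))
      stop("class_labels must be 1 or 2")
  }
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 class_labels = class_labels),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$class_labels)) "" else
                sprintf(" (classes: %d/%d)",
                        sum(x$class_labels == 1L),
                        sum(x$class_labels == 2L))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from delimited text
#'
#' Expects the first row to hold sample IDs and the first column gene IDs,
#' with a numeric body.  Ragged rows, duplicate gene IDs and non-numeric
#' cells are rejected.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("expression file needs a header and >= 1 gene row")
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in expression file")
  header <- parts[[1L]]
  sample_ids <- header[-1L]
  body <- parts[-1L]
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs in expression file")
  vals <- t(vapply(body, function(p) {
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v)) stop("non-numeric cell in expression file")
    v
  }, numeric(length(sample_ids))))
  dimnames(vals) <- list(gene_ids, sample_ids)
  expr_matrix(vals)
}

#' Write an expression matrix as delimited text
#'
#' @param expr An [expr_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @param digits Number of significant digits written.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path, delimiter = "\t", digits = 10) {
  stopifnot(inherits(expr, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", expr$sample_ids), collapse = delimiter), con)
  for (i in seq_along(expr$gene_ids)) {
    writeLines(paste(c(expr$gene_ids[i],
                       formatC(expr$values[i, ], digits = digits,
                               format = "g")),
                     collapse = delimiter), con)
  }
  invisible(path)
}

#' Log-transform and standardize an expression matrix
#'
#' Applies `log2` to all values, then standardizes each sample (column)
#' to mean 0 and population (1/N) variance 1.  Per-gene standardization
#' is available for data already oriented the other way.
#'
#' @param expr An [expr_matrix()].
#' @param log_base Base of the log transform (default 2); `NA` skips the
#'   log step.
#' @param shift Constant added before the log for data containing
#'   non-positive values; default 0 (non-positive values are an error).
#' @param by `"sample"` (default) or `"gene"`: the margin standardized to
#'   mean 0, variance 1.
#' @return A preprocessed [expr_matrix()] (class labels preserved).
#' @export
preprocess_expression <- function(expr, log_base = 2, shift = 0,
                                  by = c("sample", "gene")) {
  stopifnot(inherits(expr, "expr_matrix"))
  by <- match.arg(by)
  v <- expr$values
  if (!is.na(log_base)) {
    v <- v + shift
    if (any(v <= 0))
      stop("non-positive values; supply a shift before the log transform")
    v <- log(v, base = log_base)
  }
  margin <- if (by == "sample") 2L else 1L
  v <- apply(v, margin, function(col) {
    s <- pop_sd(col)
    if (s < 1e-12) stop("zero-variance ", by, " after log transform")
    (col - mean(col)) / s
  })
  # apply() returns the iterated margin in columns; restore orientation
  if (by == "gene") v <- t(v)
  dimnames(v) <- dimnames(expr$values)
  expr_matrix(v, expr$class_labels)
}
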