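#' Expression matrix with sample annotation
#'
#' Lightweight container pairing a genes x samples matrix of normalised,
#' log2-scale expression values with a per-sample annotation table. The
#' annotation must carry at least a `group` column (the experimental
#' condition); `sex`, `litter` and `cross` are carried along when present.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames). All values must be finite.
#' @param samples Data frame with one row per sample; must contain
#'   `sample_id` matching `colnames(values)` and a `group` column.
#' @return An object of class `expr_set`: a list with elements `values` and
#'   `samples`.
#' @export
expression_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stopf("'values' must have unique rownames (gene identifiers)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stopf("'values' must have unique colnames (sample identifiers)")
  if (!all(is.finite(values)))
    stopf("'values' contains non-finite entries")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples))
    stopf("'samples' must contain a 'sample_id' column")
  if (!"group" %in% names(samples))
    stopf("'samples' must contain a 'group' column")
  if (!setequal(samples$sample_id, colnames(values)) ||
      anyDuplicated(samples$sample_id))
    stopf("'samples$sample_id' must match colnames(values) one-to-one")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  for (col in c("sex", "litter", "cross"))
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("groups: ",
      paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                    as.integer(table(x$samples$group))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Drop genes not expressed on any sample
#'
#' Mirrors the detection-call step of array analysis: a gene is retained when
#' its expression exceeds `floor` in at least one sample; genes at or below
#' the floor everywhere are removed. Gene order is preserved.
#'
#' @param x An [expression_set()].
#' @param floor Expression threshold on the matrix scale (log2); default 0.
#'   `-Inf` retains everything.
#' @return An `expr_set` restricted to retained genes.
#' @export
filter_unexpressed <- function(x, floor = 0) {
  if (!inherits(x, "expr_set")) stopf("'x' must be an expr_set")
  if (length(floor) != 1L || is.na(floor) || is.nan(floor))
    stopf("'floor' must be a single non-missing number")
  keep <- apply(x$values, 1L, max) > floor
  if (!any(keep))
    stopf("filter_unexpressed: no gene exceeds floor %s in any sample",
          format(floor))
  expression_set(x$values[keep, , drop = FALSE], x$samples)
}

#' Write / read an expression set as TSV
#'
#' The matrix file has a leading `gene_id` column followed by one column per
#' sample; the annotation file has columns `sample_id`, `group`, `sex`,
#' `litter`, `cross`.
#'
#' @param x An [expression_set()].
#' @param matrix_path,meta_path File paths for the matrix and annotation.
#' @return `write_expression_tsv` returns the paths invisibly;
#'   `read_expression_tsv` returns an `expr_set`.
#' @export
write_expression_tsv <- function(x, matrix_path, meta_path) {
  if (!inherits(x, "expr_set")) stopf("'x' must be an expr_set")
  mat <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mat, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples[, c("sample_id", "group", "sex", "litter", "cross")],
                     meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(matrix_path, meta_path) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(mat)[1] != "gene_id")
    stopf("matrix file must start with a 'gene_id' column: %s", matrix_path)
  values <- as.matrix(mat[, -1, drop = FALSE])
  rownames(values) <- mat$gene_id
  samples <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  expression_set(values, samples)
}
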