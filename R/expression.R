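#' Construct a feature-by-sample expression matrix
#'
#' Thin wrapper around a numeric matrix (log2 scale by convention) that
#' enforces unique feature and sample ids and records whether the features
#' are miRNAs or mRNAs.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids). Missing values are
#'   allowed and must be `NA`, never zero-filled.
#' @param feature_kind `"miRNA"` or `"mRNA"`.
#' @return A numeric matrix of class `expression_matrix` with attribute
#'   `feature_kind`.
#' @export
expression_matrix <- function(values, feature_kind = c("miRNA", "mRNA")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs rownames (features) and colnames (samples)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated feature id: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicated sample id: ", paste(unique(dup), collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA")
  structure(values, feature_kind = feature_kind,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d features x %d samples, %d missing\n",
              attr(x, "feature_kind"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expected layout: first row holds sample ids, first column feature ids,
#' remaining cells numeric log2 intensities. Empty cells are read as missing
#' (`NA`); they are never silently replaced by zero.
#'
#' @param path Path to a TSV file.
#' @inheritParams expression_matrix
#' @return An [expression_matrix].
#' @export
read_expression_tsv <- function(path, feature_kind = c("miRNA", "mRNA")) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), quote = "")
  if (ncol(raw) < 2L) stop("expression table needs >= 1 sample column")
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature id: ", paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!is.na(cells) & is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 samples[bad[1, 2]]))
  dimnames(num) <- list(ids, samples)
  expression_matrix(num, feature_kind)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv]: full-precision round trip.
#'
#' @param x An [expression_matrix] (or numeric matrix with dimnames).
#' @param path Output path.
#' @param id_column Header of the feature-id column; default `"feature_id"`.
#' @export
write_expression_tsv <- function(x, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(x),
                   as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
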