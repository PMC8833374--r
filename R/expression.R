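#' Construct an expression matrix container
#'
#' Holds a genes x samples matrix of log2-scale intensities plus optional
#' per-sample annotations (cell type, compartment, group, ...).
#'
#' @param values Numeric matrix, rows = genes (rownames = gene ids),
#'   columns = samples (colnames = sample ids).  All values must be finite.
#' @param annotations Optional data.frame with a `sample_id` column matching
#'   `colnames(values)`; additional columns are free-form annotations.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, annotations = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (is.null(annotations)) {
    annotations <- data.frame(sample_id = colnames(values),
                              stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(annotations), "sample_id" %in% names(annotations))
    if (!identical(sort(as.character(annotations$sample_id)),
                   sort(colnames(values))))
      stop("annotations$sample_id must match the matrix sample ids",
           call. = FALSE)
    annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(list(values = values, annotations = annotations),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  extra <- setdiff(names(x$annotations), "sample_id")
  if (length(extra))
    cat("  annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by sample ids
#'
#' @param x An [expression_matrix].
#' @param sample_ids Character vector of sample ids to keep, in the order
#'   given.
#' @return An [expression_matrix] restricted to those samples.
#' @export
subset_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "expression_matrix"))
  missing <- setdiff(sample_ids, colnames(x$values))
  if (length(missing))
    stop("unknown sample ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  expression_matrix(x$values[, sample_ids, drop = FALSE],
                    x$annotations[match(sample_ids, x$annotations$sample_id), ,
                                  drop = FALSE])
}

#' Read an expression matrix from TSV
#'
#' Format: tab-separated, first column `gene_id`, header row of sample ids,
#' log2-scale numeric values, `#`-prefixed comment lines ignored.
#'
#' @param path Path to a TSV file.
#' @return An [expression_matrix] (without annotations).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression TSV '", path, "' needs a gene_id column and at least ",
         "one sample column", call. = FALSE)
  gene_id <- as.character(df[[1]])
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene id(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric cells in '", path, "', column(s): ",
         paste(names(vals)[non_num], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- gene_id
  expression_matrix(m)
}

#' Write an expression matrix to TSV
#'
#' Lossless round-trip with [read_expression_tsv()] up to float formatting
#' (values written with full `%.10g` precision).  A `#` comment header
#' records the writing tool.
#'
#' @param x An [expression_matrix].
#' @param path Output path.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header("expression matrix, log2 intensities"), con)
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(row)
    paste(sprintf("%.10g", row), collapse = "\t"))
  writeLines(paste(rownames(x$values), body, sep = "\t"), con)
  invisible(path)
}
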