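#' Expression matrix container
#'
#' A light wrapper around a numeric gene x sample matrix carrying a `layer`
#' tag that records what the values are: raw counts (`"counts"`), a
#' length/depth-normalized abundance such as FPKM (`"abundance"`), or
#' log2-standardized values (`"log2"`). Gene identifiers live in the row
#' names and sample identifiers in the column names; both must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   row and column names set.
#' @param layer one of `"counts"`, `"abundance"`, `"log2"`.
#' @return An object of class `expr_matrix` (a classed numeric matrix with a
#'   `layer` attribute).
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- expr_matrix(m, "counts")
#' expr_layer(em)
#' @export
expr_matrix <- function(values, layer = c("counts", "abundance", "log2")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene identifier: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample identifier: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  if (layer != "log2" && any(values < 0)) {
    stop("negative value in '", layer, "' layer", call. = FALSE)
  }
  if (layer == "counts" && any(values != floor(values))) {
    stop("counts layer must contain integers", call. = FALSE)
  }
  structure(values, layer = layer, class = c("expr_matrix", class(values)))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_layer <- function(x) attr(x, "layer")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, layer = %s\n",
              nrow(x), ncol(x), expr_layer(x)))
  invisible(x)
}

as_plain_matrix <- function(x) {
  attr(x, "layer") <- NULL
  class(x) <- "matrix"
  # matrices in R >= 4 are also "array"
  unclass(as.matrix(x))
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers (gene-major layout, the common export format of RNA-seq
#' quantification pipelines).
#'
#' @param path file path.
#' @param layer layer tag to declare for the values (see [expr_matrix()]).
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path, layer = c("counts", "abundance", "log2")) {
  layer <- match.arg(layer)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("malformed expression file '", path,
         "': need a gene id column plus at least one sample column", call. = FALSE)
  }
  gene_ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric cell in column '%s', row %d of %s",
                   names(vals)[j], if (is.na(bad)) NA else bad, path),
           call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  expr_matrix(m, layer)
}

#' Write an expression matrix as tab-separated text
#'
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @param id_column name for the gene id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_column = "gene_id") {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(rownames(x), as_plain_matrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-standardize expression values
#'
#' Applies `log2(x + pseudocount)` cell-wise, the standardization used before
#' correlation clustering and k-nearest-neighbor classification. The
#' pseudocount keeps zeros finite; the default 0.01 maps a zero to
#' `log2(0.01) = -6.64`.
#'
#' @param m an [expr_matrix()] in the `counts` or `abundance` layer.
#' @param pseudocount positive offset added before the log (default 0.01).
#' @return an [expr_matrix()] with layer `"log2"`.
#' @export
log2_standardize <- function(m, pseudocount = 0.01) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_layer(m) == "log2") {
    stop("matrix is already log2-standardized", call. = FALSE)
  }
  assert_scalar_number(pseudocount, "pseudocount", lower = 1e-12)
  if (any(m < 0)) stop("negative input cell", call. = FALSE)
  out <- log2(as_plain_matrix(m) + pseudocount)
  expr_matrix(out, "log2")
}
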