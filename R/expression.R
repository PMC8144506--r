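#' Expression matrices and biotype annotation
#'
#' Expression data are held as plain numeric matrices with genes in rows
#' (unique rownames) and samples in columns (unique colnames), the
#' convention of most expression-analysis toolchains. Values may be raw
#' counts, normalized abundances, or already-transformed (e.g. simulated
#' Gaussian-scale) expression; they must be finite.
#'
#' @name expression-matrix
#' @keywords internal
NULL

#' Validate an expression matrix
#'
#' @param x numeric matrix, genes x samples, with unique row and column
#'   names and finite values.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(x))) stop("non-finite values in expression matrix")
  invisible(x)
}

#' Read a gene x sample expression matrix
#'
#' Tab-separated, first column gene id, header row of sample ids. Integer
#' inputs round-trip bit-identically through [write_expression()].
#'
#' @param path path to the expression table.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs a gene column plus samples")
  genes <- as.character(df[[1L]])
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- genes
  validate_expression(x)
  x
}

#' Write an expression matrix
#' @param x numeric expression matrix (genes x samples).
#' @param path output path.
#' @param digits significant digits for non-integer values.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, digits = 10L) {
  validate_expression(x)
  vals <- if (all(x == round(x))) {
    format(x, scientific = FALSE, trim = TRUE)
  } else {
    signif(x, digits)
  }
  df <- data.frame(gene_id = rownames(x), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene biotype annotation
#'
#' Two tab-separated columns: gene id, biotype (`mRNA` or `lncRNA`).
#'
#' @param path path to the annotation table.
#' @return Named character vector mapping gene id -> biotype.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation table needs gene id and biotype columns")
  a <- stats::setNames(trimws(as.character(df[[2L]])), trimws(as.character(df[[1L]])))
  bad <- !a %in% .TARGET_CLASSES
  if (any(bad)) {
    stop("invalid biotype(s): ", paste(unique(a[bad]), collapse = ", "))
  }
  if (anyDuplicated(names(a))) stop("duplicate gene ids in annotation")
  a
}

#' Write a gene biotype annotation
#' @param annotation named character vector gene id -> biotype.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(gene_id = names(annotation), biotype = unname(annotation),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes with low total expression
#'
#' Drops genes whose row sum over all samples is strictly below
#' `min_total`; a gene summing exactly to the threshold is kept. The
#' default mirrors a total-count filter of 100 across the samples of a
#' study. Sample set and gene order are preserved.
#'
#' @param x expression matrix (genes x samples).
#' @param min_total non-negative threshold on the per-gene row sum.
#' @return Filtered expression matrix.
#' @export
filter_low_expression <- function(x, min_total = 100) {
  validate_expression(x)
  stopifnot(is.numeric(min_total), length(min_total) == 1L, min_total >= 0)
  if (min_total == 0) return(x)   # identity, also for signed-scale input
  keep <- rowSums(x) >= min_total
  if (!any(keep)) {
    stop("low-expression filter removed every gene (min_total = ",
         min_total, " is over-aggressive for this matrix)")
  }
  x[keep, , drop = FALSE]
}

#' Transform expression values
#'
#' `log2p1` maps v -> log2(v + 1) elementwise (requires non-negative
#' input); `none` is the identity. The correlation and causal stages must
#' consume the same transformed matrix; the pipeline guarantees this.
#'
#' @param x expression matrix.
#' @param mode `"log2p1"` or `"none"`.
#' @return Transformed matrix.
#' @export
transform_expression <- function(x, mode = c("log2p1", "none")) {
  mode <- match.arg(mode)
  validate_expression(x)
  if (mode == "none") return(x)
  if (any(x < 0)) stop("log2p1 transform requires non-negative values")
  log2(x + 1)
}

#' Partition an expression matrix by biotype
#'
#' @param x expression matrix.
#' @param annotation named character vector gene id -> biotype
#'   (`mRNA`/`lncRNA`); every gene of `x` must be annotated.
#' @return List with elements `lncrna` and `mrna`, the two disjoint
#'   submatrices (possibly zero-row) whose union of genes equals `x`'s.
#' @export
split_by_biotype <- function(x, annotation) {
  validate_expression(x)
  genes <- rownames(x)
  missing <- setdiff(genes, names(annotation))
  if (length(missing)) {
    stop("unannotated gene(s): ", paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "")
  }
  bio <- annotation[genes]
  list(
    lncrna = x[bio == "lncRNA", , drop = FALSE],
    mrna = x[bio == "mRNA", , drop = FALSE]
  )
}
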