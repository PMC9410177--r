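# Expression matrix container: genes x samples FPKM with sample metadata.

#' Construct an annotated FPKM expression matrix
#'
#' Bundles a nonnegative genes x samples FPKM matrix with its sample sheet.
#' Each sample carries the variety, tissue, developmental stage (days after
#' anthesis, DAA), replicate number and the dataset panel it belongs to
#' (multi-organ atlas, oil-content seed time series, or seed-color time
#' series).
#'
#' @param fpkm numeric matrix, genes in rows (rownames required), samples in
#'   columns
#' @param samples data.frame with columns `sample_id`, `dataset`, `variety`,
#'   `tissue`, `stage`, `replicate`; `sample_id` must match `colnames(fpkm)`
#' @return object of class `expression_set`
#' @export
expression_set <- function(fpkm, samples) {
  fpkm <- as.matrix(fpkm)
  if (nrow(fpkm) > 0 && is.null(rownames(fpkm))) {
    stopf("fpkm matrix must have gene rownames")
  }
  if (any(fpkm < 0)) stopf("FPKM values must be nonnegative")
  need <- c("sample_id", "dataset", "variety", "tissue", "stage", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(samples[need])) stopf("every sample must be fully annotated (NA found)")
  if (!identical(colnames(fpkm), as.character(samples$sample_id))) {
    stopf("colnames(fpkm) must equal samples$sample_id (same order)")
  }
  key <- do.call(paste, c(samples[c("variety", "tissue", "stage", "replicate")], sep = "\r"))
  if (anyDuplicated(key)) stopf("(variety, tissue, stage, replicate) must be unique")
  structure(list(fpkm = fpkm, samples = samples), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples\n", nrow(x$fpkm), ncol(x$fpkm)))
  cat("datasets:", paste(unique(x$samples$dataset), collapse = ", "), "\n")
  cat("varieties:", paste(unique(x$samples$variety), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$fpkm)

#' Subset an expression set by sample predicate
#'
#' @param expr an `expression_set`
#' @param dataset optional dataset label(s) to keep
#' @param variety optional variety label(s) to keep
#' @param genes optional gene ids to keep
#' @return an `expression_set`
#' @export
subset_expression <- function(expr, dataset = NULL, variety = NULL, genes = NULL) {
  keep <- rep(TRUE, nrow(expr$samples))
  if (!is.null(dataset)) keep <- keep & expr$samples$dataset %in% dataset
  if (!is.null(variety)) keep <- keep & expr$samples$variety %in% variety
  fpkm <- expr$fpkm[, keep, drop = FALSE]
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(fpkm))
    if (length(miss)) stopf("unknown gene(s): %s", paste(miss, collapse = ", "))
    fpkm <- fpkm[genes, , drop = FALSE]
  }
  structure(list(fpkm = fpkm, samples = expr$samples[keep, , drop = FALSE]),
            class = "expression_set")
}

#' Write an expression set as TSV matrix + sample sheet
#' @param expr an `expression_set`
#' @param matrix_path,samples_path output TSV paths
#' @export
write_expression_set <- function(expr, matrix_path, samples_path) {
  df <- data.frame(gene_id = rownames(expr$fpkm), expr$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$samples, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read an expression set from TSV matrix + sample sheet
#' @param matrix_path,samples_path TSV paths written by [write_expression_set()]
#' @return an `expression_set`
#' @export
read_expression_set <- function(matrix_path, samples_path) {
  df <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  fpkm <- as.matrix(df[, -1, drop = FALSE])
  rownames(fpkm) <- df$gene_id
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  expression_set(fpkm, samples)
}

# Mean FPKM per gene for a sample subset (replicates and any remaining
# stage structure averaged).
mean_fpkm <- function(expr, which_samples) {
  rowMeans(expr$fpkm[, which_samples, drop = FALSE])
}
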