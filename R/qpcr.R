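# qPCR relative quantification (2^-ddCt) and RNA-seq concordance.

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged arithmetically per gene x sample;
#' `dCt = Ct_gene - Ct_reference` within each sample, `ddCt = dCt_sample -
#' dCt_calibrator` within each gene, and relative expression is `2^-ddCt`
#' (amplification efficiency fixed at 2, no efficiency correction). Every
#' gene's value at the calibrator sample is exactly 1.
#'
#' @param records data.frame `gene`, `sample`, `replicate`, `ct`
#' @param reference_gene housekeeping gene, measured in every sample
#' @param calibrator_sample sample to which expression is relative, measured
#'   for every gene
#' @return data.frame `gene`, `sample`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr` for every non-reference gene x sample
#' @export
ddct <- function(records, reference_gene, calibrator_sample) {
  if (any(!is.finite(records$ct))) stopf("Ct values must be finite")
  mean_ct <- aggregate(ct ~ gene + sample, data = records, FUN = mean)
  samples <- unique(mean_ct$sample)
  ref <- mean_ct[mean_ct$gene == reference_gene, , drop = FALSE]
  miss <- setdiff(samples, ref$sample)
  if (!nrow(ref)) stopf("reference gene '%s' absent from the Ct table", reference_gene)
  if (length(miss)) {
    stopf("reference gene '%s' not measured in sample(s): %s",
          reference_gene, paste(miss, collapse = ", "))
  }
  if (!calibrator_sample %in% samples) {
    stopf("calibrator sample '%s' absent from the Ct table", calibrator_sample)
  }
  tgt <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]
  genes <- unique(tgt$gene)
  no_cal <- setdiff(genes, tgt$gene[tgt$sample == calibrator_sample])
  if (length(no_cal)) {
    stopf("gene(s) not measured at calibrator sample '%s': %s",
          calibrator_sample, paste(no_cal, collapse = ", "))
  }
  ref_ct <- setNames(ref$ct, ref$sample)
  tgt$delta_ct <- tgt$ct - ref_ct[tgt$sample]
  cal <- tgt[tgt$sample == calibrator_sample, , drop = FALSE]
  cal_dct <- setNames(cal$delta_ct, cal$gene)
  tgt$delta_delta_ct <- tgt$delta_ct - cal_dct[tgt$gene]
  tgt$rel_expr <- 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$sample),
             c("gene", "sample", "delta_ct", "delta_delta_ct", "rel_expr")]
  rownames(out) <- NULL
  out
}

#' Concordance between qPCR relative expression and RNA-seq FPKM
#'
#' R-squared is the squared Pearson correlation between `log2(relative
#' expression)` and `log2(FPKM + pseudocount)` over the shared
#' (gene, sample) points.
#'
#' @param qpcr_values data.frame `gene`, `sample`, `rel_expr` (as from
#'   [ddct()])
#' @param rnaseq_fpkm data.frame `gene`, `sample`, `fpkm`, or an
#'   [expression_set()] whose cells are matched by gene row and sample
#'   column
#' @param pseudocount added to FPKM before log2 (default 1)
#' @return list with `r_squared` (NA with a warning if either axis has zero
#'   variance) and `n` shared points
#' @export
concordance <- function(qpcr_values, rnaseq_fpkm, pseudocount = 1) {
  if (inherits(rnaseq_fpkm, "expression_set")) {
    rnaseq_fpkm <- data.frame(
      gene = rep(rownames(rnaseq_fpkm$fpkm), ncol(rnaseq_fpkm$fpkm)),
      sample = rep(colnames(rnaseq_fpkm$fpkm), each = nrow(rnaseq_fpkm$fpkm)),
      fpkm = as.vector(rnaseq_fpkm$fpkm), stringsAsFactors = FALSE)
  }
  shared <- merge(qpcr_values[, c("gene", "sample", "rel_expr")],
                  rnaseq_fpkm[, c("gene", "sample", "fpkm")],
                  by = c("gene", "sample"))
  if (nrow(shared) < 3L) {
    stopf("concordance needs >= 3 shared (gene, sample) points; got %d", nrow(shared))
  }
  x <- log2(shared$rel_expr)
  y <- log2(shared$fpkm + pseudocount)
  if (sd(x) == 0 || sd(y) == 0) {
    warnf("zero variance on one axis: concordance undefined")
    return(list(r_squared = NA_real_, n = nrow(shared)))
  }
  list(r_squared = cor(x, y)^2, n = nrow(shared))
}
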