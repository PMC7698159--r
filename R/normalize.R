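#' Counts per million
#'
#' Scales every sample column to counts per million assigned reads:
#' `cpm(g, s) = count(g, s) / colsum(s) * 1e6`. The denominator is the
#' column sum of the delivered count matrix (reads assigned to genes); the
#' original mapping totals are not available downstream and are not used.
#'
#' @param matrix a [count_matrix()].
#' @return an [expression_matrix()] with unit `"CPM"`.
#' @export
cpm <- function(matrix) {
  cs <- colSums(matrix)
  zero <- colnames(matrix)[cs == 0]
  if (length(zero))
    bud_stop(sprintf("sample(s) with zero total counts: %s",
                     paste(zero, collapse = ", ")), "bud_degenerate_sample_error")
  expression_matrix(sweep(unclass(matrix) * 1e6, 2L, cs, "/"), unit = "CPM")
}

#' Reads per kilobase per million
#'
#' `rpkm(g, s) = count(g, s) / (length_bp(g)/1000) / (colsum(s)/1e6)`,
#' i.e. CPM further divided by the gene length in kilobases. Lengths come
#' from the annotation's `length_bp` column (exon-union lengths when
#' derived from GFF3 via [gene_lengths_from_gff3()]).
#'
#' @param matrix a [count_matrix()].
#' @param annotation a [gene_annotation()] covering every gene in `matrix`.
#' @return an [expression_matrix()] with unit `"RPKM"`.
#' @export
rpkm <- function(matrix, annotation) {
  lens <- stats::setNames(annotation$length_bp, annotation$gene_id)
  miss <- setdiff(rownames(matrix), names(lens))
  if (length(miss))
    bud_stop(sprintf("gene(s) missing from annotation: %s",
                     paste(utils::head(miss, 10), collapse = ", ")),
             "bud_lookup_error")
  v <- cpm(matrix)
  expression_matrix(unclass(v) / (lens[rownames(matrix)] / 1000),
                    unit = "RPKM")
}

#' Select genes by total expression across samples
#'
#' Returns the genes whose per-gene sum of expression values over all
#' samples is greater than or equal to `threshold`. This is the
#' detectability filter applied before the gene-set/temperature correlation
#' (CPM-sum >= 10) and the reference-gene candidate filter (CPM-sum >= 500).
#'
#' @param expr an [expression_matrix()].
#' @param threshold non-negative cutoff on the per-gene sum.
#' @return a [gene_set()] of passing genes (possibly empty).
#' @export
filter_by_expression_sum <- function(expr, threshold) {
  stopifnot(threshold >= 0)
  keep <- rowSums(expr) >= threshold
  gene_set(rownames(expr)[keep],
           name = sprintf("expression_sum_ge_%g", threshold))
}
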