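# qRT-PCR reference-gene candidate prediction: high total expression,
# low variation relative to the typical level.

#' Expression stability score (SD over median)
#'
#' `sd(values) / median(values)` with the sample (n-1) standard deviation.
#' Lower is more stable; a constant gene scores 0. The score is invariant
#' to rescaling all values by a positive constant, so it compares genes of
#' different expression levels fairly.
#'
#' @param values per-sample expression vector, length >= 2, median > 0.
#' @return non-negative scalar.
#' @export
stability_score <- function(values) {
  if (length(values) < 2L)
    bud_stop("stability score needs >= 2 observations", "bud_undefined_score_error")
  med <- stats::median(values)
  if (med <= 0)
    bud_stop("stability score undefined for median <= 0 (filter the gene upstream)",
             "bud_undefined_score_error")
  stats::sd(values) / med
}

#' Rank qRT-PCR reference-gene candidates
#'
#' Selects genes with substantial total expression (per-gene CPM sum over
#' all samples `>= min_total_cpm`), scores each survivor with
#' [stability_score()] across all samples (replicates as separate
#' observations), sorts ascending by score with ties broken by gene id, and
#' keeps the `top_n` best.
#'
#' @param expr an [expression_matrix()] in CPM.
#' @param min_total_cpm total-CPM filter (default 500).
#' @param top_n ranking length (default 20); shorter if fewer genes pass.
#' @return object of class `stability_ranking`: data frame with columns
#'   `rank`, `gene_id`, `total_cpm`, `stability`.
#' @export
rank_reference_candidates <- function(expr, min_total_cpm = 500, top_n = 20L) {
  stopifnot(min_total_cpm >= 0, top_n >= 1L)
  if (!identical(attr(expr, "unit"), "CPM"))
    warning("reference-gene thresholds are defined on CPM; got unit ",
            attr(expr, "unit"))
  passing <- filter_by_expression_sum(expr, min_total_cpm)
  if (length(passing) == 0L)
    bud_stop(sprintf("no gene reaches a total CPM of %g", min_total_cpm),
             "bud_empty_ranking_error")
  sub <- unclass(expr)[passing, , drop = FALSE]
  score <- apply(sub, 1L, stability_score)
  total <- rowSums(sub)
  ord <- order(score, passing)      # ties broken lexicographically by gene id
  keep <- ord[seq_len(min(top_n, length(ord)))]
  out <- data.frame(rank = seq_along(keep),
                    gene_id = passing[keep],
                    total_cpm = as.numeric(total[keep]),
                    stability = as.numeric(score[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "min_total_cpm") <- min_total_cpm
  class(out) <- c("stability_ranking", "data.frame")
  out
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat(sprintf("<stability_ranking> top %d candidates (total CPM >= %g)\n",
              nrow(x), attr(x, "min_total_cpm")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
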