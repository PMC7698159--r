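# Gene-set vs environmental-covariate correlation with a matched
# random-set empirical null.

#' Select genes whose annotation text contains every keyword
#'
#' Plain case-insensitive substring matching: a gene is selected when its
#' functional description contains EVERY keyword as a substring. No word
#' boundaries are enforced, so "heat" also matches "heatmap"; heat-shock
#' protein sets are defined by requiring "heat" and "shock" together.
#'
#' @param annotation a [gene_annotation()].
#' @param keywords non-empty character vector of substrings.
#' @param name optional set name; defaults to the joined keywords.
#' @return a [gene_set()]; empty sets are returned with a warning.
#' @export
select_genes_by_keywords <- function(annotation, keywords,
                                     name = paste(keywords, collapse = "+")) {
  stopifnot(length(keywords) >= 1L)
  desc <- tolower(annotation$description)
  hit <- rep(TRUE, length(desc))
  for (kw in tolower(keywords))
    hit <- hit & grepl(kw, desc, fixed = TRUE)
  if (!any(hit))
    warning(sprintf("no gene description contains all of: %s",
                    paste(keywords, collapse = ", ")))
  gene_set(annotation$gene_id[hit], name = name)
}

#' Aggregate a gene set to one value per sample
#'
#' @param expr an [expression_matrix()].
#' @param genes a non-empty [gene_set()] fully contained in `expr`.
#' @param method `"median"` (even-sized sets: mean of the two central
#'   values) or `"mean"`.
#' @return named numeric vector, one aggregate per sample.
#' @export
aggregate_gene_set <- function(expr, genes, method = c("median", "mean")) {
  method <- match.arg(method)
  if (length(genes) == 0L)
    bud_stop("cannot aggregate an empty gene set", "bud_lookup_error")
  miss <- setdiff(genes, rownames(expr))
  if (length(miss))
    bud_stop(sprintf("gene(s) absent from matrix: %s",
                     paste(utils::head(miss, 10), collapse = ", ")),
             "bud_lookup_error")
  sub <- unclass(expr)[genes, , drop = FALSE]
  if (method == "median") apply(sub, 2L, stats::median) else colMeans(sub)
}

# Midranks (average ranks for ties); kept separate so the correlation code
# below stays an explicit rank-then-Pearson computation.
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with analytic p-value
#'
#' Computes the Pearson correlation of midrank-transformed values (ties
#' receive average ranks) and a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#' For small n the t approximation is coarse relative to the exact
#' permutation distribution; see the package vignette for the measured
#' accuracy band.
#'
#' @param x,y numeric vectors of equal length >= 3, each with >= 2 distinct
#'   values.
#' @return list with elements `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L)
    bud_stop("need at least 3 paired observations", "bud_undefined_correlation_error")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    bud_stop("correlation undefined for a constant vector",
             "bud_undefined_correlation_error")
  rx <- midrank(x); ry <- midrank(y)
  rx <- rx - mean(rx); ry <- ry - mean(ry)
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- .Machine$double.xmin       # degenerate perfect monotone case
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p <- min(1, max(p, .Machine$double.xmin))
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate aggregated gene-set expression with a dated covariate
#'
#' Aggregates the set per sample, pairs each observation with the covariate
#' value of its sampling date, and computes the Spearman rank correlation.
#' With `pairing = "per_sample"` every replicate is one observation; with
#' `pairing = "per_timepoint"` the replicate mean of the aggregate is one
#' observation per time point.
#'
#' @param expr an [expression_matrix()].
#' @param genes a [gene_set()] present in `expr`.
#' @param env an [env_series()] covering every sampling date in `sheet`.
#' @param sheet a [sample_sheet()] for the samples of `expr`.
#' @param method aggregation, `"median"` or `"mean"`.
#' @param pairing `"per_sample"` or `"per_timepoint"`.
#' @return object of class `gene_set_correlation`: list with `set_name`,
#'   `aggregation`, `pairing`, `n_obs`, `rho`, `p_analytic` and
#'   `observations` (data frame of unit, date, aggregate, covariate).
#' @export
environment_correlation <- function(expr, genes, env, sheet,
                                    method = c("median", "mean"),
                                    pairing = c("per_sample", "per_timepoint")) {
  method <- match.arg(method)
  pairing <- match.arg(pairing)
  miss_d <- setdiff(format(unique(sheet$date)), format(env$date))
  if (length(miss_d))
    bud_stop(sprintf("sampling date(s) missing from covariate series: %s",
                     paste(miss_d, collapse = ", ")), "bud_covariate_coverage_error")
  agg <- aggregate_gene_set(keep_samples(expr, sheet$sample_id), genes, method)
  temp_of <- stats::setNames(env$value, format(env$date))
  if (pairing == "per_sample") {
    obs <- data.frame(unit = sheet$sample_id,
                      date = sheet$date,
                      aggregate = as.numeric(agg[sheet$sample_id]),
                      covariate = as.numeric(temp_of[format(sheet$date)]),
                      stringsAsFactors = FALSE)
  } else {
    tps <- split(seq_len(nrow(sheet)), sheet$timepoint)
    recs <- lapply(names(tps), function(tp) {
      i <- tps[[tp]]
      data.frame(unit = tp, date = sheet$date[i[1]],
                 aggregate = mean(agg[sheet$sample_id[i]]),
                 covariate = as.numeric(temp_of[format(sheet$date[i[1]])]),
                 stringsAsFactors = FALSE)
    })
    obs <- do.call(rbind, recs)
    obs <- obs[order(obs$date), , drop = FALSE]
    rownames(obs) <- NULL
  }
  sc <- spearman_cor(obs$aggregate, obs$covariate)
  structure(list(set_name = attr(genes, "name"),
                 aggregation = method,
                 pairing = pairing,
                 n_obs = sc$n,
                 rho = sc$rho,
                 p_analytic = sc$p,
                 observations = obs),
            class = "gene_set_correlation")
}

#' @export
print.gene_set_correlation <- function(x, ...) {
  cat(sprintf("<gene_set_correlation> %s (%s, %s)\n  rho = %.4f, p = %.3g, n = %d\n",
              x$set_name, x$aggregation, x$pairing, x$rho, x$p_analytic, x$n_obs))
  invisible(x)
}

#' Random gene-set null distribution for a set/covariate correlation
#'
#' Draws `n_draws` random gene sets of the focal set's size, uniformly
#' without replacement from the genes passing the same expression cutoff as
#' the focal set, recomputes the correlation for each, and summarises the
#' observed statistic against the resulting null. The empirical p uses the
#' add-one estimator `(1 + #{|draw| >= |rho_obs|}) / (1 + n_draws)` so it is
#' never exactly zero.
#'
#' @param expr,env,sheet,method,pairing as in [environment_correlation()].
#' @param eligible [gene_set()] of genes eligible for random draws (those
#'   passing the focal set's expression cutoff).
#' @param set_size number of genes per draw (the focal set's size).
#' @param rho_obs observed correlation to calibrate (from
#'   [environment_correlation()]).
#' @param n_draws number of random sets (>= 1).
#' @param seed integer seed; recorded in the result.
#' @return object of class `null_distribution`: list with `set_size`,
#'   `n_draws`, `seed`, `draws` (numeric vector of rho), `empirical_p`, `z`.
#' @export
random_set_null <- function(expr, eligible, set_size, env, sheet,
                            method = c("median", "mean"),
                            pairing = c("per_sample", "per_timepoint"),
                            n_draws = 200L, seed = 1L, rho_obs) {
  method <- match.arg(method)
  pairing <- match.arg(pairing)
  stopifnot(n_draws >= 1L, set_size >= 2L)
  if (set_size > length(eligible))
    bud_stop(sprintf("set_size %d exceeds eligible pool of %d genes",
                     set_size, length(eligible)), "bud_sampling_error")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    g <- gene_set(sample(eligible, set_size), name = sprintf("random_%d", i))
    environment_correlation(expr, g, env, sheet, method, pairing)$rho
  }, numeric(1))
  structure(list(set_size = set_size,
                 n_draws = n_draws,
                 seed = seed,
                 draws = draws,
                 rho_obs = rho_obs,
                 empirical_p = (1 + sum(abs(draws) >= abs(rho_obs))) / (1 + n_draws),
                 z = (rho_obs - mean(draws)) / stats::sd(draws)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d draws of %d genes (seed %d)\n  rho_obs = %.4f, empirical p = %.4g, z = %.2f\n",
    x$n_draws, x$set_size, x$seed, x$rho_obs, x$empirical_p, x$z))
  invisible(x)
}
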