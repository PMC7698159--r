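# Small in-code fixtures and independent oracles shared across test files.

tiny_counts <- function() {
  count_matrix(matrix(c(10L, 5L, 0L, 0L, 5L, 100L), nrow = 3,
                      dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
}

tiny_sheet <- function(timepoints = 2, reps = 3,
                       dates = as.Date("2016-06-01") + (seq_len(timepoints) - 1) * 14) {
  sample_sheet(data.frame(
    sample_id = paste0("T", rep(seq_len(timepoints), each = reps), "_R",
                       rep(seq_len(reps), timepoints)),
    timepoint = paste0("T", rep(seq_len(timepoints), each = reps)),
    date = rep(dates, each = reps),
    replicate = rep(seq_len(reps), timepoints)))
}

tiny_env <- function(dates, values = seq(18, by = 1, length.out = length(dates))) {
  env_series(data.frame(date = dates, value = values))
}

# random count matrix paired with a complete sheet/env
random_design <- function(n_genes = 20, timepoints = 4, reps = 3, seed = 1) {
  withr::local_seed(seed, .local_envir = parent.frame())
  sheet <- tiny_sheet(timepoints, reps)
  m <- matrix(rpois(n_genes * nrow(sheet), lambda = 50), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), sheet$sample_id))
  list(counts = count_matrix(m), sheet = sheet,
       env = tiny_env(unique(sheet$date)))
}

# numeric matrix stripped to dim/dimnames, for unit-tag-insensitive comparison
bare <- function(m) matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))

# --- independent Spearman oracles ------------------------------------------

# rank-then-Pearson via stats::cor, a different code path than the package's
# explicit cross-product computation
oracle_spearman_rho <- function(x, y)
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))

all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# exact two-sided permutation p for |rho| by full enumeration of rank orders
oracle_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  rhos <- apply(all_perms(length(x)), 1, function(pm) stats::cor(rx, ry[pm]))
  mean(abs(rhos) >= obs - 1e-12)
}
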