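test_that("keyword selection is conjunctive, case-insensitive substring matching", {
  ann <- gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g3"),
    length_bp = 1000L,
    description = c("heat shock protein 90", "heatmap factor", "shock only")))
  hsp <- select_genes_by_keywords(ann, c("heat", "shock"))
  expect_identical(as.character(hsp), "g1")

  # case-insensitive, and no word boundaries ("heat" inside "heat-inducible")
  ann2 <- gene_annotation(data.frame(gene_id = "g", length_bp = 1L,
                                     description = "heat-inducible"))
  expect_length(select_genes_by_keywords(ann2, "HEAT"), 1)

  expect_warning(empty <- select_genes_by_keywords(ann2, c("heat", "shock")),
                 "no gene")
  expect_length(empty, 0)
})

test_that("gene-set aggregation follows the median/mean conventions", {
  v <- expression_matrix(matrix(c(1, 2, 9, 4), 4,
                                dimnames = list(paste0("g", 1:4), "s1")),
                         unit = "CPM")
  g3 <- gene_set(c("g1", "g2", "g3"))
  expect_equal(unname(aggregate_gene_set(v, g3, "median")), 2)
  g4 <- gene_set(paste0("g", 1:4))  # values 1, 2, 9, 4
  expect_equal(unname(aggregate_gene_set(v, g4, "median")), 3)  # mean of 2 and 4
  expect_equal(unname(aggregate_gene_set(v, g4, "mean")), 4)
  expect_error(aggregate_gene_set(v, gene_set("nope")), class = "bud_lookup_error")
})

test_that("spearman_cor handles monotone extremes and rejects degenerate input", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  expect_error(spearman_cor(1:3, c(5, 5, 5)),
               class = "bud_undefined_correlation_error")
  expect_error(spearman_cor(1:2, 2:1), class = "bud_undefined_correlation_error")

  sc <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(sc$rho, oracle_spearman_rho(1:5, c(2, 1, 4, 3, 5)), tolerance = 1e-12)
})

test_that("spearman_cor matches the rank-then-Pearson oracle with and without ties", {
  withr::local_seed(202)
  for (i in 1:250) {
    n <- sample(4:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 2 == 0) {  # inject ties
      x <- round(x, 1)
      y <- round(y, 1)
    }
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    sc <- spearman_cor(x, y)
    expect_equal(sc$rho, oracle_spearman_rho(x, y), tolerance = 1e-10)
    if (!anyDuplicated(x) && !anyDuplicated(y) && abs(sc$rho) < 1) {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      expect_equal(sc$p, unname(ct$p.value), tolerance = 1e-9)
    }
  }
})

test_that("spearman_cor is invariant under strictly increasing transforms", {
  withr::local_seed(7)
  for (i in 1:20) {
    x <- runif(15, 1, 10); y <- runif(15, 1, 10)
    base <- spearman_cor(x, y)$rho
    expect_equal(spearman_cor(log(x), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_cor(x, 3 * y + 2)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_cor(exp(x), y^3)$rho, base, tolerance = 1e-12)
  }
})

test_that("analytic p stays within the measured band of exact permutation p", {
  # Band measured during development at 0.15 (worst cases are near-perfect
  # correlations at tiny n, where the t approximation is coarsest).
  withr::local_seed(31)
  for (i in 1:40) {
    n <- sample(4:7, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    sc <- spearman_cor(x, y)
    expect_lt(abs(sc$p - oracle_exact_p(x, y)), 0.16)
  }
})

test_that("environment_correlation pairs observations by date under both pairings", {
  sheet <- tiny_sheet(4)
  env <- tiny_env(unique(sheet$date), c(18, 21, 15, 9))
  temp_of <- setNames(env$value, format(env$date))
  # two genes whose expression equals the day's temperature in every replicate
  row <- rep(unname(temp_of[format(unique(sheet$date))]), each = 3)
  v <- expression_matrix(matrix(rep(row, 2), nrow = 2, byrow = TRUE,
                                dimnames = list(c("g1", "g2"), sheet$sample_id)),
                         unit = "CPM")
  g <- gene_set(c("g1", "g2"), "both")
  for (pairing in c("per_sample", "per_timepoint")) {
    res <- environment_correlation(v, g, env, sheet, pairing = pairing)
    expect_equal(res$rho, 1)
    expect_identical(res$n_obs, nrow(res$observations))
    expect_identical(res$n_obs, if (pairing == "per_sample") 12L else 4L)
    expect_equal(res$observations$aggregate, res$observations$covariate)
  }

  # constant aggregate -> undefined correlation
  vc <- expression_matrix(matrix(5, 2, 12, dimnames = dimnames(v)), unit = "CPM")
  expect_error(environment_correlation(vc, g, env, sheet),
               class = "bud_undefined_correlation_error")

  # covariate must cover every sampling date
  expect_error(environment_correlation(v, g, env[-2, ], sheet),
               class = "bud_covariate_coverage_error")
})

test_that("random_set_null formula bounds and degenerate resampling", {
  d <- random_design(n_genes = 30, timepoints = 5, seed = 13)
  v <- cpm(d$counts)
  eligible <- filter_by_expression_sum(v, 0)
  expect_error(random_set_null(v, eligible, 50, d$env, d$sheet, rho_obs = 0),
               class = "bud_sampling_error")
  expect_error(random_set_null(v, eligible, 5, d$env, d$sheet,
                               n_draws = 0, rho_obs = 0))

  # n_draws = 1: empirical p is (1 + {0 or 1}) / 2
  n1 <- random_set_null(v, eligible, 5, d$env, d$sheet, n_draws = 1,
                        seed = 4, rho_obs = 0.2)
  expect_true(n1$empirical_p %in% c(0.5, 1))

  # eligible == focal: every draw reproduces the observed rho, p = 1
  focal <- gene_set(as.character(eligible)[1:6], "focal")
  obs <- environment_correlation(v, focal, d$env, d$sheet)
  nn <- random_set_null(v, focal, 6, d$env, d$sheet, n_draws = 20,
                        seed = 5, rho_obs = obs$rho)
  expect_true(all(abs(nn$draws - obs$rho) < 1e-12))
  expect_equal(nn$empirical_p, 1)

  # reproducible under a fixed seed
  nn2 <- random_set_null(v, focal, 6, d$env, d$sheet, n_draws = 20,
                         seed = 5, rho_obs = obs$rho)
  expect_identical(nn$draws, nn2$draws)
})
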