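test_that("replicate summary reports per-time-point mean/min/max in date order", {
  sheet <- tiny_sheet(2)
  v <- expression_matrix(matrix(c(2, 4, 9, 7, 7, 7), 1,
                                dimnames = list("g1", sheet$sample_id)),
                         unit = "CPM")
  ts <- replicate_summary(v, sheet, "g1")
  expect_identical(nrow(ts), 2L)
  expect_equal(ts$mean, c(5, 7))
  expect_equal(ts$min, c(2, 7))
  expect_equal(ts$max, c(9, 7))   # identical replicates give a degenerate bar
  expect_true(!is.unsorted(ts$date))
  expect_error(replicate_summary(v, sheet, "nope"), class = "bud_lookup_error")
})

test_that("replicate summary is internally consistent on random matrices", {
  d <- random_design(n_genes = 5, timepoints = 6, seed = 17)
  v <- cpm(d$counts)
  for (g in rownames(v)) {
    ts <- replicate_summary(v, d$sheet, g)
    expect_true(all(ts$min <= ts$mean & ts$mean <= ts$max))
    for (i in seq_len(nrow(ts))) {
      reps <- v[g, d$sheet$sample_id[d$sheet$timepoint == ts$timepoint[i]]]
      expect_equal(ts$mean[i], mean(reps))
      expect_equal(range(reps), c(ts$min[i], ts$max[i]))
    }
  }
})

test_that("switch-up genes rise across the planted switch date", {
  sim <- simulate_counts(seed = 4)
  v <- cpm(sim$counts)
  cfg <- sim_config()
  up <- sim$truth$gene_id[sim$truth$class == "switch" & sim$truth$switch_direction == 1]
  for (g in up[1:5]) {
    ts <- replicate_summary(v, sim$sheet, g)
    expect_lt(mean(ts$mean[ts$date < cfg$switch_date - 7]),
              mean(ts$mean[ts$date > cfg$switch_date + 7]))
  }
})

test_that("family heatmap filters, orders and scales as declared", {
  d <- random_design(n_genes = 10, timepoints = 4, seed = 23)
  v <- cpm(d$counts)
  fam <- data.frame(name = c("GeneB", "GeneA"),
                    gene_id = c("g002", "g001"))
  hm <- family_heatmap(v, fam, v, d$sheet, threshold = 0, scaling = "none")
  expect_identical(rownames(hm), c("GeneB", "GeneA"))  # input family order
  expect_identical(colnames(hm), format(sort(unique(d$sheet$date))))
  # threshold 0 + no scaling = pure selection with replicate-mean columns
  tp1 <- d$sheet$sample_id[d$sheet$timepoint == "T1"]
  expect_equal(hm["GeneA", 1], mean(v["g001", tp1]))

  # member below the detectability threshold is dropped
  filt <- expression_matrix(matrix(c(rep(0, 12), rep(100, 12)), 2, byrow = TRUE,
                                   dimnames = list(c("g002", "g001"),
                                                   d$sheet$sample_id)),
                            unit = "CPM")
  hm2 <- family_heatmap(v, fam, filt, d$sheet, threshold = 10)
  expect_identical(rownames(hm2), "GeneA")
  expect_identical(attr(hm2, "dropped"), "GeneB")
  expect_error(family_heatmap(v, fam, filt, d$sheet, threshold = 1e9),
               class = "bud_empty_heatmap_error")

  # row_max scaling
  vm <- expression_matrix(matrix(c(0, 5, 10), 1,
                                 dimnames = list("g001", tiny_sheet(3, 1)$sample_id)),
                          unit = "RPKM")
  sh1 <- tiny_sheet(3, 1)
  hm3 <- family_heatmap(vm, data.frame(name = "A", gene_id = "g001"),
                        vm, sh1, threshold = 0, scaling = "row_max")
  expect_equal(unname(hm3[1, ]), c(0, 0.5, 1))
})

test_that("day length matches the almanac oracle and behaves at equinox/equator", {
  # frozen values from an independent NOAA Julian-day solar computation
  expect_lt(abs(day_length("2016-06-21", 49.218) - 16.2378), 10 / 60)
  expect_lt(abs(day_length("2016-12-21", 49.218) - 8.1907), 10 / 60)
  expect_gt(day_length("2016-06-21", 49.218), 12)
  expect_lt(day_length("2016-12-21", 49.218), 12)

  for (lat in c(-60, -30, 0, 30, 60))
    expect_lt(abs(day_length("2016-03-20", lat) - 12), 0.25)
  for (d in c("2016-01-15", "2016-06-21", "2016-10-01"))
    expect_lt(abs(day_length(d, 0) - 12), 0.25)

  expect_error(day_length("2016-06-21", 70), class = "bud_unsupported_latitude_error")
})

test_that("day length increases monotonically from winter to summer solstice", {
  dl <- day_length(seq(as.Date("2015-12-22"), as.Date("2016-06-20"), by = "day"),
                   49.218)
  expect_true(all(diff(dl) > 0))
  s <- day_length_series("2016-06-01", "2016-11-03")
  expect_true(all(s$day_length >= 0 & s$day_length <= 24))
  expect_identical(nrow(s), 156L)
})
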