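# Synthetic-data generator: a dated, replicated count matrix with planted
# gene classes and a matching daily temperature series, emulating an
# 18-time-point x 3-replicate field season (June through early November).

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults emulate the field design being modelled: 18 sampling dates with
#' 3 replicates each between 2016-06-01 and 2016-11-03, about one thousand
#' genes split into planted classes, and library sizes around one million
#' reads. `coupling_beta` is the change in a temperature-coupled gene's
#' natural-log mean per degree Celsius.
#'
#' @param n_timepoints number of sampling dates (default 18).
#' @param replicates biological replicates per date (default 3).
#' @param date_from,date_to sampling window (defaults 2016-06-01..2016-11-03).
#' @param n_coupled,n_housekeeping,n_switch,n_peak,n_background,n_low class
#'   sizes (defaults 60, 20, 40, 20, 800, 60).
#' @param coupling_beta log-scale expression change per degree C (default 0.08).
#' @param switch_date date of the planted expression-program switch
#'   (default 2016-07-15).
#' @param switch_delta log-scale magnitude of the switch (default 1.5).
#' @param switch_tau logistic time constant of the switch in days (default 5).
#' @param peak_amp,peak_sd_days transient-peak bump height (log scale,
#'   default 2) and width (days, default 10).
#' @param dispersion named per-class negative-binomial dispersions
#'   (1/size); housekeeping genes are nearly Poisson, background genes are
#'   strongly overdispersed.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library-size model
#'   (defaults log(1e6) and 0.15).
#' @param temp_mean,temp_amplitude,temp_peak_doy,temp_ar1,temp_noise_sd
#'   seasonal temperature model: level (12 C), half-range (9 C), day of
#'   year of the warmest day (196, mid-July), lag-1 autocorrelation (0.7)
#'   and innovation SD (2.5 C) of the AR(1) weather noise.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 18L, replicates = 3L,
                       date_from = "2016-06-01", date_to = "2016-11-03",
                       n_coupled = 60L, n_housekeeping = 20L, n_switch = 40L,
                       n_peak = 20L, n_background = 800L, n_low = 60L,
                       coupling_beta = 0.08,
                       switch_date = "2016-07-15", switch_delta = 1.5,
                       switch_tau = 5,
                       peak_amp = 2, peak_sd_days = 10,
                       dispersion = c(coupled = 0.05, housekeeping = 0.005,
                                      switch = 0.05, peak = 0.05,
                                      background = 0.2, low = 0.3),
                       lib_size_meanlog = log(1e6), lib_size_sdlog = 0.15,
                       temp_mean = 12, temp_amplitude = 9,
                       temp_peak_doy = 196, temp_ar1 = 0.7,
                       temp_noise_sd = 2.5) {
  cfg <- as.list(environment())
  cfg$date_from <- parse_iso_date(date_from)
  cfg$date_to <- parse_iso_date(date_to)
  cfg$switch_date <- parse_iso_date(switch_date)
  if (cfg$date_to <= cfg$date_from)
    bud_stop("empty simulation date range", "bud_config_error")
  total <- with(cfg, n_coupled + n_housekeeping + n_switch + n_peak +
                  n_background + n_low)
  if (total < 2L || cfg$replicates < 1L || cfg$n_timepoints < 2L)
    bud_stop("invalid simulation design", "bud_config_error")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a daily mean-temperature series
#'
#' Seasonal sinusoid (warmest around mid-July) plus first-order
#' autoregressive weather noise, one value per day over the configured
#' range. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return an [env_series()].
#' @export
simulate_temperature <- function(config = sim_config(), seed = 1L) {
  dates <- seq(config$date_from, config$date_to, by = "day")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$temp_mean +
    config$temp_amplitude * cos(2 * pi * (doy - config$temp_peak_doy) / 365.25)
  noise <- with_seed(derive_seed(seed, 1L), {
    e <- stats::rnorm(length(dates), sd = config$temp_noise_sd)
    n <- numeric(length(dates))
    n[1] <- e[1] / sqrt(1 - config$temp_ar1^2)   # stationary start
    for (i in seq_along(dates)[-1])
      n[i] <- config$temp_ar1 * n[i - 1] + e[i]
    n
  })
  env_series(data.frame(date = dates, value = round(seasonal + noise, 2)))
}

class_descriptions <- list(
  coupled = function(i) sprintf("heat shock protein %d, chaperone", i),
  housekeeping = function(i) {
    pool <- c("polyubiquitin", "glyceraldehyde-3-phosphate dehydrogenase",
              "elongation factor 1-alpha", "actin", "ubiquitin-conjugating enzyme",
              "60S ribosomal protein", "tubulin alpha chain",
              "eukaryotic translation initiation factor")
    sprintf("%s %d", pool[(i - 1) %% length(pool) + 1], i)
  },
  switch = function(i) {
    pool <- c("MADS-box transcription factor", "WRKY transcription factor",
              "R2R3-MYB transcription factor")
    sprintf("%s %d", pool[(i - 1) %% length(pool) + 1], i)
  },
  peak = function(i) sprintf("transiently induced protein %d", i),
  background = function(i) sprintf("uncharacterized protein %d", i),
  low = function(i) sprintf("hypothetical protein %d, low abundance", i)
)

# Per-class baseline draw: natural-log expected count at a library of 1e6
# (i.e. log CPM). Levels chosen as typical for moderately to highly
# expressed genes in bulk RNA-seq.
class_baseline <- function(class, n) {
  switch(class,
    coupled      = stats::rnorm(n, log(150), 0.5),
    housekeeping = stats::rnorm(n, log(2000), 0.3),
    switch       = stats::rnorm(n, log(100), 0.5),
    peak         = stats::rnorm(n, log(80), 0.5),
    background   = stats::rnorm(n, log(30), 1.2),
    low          = stats::rnorm(n, log(0.05), 0.5))
}

#' Simulate a replicated, dated RNA-seq count matrix with planted truth
#'
#' Generates (deterministically for a fixed seed) a negative-binomial count
#' matrix over `n_timepoints * replicates` samples with six planted gene
#' classes: temperature-coupled genes whose log mean tracks the simulated
#' daily temperature (descriptions contain the phrase "heat shock protein"
#' so keyword selection doubles as truth recovery), stable high-expression
#' housekeeping genes, genes switching up or down sigmoidally at the
#' configured switch date, transient-peak genes, background genes, and
#' near-silent low-expression genes. Library sizes are log-normal; gene
#' lengths are uniform on 500..5000 bp.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; temperature, gene parameters and counts use
#'   sub-streams derived from it, so e.g. adding genes does not perturb the
#'   temperature series.
#' @return list with elements `counts` ([count_matrix()]), `sheet`
#'   ([sample_sheet()]), `annotation` ([gene_annotation()]), `env`
#'   ([env_series()]) and `truth` (data frame: `gene_id`, `class`,
#'   `baseline_log_mean`, `coupling`, `switch_direction`, `peak_date`,
#'   plus attribute `lib_sizes`).
#' @export
simulate_counts <- function(config = sim_config(), seed = 1L) {
  env <- simulate_temperature(config, seed)
  tbar <- mean(env$value)
  tp_dates <- unique(round(seq(as.numeric(config$date_from),
                               as.numeric(config$date_to),
                               length.out = config$n_timepoints)))
  tp_dates <- as.Date(tp_dates, origin = "1970-01-01")
  tp_lab <- sprintf("T%02d", seq_along(tp_dates))
  sheet <- sample_sheet(data.frame(
    sample_id = paste0(rep(tp_lab, each = config$replicates), "_R",
                       rep(seq_len(config$replicates), length(tp_dates))),
    timepoint = rep(tp_lab, each = config$replicates),
    date = rep(tp_dates, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(tp_dates))))

  classes <- rep(c("coupled", "housekeeping", "switch", "peak", "background", "low"),
                 c(config$n_coupled, config$n_housekeeping, config$n_switch,
                   config$n_peak, config$n_background, config$n_low))
  n_genes <- length(classes)
  gene_ids <- sprintf("SYNG%04d", seq_len(n_genes))

  truth <- with_seed(derive_seed(seed, 2L), {
    baseline <- unlist(lapply(split(seq_len(n_genes), factor(classes, unique(classes))),
                              function(i) class_baseline(classes[i[1]], length(i))),
                       use.names = FALSE)
    sw_dir <- ifelse(classes == "switch",
                     sample(c(1, -1), n_genes, replace = TRUE), 0)
    peak_date <- as.Date(ifelse(
      classes == "peak",
      round(stats::runif(n_genes, as.numeric(config$date_from) + config$peak_sd_days,
                         as.numeric(config$date_to) - config$peak_sd_days)),
      NA), origin = "1970-01-01")
    lengths <- as.integer(round(stats::runif(n_genes, 500, 5000)))
    data.frame(gene_id = gene_ids, class = classes,
               baseline_log_mean = baseline,
               coupling = ifelse(classes == "coupled", config$coupling_beta, 0),
               switch_direction = sw_dir,
               peak_date = peak_date,
               length_bp = lengths,
               stringsAsFactors = FALSE)
  })

  temp_of <- stats::setNames(env$value, format(env$date))
  t_sample <- as.numeric(temp_of[format(sheet$date)])
  d_num <- as.numeric(sheet$date)
  n_samples <- nrow(sheet)

  # per-gene x per-sample log mean at a nominal library of 1e6
  log_mu <- matrix(truth$baseline_log_mean, n_genes, n_samples)
  cc <- truth$class == "coupled"
  log_mu[cc, ] <- log_mu[cc, ] +
    truth$coupling[cc] %o% (t_sample - tbar)
  sw <- truth$class == "switch"
  step <- 1 / (1 + exp(-(d_num - as.numeric(config$switch_date)) / config$switch_tau))
  log_mu[sw, ] <- log_mu[sw, ] +
    config$switch_delta * (truth$switch_direction[sw] %o% step)
  pk <- truth$class == "peak"
  if (any(pk)) {
    bump <- exp(-outer(as.numeric(truth$peak_date[pk]), d_num, "-")^2 /
                  (2 * config$peak_sd_days^2))
    log_mu[pk, ] <- log_mu[pk, ] + config$peak_amp * bump
  }

  counts_truth <- with_seed(derive_seed(seed, 3L), {
    libs <- stats::rlnorm(n_samples, config$lib_size_meanlog, config$lib_size_sdlog)
    mu <- exp(log_mu) * rep(libs / 1e6, each = n_genes)
    size <- 1 / config$dispersion[truth$class]
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = rep(size, n_samples)),
                  n_genes, n_samples,
                  dimnames = list(gene_ids, sheet$sample_id))
    list(counts = cnt, libs = libs)
  })

  desc <- vapply(seq_len(n_genes), function(i)
    class_descriptions[[classes[i]]](i), character(1))
  ann <- gene_annotation(data.frame(gene_id = gene_ids,
                                    length_bp = truth$length_bp,
                                    description = desc,
                                    stringsAsFactors = FALSE))
  attr(truth, "lib_sizes") <- stats::setNames(counts_truth$libs, sheet$sample_id)
  list(counts = count_matrix(counts_truth$counts),
       sheet = sheet,
       annotation = ann,
       env = env,
       truth = truth)
}
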