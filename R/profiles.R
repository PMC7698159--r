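# Marker-gene time-course summaries, TF-family heatmap matrices, and the
# photoperiod (day length) model for the sampling location.

#' Replicate summary of one gene's time course
#'
#' For each retained time point, the arithmetic mean, minimum and maximum of
#' the gene's expression across replicates — the numbers behind a profile
#' plot whose dots are replicate means and whose bars span the lowest and
#' highest replicate.
#'
#' @param expr an [expression_matrix()].
#' @param sheet a [sample_sheet()], already filtered to complete time points.
#' @param gene_id gene present in `expr`.
#' @return object of class `time_course_summary`: data frame with columns
#'   `timepoint`, `date`, `mean`, `min`, `max`, ordered by date; attribute
#'   `gene_id` and `unit`.
#' @export
replicate_summary <- function(expr, sheet, gene_id) {
  if (!gene_id %in% rownames(expr))
    bud_stop(sprintf("unknown gene: %s", gene_id), "bud_lookup_error")
  v <- unclass(expr)[gene_id, sheet$sample_id]
  tps <- split(seq_len(nrow(sheet)), sheet$timepoint)
  recs <- lapply(names(tps), function(tp) {
    i <- tps[[tp]]
    data.frame(timepoint = tp, date = sheet$date[i[1]],
               mean = mean(v[i]), min = min(v[i]), max = max(v[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gene_id") <- gene_id
  attr(out, "unit") <- attr(expr, "unit")
  class(out) <- c("time_course_summary", "data.frame")
  out
}

#' Plot a replicate time-course summary
#'
#' Dots at the replicate mean, grey bars from lowest to highest replicate;
#' optionally a temperature overlay on a secondary axis.
#'
#' @param x a `time_course_summary`.
#' @param env optional [env_series()] to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.time_course_summary <- function(x, env = NULL, ...) {
  graphics::plot(x$date, x$mean, ylim = range(x$min, x$max), pch = 16,
                 xlab = "date", ylab = attr(x, "unit"),
                 main = attr(x, "gene_id"), ...)
  graphics::segments(x$date, x$min, x$date, x$max, col = "grey50", lwd = 2)
  graphics::points(x$date, x$mean, pch = 16)
  if (!is.null(env)) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(env$date, env$value, type = "l", col = "orange", lty = 2,
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "orange")
  }
  invisible(x)
}

#' Gene-family heatmap matrix
#'
#' Builds the matrix behind a family expression heatmap: rows are the family
#' members (in input order, labelled by display name) that pass the CPM-sum
#' detectability filter, columns are time points ordered by date (replicate
#' means), values are RPKM, optionally row-scaled.
#'
#' @param expr an [expression_matrix()] (typically RPKM) to display.
#' @param family data frame with columns `name` (display label) and
#'   `gene_id`, e.g. from [read_alias_table()].
#' @param cpm_expr an [expression_matrix()] in CPM on which the
#'   detectability filter operates.
#' @param sheet a [sample_sheet()].
#' @param threshold CPM-sum detectability cutoff (default 10).
#' @param scaling `"none"`, `"row_max"` (each row divided by its maximum;
#'   all-zero rows are dropped first) or `"row_z"` (per-row z-score).
#' @return numeric matrix with display-name rows and ISO-date columns;
#'   attributes `scaling` and `dropped` (family members filtered out).
#' @export
family_heatmap <- function(expr, family, cpm_expr, sheet, threshold = 10,
                           scaling = c("none", "row_max", "row_z")) {
  scaling <- match.arg(scaling)
  if (nrow(family) == 0L)
    bud_stop("empty gene family", "bud_empty_heatmap_error")
  miss <- setdiff(family$gene_id, rownames(expr))
  if (length(miss))
    bud_stop(sprintf("family gene(s) absent from matrix: %s",
                     paste(miss, collapse = ", ")), "bud_lookup_error")
  detectable <- filter_by_expression_sum(cpm_expr, threshold)
  keep <- family$gene_id %in% detectable
  dropped <- family$name[!keep]
  family <- family[keep, , drop = FALSE]
  if (nrow(family) == 0L)
    bud_stop("all family members removed by the detectability filter",
             "bud_empty_heatmap_error")
  # columns: replicate means per time point, date order
  tps <- split(sheet$sample_id, sheet$timepoint)
  tp_date <- vapply(split(as.character(sheet$date), sheet$timepoint), `[`, character(1), 1)
  ord <- order(as.Date(tp_date))
  m <- sapply(names(tps)[ord], function(tp)
    rowMeans(unclass(expr)[family$gene_id, tps[[tp]], drop = FALSE]))
  m <- matrix(m, nrow = nrow(family),
              dimnames = list(family$name, unname(tp_date[ord])))
  if (scaling == "row_max") {
    nz <- apply(m, 1L, max) > 0
    dropped <- c(dropped, rownames(m)[!nz])
    m <- m[nz, , drop = FALSE]
    m <- m / apply(m, 1L, max)
  } else if (scaling == "row_z") {
    m <- t(scale(t(m)))
  }
  if (nrow(m) == 0L)
    bud_stop("all family members removed by the detectability filter",
             "bud_empty_heatmap_error")
  attr(m, "scaling") <- scaling
  attr(m, "dropped") <- dropped
  m
}

#' Astronomical day length
#'
#' Closed-form solar model: solar declination from the day of year (Fourier
#' series), sunrise/sunset hour angle at solar altitude -0.833 degrees
#' (atmospheric refraction plus solar radius). Accuracy is within about ten
#' minutes of published sunrise/sunset tables for mid-latitudes, which is
#' sufficient for plotting photoperiod against expression profiles.
#'
#' @param date `Date` vector (or ISO-8601 strings).
#' @param latitude_deg latitude in degrees north, |latitude| <= 66 (polar
#'   day/night is not handled).
#' @return numeric vector of day lengths in hours, within \[0, 24\].
#' @export
day_length <- function(date, latitude_deg) {
  if (abs(latitude_deg) > 66)
    bud_stop("polar latitudes (|lat| > 66) unsupported", "bud_unsupported_latitude_error")
  date <- parse_iso_date(date)
  doy <- as.integer(format(date, "%j"))
  yl <- ifelse(as.integer(format(date, "%Y")) %% 4 == 0, 366, 365)
  g <- 2 * pi / yl * (doy - 1 + 0.5)           # fractional year at solar noon
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lat <- latitude_deg * pi / 180
  zen <- 90.833 * pi / 180                      # civil rise/set zenith
  cosH <- (cos(zen) - sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  cosH <- pmin(1, pmax(-1, cosH))
  2 * acos(cosH) * 180 / pi / 15
}

#' Day-length series over the sampling period
#'
#' @param from,to inclusive date range (ISO-8601 or `Date`).
#' @param latitude_deg latitude in degrees north (default 49.218, the
#'   vineyard's latitude).
#' @return data frame of class `day_length_series` with columns `date`,
#'   `day_length` (hours); attribute `latitude`.
#' @export
day_length_series <- function(from, to, latitude_deg = 49.218) {
  dates <- seq(parse_iso_date(from), parse_iso_date(to), by = "day")
  out <- data.frame(date = dates, day_length = day_length(dates, latitude_deg))
  attr(out, "latitude") <- latitude_deg
  class(out) <- c("day_length_series", "data.frame")
  out
}
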