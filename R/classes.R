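#' @keywords internal
"_PACKAGE"

# Classed error helper so callers can test on condition class rather than
# message text.
bud_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "budclock_error", "error", "condition")))
}

#' Construct a validated count matrix
#'
#' A `count_matrix` is an integer matrix of non-negative read counts with
#' unique gene identifiers as row names and unique sample identifiers as
#' column names.
#'
#' @param counts numeric matrix of non-negative integral counts with
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @return an integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    bud_stop("count matrix needs at least one gene and one sample", "bud_format_error")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    bud_stop("count matrix needs gene row names and sample column names", "bud_format_error")
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    bud_stop(sprintf("duplicate gene id(s): %s", paste(dup_g, collapse = ", ")),
             "bud_format_error")
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    bud_stop(sprintf("duplicate sample id(s): %s", paste(dup_s, collapse = ", ")),
             "bud_format_error")
  if (anyNA(counts) || any(counts < 0))
    bud_stop("counts must be non-negative and non-missing", "bud_format_error")
  if (any(counts != round(counts)))
    bud_stop("counts must be integral", "bud_format_error")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("count_matrix", class(matrix())))
}

#' Construct a validated sample sheet
#'
#' Per-sample metadata driving replicate filtering and the pairing of
#' samples with the dated environmental covariate.
#'
#' @param df data frame with columns `sample_id`, `timepoint`, `date`
#'   (ISO-8601 string or `Date`), `replicate` (positive integer).
#' @return data frame of class `sample_sheet`, `date` parsed to `Date`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "timepoint", "date", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    bud_stop(sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")),
             "bud_format_error")
  df <- as.data.frame(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$timepoint <- as.character(df$timepoint)
  df$date <- parse_iso_date(df$date)
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    bud_stop("replicate must be a positive integer", "bud_format_error")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    bud_stop(sprintf("duplicate sample id(s): %s", paste(dup, collapse = ", ")),
             "bud_format_error")
  key <- paste(df$timepoint, df$replicate, sep = "\r")
  dupk <- unique(key[duplicated(key)])
  if (length(dupk))
    bud_stop(sprintf("duplicate (timepoint, replicate) pair(s): %s",
                     paste(gsub("\r", ", rep ", dupk), collapse = "; ")),
             "bud_format_error")
  # all samples of one timepoint share one date
  by_tp <- split(df$date, df$timepoint)
  bad <- names(by_tp)[vapply(by_tp, function(d) length(unique(d)) > 1L, logical(1))]
  if (length(bad))
    bud_stop(sprintf("timepoint(s) with conflicting dates: %s", paste(bad, collapse = ", ")),
             "bud_format_error")
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Construct a validated environmental series
#'
#' Calendar-dated daily values of an environmental covariate (here: daily
#' mean air temperature in degrees Celsius).
#'
#' @param df data frame with columns `date` and `value`. Rows are sorted by
#'   date; duplicate dates are an error.
#' @return data frame of class `env_series`.
#' @export
env_series <- function(df) {
  need <- c("date", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    bud_stop(sprintf("environmental series missing column(s): %s",
                     paste(miss, collapse = ", ")), "bud_format_error")
  df <- as.data.frame(df)[need]
  df$date <- parse_iso_date(df$date)
  df$value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(df$value))
    bud_stop("non-numeric value in environmental series", "bud_format_error")
  dup <- unique(df$date[duplicated(df$date)])
  if (length(dup))
    bud_stop(sprintf("duplicate date(s) in environmental series: %s",
                     paste(format(dup), collapse = ", ")), "bud_format_error")
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("env_series", "data.frame")
  df
}

#' Construct a validated gene annotation table
#'
#' @param df data frame with columns `gene_id`, `length_bp` (positive
#'   integer), `description` (free text); optional `homolog_id`.
#' @return data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "length_bp", "description")
  miss <- setdiff(need, names(df))
  if (length(miss))
    bud_stop(sprintf("annotation missing column(s): %s", paste(miss, collapse = ", ")),
             "bud_format_error")
  df <- as.data.frame(df)
  df$gene_id <- as.character(df$gene_id)
  df$length_bp <- as.integer(df$length_bp)
  df$description <- as.character(df$description)
  if (!"homolog_id" %in% names(df)) df$homolog_id <- NA_character_
  df <- df[c("gene_id", "length_bp", "description", "homolog_id")]
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    bud_stop(sprintf("duplicate gene id(s) in annotation: %s", paste(dup, collapse = ", ")),
             "bud_format_error")
  if (anyNA(df$length_bp) || any(df$length_bp < 1L))
    bud_stop("gene length must be a positive integer (bp)", "bud_format_error")
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Construct a named gene set
#'
#' @param members character vector of gene identifiers.
#' @param name label for the set.
#' @return character vector of class `gene_set` with a `name` attribute.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- unique(as.character(members))
  structure(members, name = name, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d gene(s)\n", attr(x, "name"), length(x)))
  if (length(x)) cat(" ", paste(utils::head(x, 6), collapse = ", "),
                     if (length(x) > 6) "..." else "", "\n")
  invisible(x)
}

#' Construct an expression matrix with a unit tag
#'
#' @param values non-negative numeric matrix with gene row names and sample
#'   column names.
#' @param unit `"CPM"` or `"RPKM"`.
#' @return numeric matrix of class `expression_matrix` with a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("CPM", "RPKM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    bud_stop("expression matrix needs gene and sample names", "bud_format_error")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    bud_stop("expression values must be finite and non-negative", "bud_format_error")
  structure(values, unit = unit, class = c("expression_matrix", class(matrix())))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> unit=%s: %d genes x %d samples\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}

# Strict ISO-8601 date parsing; rejects impossible dates such as June 31.
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) | format(d, "%Y-%m-%d") != x
  if (any(bad))
    bud_stop(sprintf("unparseable ISO-8601 date(s): %s",
                     paste(unique(x[bad]), collapse = ", ")), "bud_format_error")
  d
}

# Subset a count/expression matrix to samples, preserving class attributes.
keep_samples <- function(m, sample_ids) {
  out <- m[, sample_ids, drop = FALSE]
  if (inherits(m, "expression_matrix")) {
    attr(out, "unit") <- attr(m, "unit")
    class(out) <- class(m)
  } else if (inherits(m, "count_matrix")) {
    class(out) <- class(m)
  }
  out
}
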