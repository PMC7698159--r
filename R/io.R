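# Readers/writers for the plain-text exchange formats. All tables are UTF-8
# TSV/CSV with a header row; comment lines starting with "#" are skipped
# (featureCounts emits such a header line).

read_table_auto <- function(path) {
  if (!file.exists(path))
    bud_stop(sprintf("file not found: %s", path), "bud_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "\"", fileEncoding = "UTF-8"),
    error = function(e) bud_stop(sprintf("cannot parse %s: %s", path,
                                         conditionMessage(e)), "bud_format_error"))
  if (nrow(df) == 0L)
    bud_stop(sprintf("empty table: %s", path), "bud_format_error")
  df
}

#' Read a count table into a count matrix
#'
#' Two dialects are supported. `"merged"`: first column gene ids, remaining
#' columns one sample each (header row holds sample ids). `"per_sample"`:
#' one file per sample with columns `gene_id`, optional `length`, and a
#' single count column; `path` may then be a vector of files, merged in the
#' given order after checking that all files share an identical gene
#' universe. Comment lines starting `#` are skipped.
#'
#' @param path path to a merged table, or character vector of per-sample
#'   files.
#' @param dialect `"merged"` or `"per_sample"`.
#' @param sample_ids for `per_sample`: ids for the columns; defaults to
#'   file base names without extension.
#' @return a [count_matrix()]. For per-sample files carrying a `length`
#'   column, the lengths are attached as attribute `lengths` (named integer
#'   vector) for use by [rpkm()] via [gene_annotation()].
#' @export
read_count_table <- function(path, dialect = c("merged", "per_sample"),
                             sample_ids = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "merged") {
    df <- read_table_auto(path[1])
    if (ncol(df) < 2L)
      bud_stop("merged count table needs a gene column plus >= 1 sample column",
               "bud_format_error")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[-1])
    mode(m) <- "numeric"
    if (anyNA(m))
      bud_stop("non-numeric count in merged table", "bud_format_error")
    rownames(m) <- genes
    return(count_matrix(m))
  }
  files <- path
  if (is.null(sample_ids))
    sample_ids <- tools::file_path_sans_ext(basename(files))
  stopifnot(length(sample_ids) == length(files))
  cols <- vector("list", length(files))
  lens <- NULL
  genes0 <- NULL
  for (i in seq_along(files)) {
    df <- read_table_auto(files[i])
    nm <- tolower(names(df))
    gid <- as.character(df[[which(nm %in% c("gene_id", "geneid", "gene"))[1]]])
    len_col <- which(nm == "length")
    cnt_col <- setdiff(seq_along(df), c(which(nm %in% c("gene_id", "geneid", "gene")), len_col))
    if (length(cnt_col) != 1L)
      bud_stop(sprintf("%s: expected exactly one count column", files[i]),
               "bud_format_error")
    if (is.null(genes0)) {
      genes0 <- gid
      if (length(len_col))
        lens <- stats::setNames(as.integer(df[[len_col[1]]]), gid)
    } else if (!identical(sort(gid), sort(genes0))) {
      bud_stop(sprintf("%s: gene universe differs from first file", files[i]),
               "bud_format_error")
    }
    cols[[i]] <- stats::setNames(as.numeric(df[[cnt_col]]), gid)[genes0]
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(genes0, sample_ids)
  cm <- count_matrix(m)
  if (!is.null(lens)) attr(cm, "lengths") <- lens
  cm
}

#' Read a sample sheet
#'
#' @param path TSV/CSV with columns `sample_id`, `timepoint`, `date`
#'   (ISO-8601), `replicate`.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) sample_sheet(read_table_auto(path))

#' Read a daily environmental series
#'
#' @param path CSV/TSV with columns `date` (ISO-8601) and `value` (daily
#'   mean air temperature, degrees Celsius). Rows may be unsorted; duplicate
#'   dates are rejected.
#' @return an [env_series()] sorted by date.
#' @export
read_env_series <- function(path) env_series(read_table_auto(path))

#' Read a gene annotation table
#'
#' @param path TSV/CSV with columns `gene_id`, `length_bp`, `description`
#'   and optionally `homolog_id`.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) gene_annotation(read_table_auto(path))

#' Read a gene family / alias list
#'
#' Two-column table mapping display names (e.g. `VviAP1`) to gene ids.
#'
#' @param path TSV/CSV with columns `name` and `gene_id`.
#' @return data frame with columns `name`, `gene_id`.
#' @export
read_alias_table <- function(path) {
  df <- read_table_auto(path)
  miss <- setdiff(c("name", "gene_id"), names(df))
  if (length(miss))
    bud_stop(sprintf("alias table missing column(s): %s", paste(miss, collapse = ", ")),
             "bud_format_error")
  data.frame(name = as.character(df$name), gene_id = as.character(df$gene_id),
             stringsAsFactors = FALSE)
}

#' Drop time points lacking the required replicate count
#'
#' Sampling dates for which fewer than `required_replicates` successful
#' replicates exist are excluded entirely (samples dropped from both the
#' matrix and the sheet), mirroring the policy of analysing only complete
#' triplicate time points.
#'
#' @param matrix a [count_matrix()] or [expression_matrix()].
#' @param sheet a [sample_sheet()] covering the matrix samples.
#' @param required_replicates minimum replicates per time point (default 3).
#' @param quiet suppress the message listing dropped time points.
#' @return list with elements `matrix`, `sheet`, and `dropped` (character
#'   vector of dropped timepoint labels).
#' @export
filter_complete_timepoints <- function(matrix, sheet, required_replicates = 3L,
                                       quiet = FALSE) {
  stopifnot(required_replicates >= 1L)
  miss <- setdiff(sheet$sample_id, colnames(matrix))
  if (length(miss))
    bud_stop(sprintf("sample(s) in sheet absent from matrix: %s",
                     paste(miss, collapse = ", ")), "bud_format_error")
  n_rep <- table(sheet$timepoint)
  drop_tp <- names(n_rep)[n_rep < required_replicates]
  keep <- !(sheet$timepoint %in% drop_tp)
  if (!any(keep))
    bud_stop("no time point satisfies the replicate requirement", "bud_empty_design_error")
  sheet2 <- sheet[keep, , drop = FALSE]
  rownames(sheet2) <- NULL
  class(sheet2) <- class(sheet)
  if (length(drop_tp) && !quiet)
    message("dropped incomplete timepoint(s): ", paste(drop_tp, collapse = ", "))
  list(matrix = keep_samples(matrix, sheet2$sample_id),
       sheet = sheet2,
       dropped = drop_tp)
}

#' Write a count matrix as a merged TSV
#' @param matrix a [count_matrix()].
#' @param path output path.
#' @export
write_count_table <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV with a unit comment line
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s", attr(expr, "unit")), con)
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract exon-union gene lengths from a GFF3 file
#'
#' Exon intervals (1-based, end-inclusive) are grouped by their gene and the
#' length of the per-gene union of intervals is returned. Requires the
#' `rtracklayer` and `GenomicRanges` packages.
#'
#' @param path GFF3 file with `gene` and `exon` features; exons must carry a
#'   `Parent` (mRNA) whose own `Parent` is the gene, or a direct gene Parent.
#' @return a [gene_annotation()] with `length_bp` set and empty descriptions.
#' @export
gene_lengths_from_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    bud_stop("rtracklayer/GenomicRanges required for GFF3 import", "bud_io_error")
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  tx2gene <- stats::setNames(as.character(tx$Parent), tx$ID)
  parent <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
  gene_of <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
  by_gene <- split(ex, gene_of)
  lens <- vapply(by_gene, function(g)
    sum(GenomicRanges::width(GenomicRanges::reduce(g))), numeric(1))
  gene_annotation(data.frame(gene_id = names(lens),
                             length_bp = as.integer(lens),
                             description = "",
                             stringsAsFactors = FALSE))
}
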