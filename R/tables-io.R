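# Tabular dialects exchanged between pipeline stages. Everything is TSV
# (UTF-8, LF); reading is gzip-transparent through R connections.

diff_columns <- c("gene_id", "sample_1", "sample_2", "value_1", "value_2",
                  "log2_fc", "p_value", "q_value", "status")

#' Read a pairwise differential table
#'
#' Parses the gene_exp.diff-style dialect: one row per gene and contrast,
#' with mean expression of both conditions, log2 fold-change, p, FDR-adjusted
#' q and a status flag (`OK`, `NOTEST`, `LOWDATA`). Unknown extra columns are
#' ignored; malformed numeric fields and bound violations are reported with
#' 1-based data-row numbers.
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return Data frame with the columns in `elicitR:::diff_columns`.
#' @seealso [write_diff_table()], [test_contrast()]
#' @export
read_diff_table <- function(path) {
  df <- read_tsv(path, required = diff_columns)
  if (nrow(df) == 0) abort_input("%s: empty differential table", path)
  for (col in c("value_1", "value_2", "log2_fc", "p_value", "q_value")) {
    df[[col]] <- numeric_column(df, col, path)
  }
  for (col in c("p_value", "q_value")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad)) {
      abort_input("%s: %s outside [0, 1] at row(s) %s", path, col,
                  paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  bad_status <- which(!df$status %in% c("OK", "NOTEST", "LOWDATA"))
  if (length(bad_status)) {
    abort_input("%s: unknown status at row(s) %s", path,
                paste(utils::head(bad_status, 5), collapse = ", "))
  }
  # sign(log2_fc) must agree with value_2 vs value_1 when both are positive
  both_pos <- !is.na(df$value_1) & !is.na(df$value_2) &
    df$value_1 > 0 & df$value_2 > 0 & !is.na(df$log2_fc)
  incons <- which(both_pos & abs(df$log2_fc) > 1e-9 &
                    sign(df$log2_fc) * sign(df$value_2 - df$value_1) == -1)
  if (length(incons)) {
    abort_input("%s: log2_fc sign inconsistent with values at row(s) %s",
                path, paste(utils::head(incons, 5), collapse = ", "))
  }
  df[diff_columns]
}

#' Write a pairwise differential table
#' @param diffs Data frame as produced by [test_contrast()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_diff_table <- function(diffs, path) {
  miss <- setdiff(diff_columns, names(diffs))
  if (length(miss)) {
    abort_input("diff table missing column(s): %s", paste(miss, collapse = ", "))
  }
  write_tsv(diffs[diff_columns], path)
}

#' Read a long-format expression table
#'
#' Expects columns `gene_id`, `genotype`, `timepoint_min`, `replicate`,
#' `fpkm`. Duplicate (gene, genotype, timepoint, replicate) keys are fatal.
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return Data frame in long format.
#' @export
read_expression_long <- function(path) {
  cols <- c("gene_id", "genotype", "timepoint_min", "replicate", "fpkm")
  df <- read_tsv(path, required = cols)
  df <- df[cols]
  df$timepoint_min <- numeric_column(df, "timepoint_min", path)
  df$replicate <- numeric_column(df, "replicate", path)
  df$fpkm <- numeric_column(df, "fpkm", path)
  if (any(df$fpkm < 0, na.rm = TRUE)) {
    abort_input("%s: negative fpkm values", path)
  }
  key <- paste(df$gene_id, df$genotype, df$timepoint_min, df$replicate)
  if (anyDuplicated(key)) {
    abort_input("%s: duplicate (gene, genotype, timepoint, replicate) rows (%d)",
                path, sum(duplicated(key)))
  }
  df
}

#' Write a long-format expression table
#' @param expr Long-format expression data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_expression_long <- function(expr, path) {
  cols <- c("gene_id", "genotype", "timepoint_min", "replicate", "fpkm")
  miss <- setdiff(cols, names(expr))
  if (length(miss)) {
    abort_input("expression table missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  write_tsv(expr[cols], path)
}

#' Read a flat gene-to-term annotation map
#'
#' Two-column TSV (`gene_id`, `term_id`). Duplicated pairs are deduplicated
#' with a warning reporting the count; an empty map (header only) is valid
#' and simply yields zero enrichment tests downstream.
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return Data frame `gene_id`, `term_id`.
#' @export
read_annotation_map <- function(path) {
  df <- read_tsv(path, required = c("gene_id", "term_id"))
  df <- df[c("gene_id", "term_id")]
  dup <- duplicated(paste(df$gene_id, df$term_id))
  if (any(dup)) {
    warning(sprintf("%s: %d duplicated gene-term pair(s) removed",
                    path, sum(dup)))
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a flat gene-to-term annotation map
#' @param term_map Data frame `gene_id`, `term_id`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_annotation_map <- function(term_map, path) {
  write_tsv(term_map[c("gene_id", "term_id")], path)
}

call_columns <- c("gene_id", "timepoint_min", "responsive", "direction",
                  "category", "baseline_diff")

#' Write per-gene classification calls
#' @param calls Data frame from [classify_genes()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_gene_calls <- function(calls, path) {
  cols <- intersect(call_columns, names(calls))
  write_tsv(calls[cols], path)
}

#' Read per-gene classification calls
#' @param path TSV written by [write_gene_calls()].
#' @return Data frame of calls.
#' @export
read_gene_calls <- function(path) {
  df <- read_tsv(path, required = c("gene_id", "timepoint_min", "responsive",
                                    "direction", "category"))
  df$timepoint_min <- numeric_column(df, "timepoint_min", path)
  df$responsive <- as.logical(df$responsive)
  if ("baseline_diff" %in% names(df)) {
    df$baseline_diff <- as.logical(df$baseline_diff)
  }
  df
}
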