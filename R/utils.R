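# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Input errors (bad files, bad arguments) carry their own condition class so
# the CLI can map them to exit code 1 while genuine bugs map to 2.
abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("elicitr_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Condition labels follow the grammar "<genotype>_<minutes>"; genotype labels
# may themselves contain underscores (mkp1_mpk6), so parse from the right.
condition_label <- function(genotype, timepoint_min) {
  paste(genotype, timepoint_min, sep = "_")
}

parse_condition <- function(label) {
  m <- regmatches(label, regexec("^(.*)_([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort_input("malformed condition label(s): %s",
                paste(label[bad], collapse = ", "))
  }
  data.frame(genotype = vapply(m, `[`, "", 2L),
             timepoint_min = as.numeric(vapply(m, `[`, "", 3L)))
}

#' Percentage of a count over a denominator
#'
#' Shared summary arithmetic: percentages are reported rounded to the nearest
#' integer in prose-style summaries and to two decimals in tables. A zero
#' denominator yields `NA` (undefined), never zero and never an error.
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @param digits Decimal places (0 for prose style, 2 for table style).
#' @return Numeric vector of percentages on the 0-100 scale, `NA` where the
#'   denominator is zero.
#' @examples
#' percent_of(180, 220)      # 82
#' percent_of(1136, 2548, 2) # 44.58
#' @export
percent_of <- function(num, den, digits = 0) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  ifelse(den == 0, NA_real_, round(100 * num / den, digits))
}

# "44.58%(1136/2548)"-style cell used by the report tables.
percent_label <- function(num, den, digits = 2) {
  p <- percent_of(num, den, digits)
  n <- length(p)
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  ifelse(is.na(p), "undef",
         sprintf("%s%%(%d/%d)", formatC(p, format = "f", digits = digits),
                 num, den))
}

write_tsv <- function(df, path) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) abort_input("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort_input("cannot read %s: %s", path,
                                    conditionMessage(e)))
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      abort_input("%s: missing mandatory column(s): %s", path,
                  paste(miss, collapse = ", "))
    }
  }
  df
}

# Coerce a column to numeric, reporting 1-based data-row numbers of failures.
numeric_column <- function(df, col, path) {
  x <- df[[col]]
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "NA")
  if (length(bad)) {
    abort_input("%s: column '%s' not numeric at row(s) %s", path, col,
                paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}
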