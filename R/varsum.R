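#' Read a variant-classification count table
#'
#' Reads a TSV whose first column is the gene symbol and whose remaining
#' columns are non-negative integer counts of variants per annotation class
#' (gnomAD schema) or clinical-significance class (ClinVar schema). A
#' \code{"-"} (or empty) cell denotes a gene absent from the source and is
#' recorded as missing, not zero, so it is excluded from totals and
#' denominators.
#'
#' @param path file path.
#' @param schema \code{"gnomad"} (requires columns \code{all},
#'   \code{missense}, \code{synonymous}) or \code{"clinvar"} (requires
#'   \code{all}, \code{b_lb}, \code{p_lp}, \code{vus}).
#' @return data.frame of class \code{variant_class_table}: \code{gene} plus
#'   integer count columns with \code{NA} for missing cells.
#' @export
read_counts <- function(path, schema = c("gnomad", "clinvar")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  names(df) <- tolower(names(df))
  if (ncol(df) < 2L) stopf("parse error: need a gene column plus counts")
  required <- switch(schema,
                     gnomad = c("all", "missense", "synonymous"),
                     clinvar = c("all", "b_lb", "p_lp", "vus"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stopf("schema error (%s): missing column(s) %s", schema,
          paste(missing_cols, collapse = ", "))
  }
  gene <- toupper(trimws(df[[1L]]))
  counts <- df[-1L]
  parsed <- lapply(names(counts), function(col) {
    x <- trimws(counts[[col]])
    x[x %in% c("-", "")] <- NA
    bad <- !is.na(x) & !grepl("^[0-9]+$", x)
    if (any(bad)) {
      stopf("parse error: non-integer count '%s' in column '%s'",
            x[bad][1L], col)
    }
    as.integer(x)
  })
  out <- data.frame(gene = gene, stats::setNames(parsed, names(counts)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("variant_class_table", "data.frame")
  out
}

get_column <- function(table, column) {
  column <- tolower(column)
  if (!column %in% names(table)) {
    stopf("unknown column: %s (have: %s)", column,
          paste(setdiff(names(table), "gene"), collapse = ", "))
  }
  table[[column]]
}

#' Total count over genes with a present cell
#'
#' @param table a \code{variant_class_table}.
#' @param column count column name.
#' @return integer sum over present (non-missing) cells.
#' @export
total <- function(table, column = "all") {
  x <- get_column(table, column)
  sum(x, na.rm = TRUE)
}

#' Percentage of one count class over another, truncated to one decimal
#'
#' Computes 100 * numerator / denominator and truncates (toward zero) at one
#' decimal place -- the convention under which the published percentages are
#' mutually consistent with their printed counts. With \code{gene = "ALL"}
#' the column totals over present cells are used.
#'
#' @param table a \code{variant_class_table}.
#' @param numerator_column count column for the numerator.
#' @param gene a gene symbol, or \code{"ALL"} for column totals.
#' @param denominator_column count column for the denominator (default
#'   \code{"all"}).
#' @return percentage truncated to one decimal place.
#' @export
fraction <- function(table, numerator_column, gene = "ALL",
                     denominator_column = "all") {
  if (identical(toupper(gene), "ALL")) {
    num <- total(table, numerator_column)
    den <- total(table, denominator_column)
  } else {
    i <- match(toupper(gene), table$gene)
    if (is.na(i)) stopf("unknown gene: %s", gene)
    num <- get_column(table, numerator_column)[i]
    den <- get_column(table, denominator_column)[i]
  }
  if (is.na(num) || is.na(den)) stopf("missing cell for gene '%s'", gene)
  if (den <= 0) stopf("undefined value: zero denominator")
  trunc(1000 * num / den) / 10
}

#' Gene with the maximal count in a column
#'
#' @param table a \code{variant_class_table}.
#' @param column count column name.
#' @return the gene symbol with the largest present count; ties go to the
#'   lexicographically smallest symbol with a warning.
#' @export
argmax_gene <- function(table, column = "all") {
  x <- get_column(table, column)
  if (all(is.na(x))) stopf("all cells are missing in column '%s'", column)
  top <- which(x == max(x, na.rm = TRUE))
  genes <- sort(table$gene[top])
  if (length(genes) > 1L) {
    warning("tie in column '", column, "': ", paste(genes, collapse = ", "))
  }
  genes[1L]
}
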