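#' Annotation sets: term-to-gene mappings for one namespace
#'
#' An \code{annotation_set} maps ontology term IDs to sets of upper-cased
#' gene symbols for a single namespace (GO biological process, or HPO
#' phenotypic abnormality). Empty terms are dropped, duplicate genes within a
#' term collapse to one.
#'
#' @param namespace \code{"GO_BP"} or \code{"HPO"}.
#' @param terms named list: term ID -> character vector of gene symbols.
#' @param source free-text provenance.
#' @return an \code{annotation_set} object.
#' @export
annotation_set <- function(namespace = c("GO_BP", "HPO"), terms,
                           source = "") {
  namespace <- match.arg(namespace)
  if (anyDuplicated(names(terms))) {
    dup <- unique(names(terms)[duplicated(names(terms))])
    merged <- lapply(dup, function(id) {
      unlist(terms[names(terms) == id], use.names = FALSE)
    })
    terms <- c(terms[!names(terms) %in% dup], stats::setNames(merged, dup))
  }
  terms <- lapply(terms, function(g) sort(norm_symbols(g)))
  terms <- terms[vapply(terms, length, integer(1L)) > 0L]
  structure(list(namespace = namespace, terms = terms, source = source),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d terms, %d distinct genes (%s)\n",
              x$namespace, length(x$terms),
              length(unique(unlist(x$terms))), x$source))
  invisible(x)
}

#' Read a GAF 2.x gene association file
#'
#' Parses the 15+ column tab layout: column 2 is the gene symbol, column 4
#' the qualifier, column 5 the term ID. Rows whose qualifier contains
#' \code{NOT} are dropped, comment lines starting with \code{!} are ignored.
#'
#' @param path file path.
#' @return an \code{annotation_set} with namespace \code{GO_BP}.
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  if (!any(keep)) {
    warning("GAF file contains no association rows: ", path)
    return(annotation_set("GO_BP", list(), source = path))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- vapply(fields, length, integer(1L))
  if (any(nfield < 15L)) {
    bad <- which(keep)[which(nfield < 15L)[1L]]
    stopf("GAF parse error at line %d: %d columns, expected >= 15",
          bad, nfield[which(nfield < 15L)[1L]])
  }
  symbol <- toupper(vapply(fields, `[[`, character(1L), 2L))
  qualifier <- vapply(fields, `[[`, character(1L), 4L)
  term <- vapply(fields, `[[`, character(1L), 5L)
  ok <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  terms <- lapply(split(symbol[ok], term[ok]), unique)
  annotation_set("GO_BP", terms, source = path)
}

#' Read an HPO genes_to_phenotype association table
#'
#' Expects a TSV with a gene-symbol column (\code{gene_symbol}) and an HPO
#' term column (\code{hpo_id}); the header is detected and skipped, rows for
#' the same term are merged, and Windows line endings are tolerated.
#'
#' @param path file path.
#' @return an \code{annotation_set} with namespace \code{HPO}.
#' @export
read_hpo_assoc <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("\r$", "", tolower(names(df)))
  gene_col <- intersect(c("gene_symbol", "gene-symbol", "entrez-gene-symbol",
                          "gene"), names(df))[1L]
  term_col <- intersect(c("hpo_id", "hpo-term-id", "hpo term id", "term_id"),
                        names(df))[1L]
  if (is.na(gene_col) || is.na(term_col)) {
    stopf("schema error: need gene symbol and HPO term columns, found: %s",
          paste(names(df), collapse = ", "))
  }
  df[] <- lapply(df, function(x) if (is.character(x)) sub("\r$", "", x) else x)
  terms <- lapply(split(toupper(df[[gene_col]]), df[[term_col]]), unique)
  annotation_set("HPO", terms, source = path)
}

#' Union the gene sets of selected ontology terms
#'
#' @param ann an \code{annotation_set}.
#' @param term_ids term IDs to select; unknown IDs raise a warning (an error
#'   if none are known).
#' @return sorted character vector of gene symbols.
#' @export
genes_for_terms <- function(ann, term_ids) {
  if (length(term_ids) == 0L) stopf("term_ids must be nonempty")
  unknown <- setdiff(term_ids, names(ann$terms))
  if (length(unknown) == length(term_ids)) {
    stopf("no selected term is present in the annotation set: %s",
          paste(unknown, collapse = ", "))
  }
  if (length(unknown) > 0L) {
    warning("unknown term IDs skipped: ", paste(unknown, collapse = ", "))
  }
  sort(unique(unlist(ann$terms[setdiff(term_ids, unknown)], use.names = FALSE)))
}

#' Venn counts for two gene sets
#'
#' @param a,b character vectors of gene symbols (case-normalized internally).
#' @return named integer vector \code{c(only_a, only_b, both)}.
#' @export
venn_counts <- function(a, b) {
  a <- norm_symbols(a)
  b <- norm_symbols(b)
  both <- length(intersect(a, b))
  c(only_a = length(a) - both, only_b = length(b) - both, both = both)
}

#' Read and write GMT gene-set files
#'
#' One set per line: \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param sets named list of character vectors (names become set names).
#' @param path file path.
#' @return \code{read_gmt}: named list of character vectors;
#'   \code{write_gmt}: the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) sort(norm_symbols(f[-(1:2)]))),
                  vapply(fields, `[[`, character(1L), 1L))
}
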