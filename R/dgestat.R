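#' Two-group differential expression on log2 data
#'
#' Per-gene two-sample contrast on a log2-scale expression matrix: logFC is
#' the case-group mean minus the control-group mean, p-values are two-sided,
#' and q-values are Benjamini-Hochberg adjusted over all tested genes.
#'
#' Two test statistics are available. \code{"moderated"} (the default) is
#' the empirical-Bayes moderated t of limma, which shrinks per-gene
#' variances toward a common prior and is the conventional choice for the
#' small per-group sample sizes of knockdown/knockout assays.
#' \code{"welch"} is a plain Welch two-sample t with Welch-Satterthwaite
#' degrees of freedom, useful as a dependency-light, closed-form reference.
#' Genes with zero variance in both groups and equal means get p = 1 and are
#' flagged with a warning (Welch path).
#'
#' @param expr numeric matrix, genes x samples, log2 scale, with rownames.
#' @param groups two-level group labels, one per column.
#' @param alpha FDR level for the \code{significant} flag (default 0.05).
#' @param control label of the reference group; defaults to the
#'   alphabetically first label (so the contrast does not depend on sample
#'   order).
#' @param method \code{"moderated"} (limma eBayes) or \code{"welch"}.
#' @return data.frame with columns \code{gene}, \code{logFC}, \code{p},
#'   \code{q}, \code{significant}; attributes \code{control} and \code{case}.
#' @export
dge_contrast <- function(expr, groups, alpha = 0.05, control = NULL,
                         method = c("moderated", "welch")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  if (length(groups) != ncol(expr)) {
    stopf("design error: %d group labels for %d samples",
          length(groups), ncol(expr))
  }
  lev <- unique(groups)
  if (length(lev) != 2L) {
    stopf("design error: need exactly 2 groups, got %d", length(lev))
  }
  control <- control %||% sort(lev)[1L]  # order-independent default
  if (!control %in% lev) stopf("design error: control level '%s' not found",
                               control)
  case <- setdiff(lev, control)
  i1 <- groups == control
  i2 <- groups == case
  if (sum(i1) < 2L || sum(i2) < 2L) {
    stopf("design error: need >= 2 samples per group")
  }
  if (method == "moderated") {
    design <- stats::model.matrix(~ factor(groups, levels = c(control, case)))
    fit <- limma::eBayes(limma::lmFit(expr, design))
    p <- fit$p.value[, 2L]
    q <- stats::p.adjust(p, method = "BH")
    return(structure(
      data.frame(gene = rownames(expr),
                 logFC = as.numeric(fit$coefficients[, 2L]),
                 p = as.numeric(p), q = as.numeric(q),
                 significant = q < alpha,
                 stringsAsFactors = FALSE, row.names = NULL),
      control = control, case = case, alpha = alpha, method = method))
  }
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(expr[, i2, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  logfc <- m2 - m1
  tstat <- ifelse(se2 > 0, logfc / sqrt(se2), ifelse(logfc == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L)),
               1)
  p <- 2 * stats::pt(-abs(tstat), df)
  constant <- se2 == 0 & logfc == 0
  if (any(constant)) {
    warning(sum(constant), " all-constant gene(s) set to p = 1")
    p[constant] <- 1
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  q <- stats::p.adjust(p, method = "BH")
  structure(data.frame(gene = rownames(expr), logFC = as.numeric(logfc),
                       p = as.numeric(p), q = as.numeric(q),
                       significant = q < alpha,
                       stringsAsFactors = FALSE, row.names = NULL),
            control = control, case = case, alpha = alpha, method = method)
}

#' Load a precomputed differential-expression table
#'
#' Ingests a TSV with gene, logFC, and p and/or q columns (for example a
#' table exported from a limma or edgeR run). When q is absent it is
#' recomputed from p by Benjamini-Hochberg; when both are present, any gene
#' with q < p is rejected as inconsistent with an FDR adjustment.
#'
#' @param path file path.
#' @param schema named character vector mapping the standard names
#'   \code{gene}, \code{logFC}, \code{p}, \code{q} to the file's column names.
#' @param alpha FDR level for the \code{significant} flag.
#' @return data.frame as in [dge_contrast()].
#' @export
load_dge_table <- function(path,
                           schema = c(gene = "gene", logFC = "logFC",
                                      p = "p", q = "q"),
                           alpha = 0.05) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(std) {
    col <- if (std %in% names(schema)) schema[[std]] else std
    if (col %in% names(df)) df[[col]] else NULL
  }
  gene <- pick("gene"); logfc <- pick("logFC")
  p <- pick("p"); q <- pick("q")
  if (is.null(gene) || is.null(logfc)) {
    stopf("schema error: gene and logFC columns are required")
  }
  if (is.null(p) && is.null(q)) stopf("schema error: need a p or q column")
  check_range <- function(x, nm) {
    if (any(!is.finite(x) | x <= 0 | x > 1)) {
      stopf("range error: %s values must lie in (0, 1]", nm)
    }
  }
  if (!is.null(p)) check_range(p, "p")
  if (!is.null(q)) check_range(q, "q")
  if (is.null(q)) q <- stats::p.adjust(p, method = "BH")
  else if (!is.null(p) && any(q < p - 1e-12)) {
    stopf("integrity error: q < p for %d gene(s)", sum(q < p - 1e-12))
  }
  if (is.null(p)) p <- NA_real_
  data.frame(gene = toupper(gene), logFC = as.numeric(logfc),
             p = as.numeric(p), q = as.numeric(q), significant = q < alpha,
             stringsAsFactors = FALSE)
}

#' Write a differential-expression table
#'
#' @param dge data.frame from [dge_contrast()] or [load_dge_table()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_dge_table <- function(dge, path) {
  utils::write.table(dge, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
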