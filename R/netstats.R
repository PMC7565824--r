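#' Normalized betweenness centrality
#'
#' Brandes betweenness over unweighted shortest paths, endpoints excluded,
#' with pair normalization 2 / ((N - 1)(N - 2)) so scores lie in [0, 1].
#' Edge weights, if present, are ignored: path computations throughout the
#' package follow the unweighted NetworkAnalyzer convention.
#'
#' @param net igraph gene network.
#' @return named numeric vector, one score per gene.
#' @export
betweenness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stopf("empty network")
  if (n < 3L) {
    warning("betweenness is degenerate for networks with < 3 nodes")
    return(stats::setNames(rep(0, n), igraph::V(net)$name))
  }
  b <- igraph::betweenness(net, directed = FALSE, weights = NA,
                           normalized = TRUE)
  stats::setNames(as.numeric(b), igraph::V(net)$name)
}

#' Wasserman-Faust closeness centrality
#'
#' For each vertex with r reachable vertices (itself included) at total
#' unweighted distance D to the other r - 1, the score is
#' ((r - 1) / D) * ((r - 1) / (N - 1)): the within-component closeness scaled
#' by the reachable fraction, so disconnected components are penalized and
#' isolated nodes score 0.
#'
#' @param net igraph gene network.
#' @return named numeric vector in [0, 1].
#' @export
closeness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stopf("empty network")
  nm <- igraph::V(net)$name
  if (n == 1L) return(stats::setNames(0, nm))
  d <- igraph::distances(net, weights = NA)
  score <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    r1 <- length(di)
    if (r1 == 0L) return(0)
    (r1 / sum(di)) * (r1 / (n - 1L))
  }, numeric(1L))
  stats::setNames(score, nm)
}

#' HITS hub and authority scores
#'
#' Power iteration of the hub/authority recurrence with each undirected edge
#' treated as a pair of directed edges; computed per connected component and
#' concatenated, then each vector is scaled to unit Euclidean norm over all
#' nodes. On an undirected graph the two scores coincide analytically with
#' eigenvector centrality; both are still reported separately.
#'
#' @param net igraph gene network.
#' @return list with named numeric vectors \code{hub} and \code{authority}.
#' @export
hits_scores_net <- function(net) {
  nm <- igraph::V(net)$name
  hub <- stats::setNames(numeric(length(nm)), nm)
  auth <- hub
  comp <- igraph::components(net)
  for (k in seq_len(comp$no)) {
    sub <- igraph::induced_subgraph(net, which(comp$membership == k))
    if (igraph::vcount(sub) == 1L) {
      hub[igraph::V(sub)$name] <- 1
      auth[igraph::V(sub)$name] <- 1
      next
    }
    hs <- igraph::hits_scores(sub, scale = TRUE)
    hub[names(hs$hub)] <- as.numeric(hs$hub)
    auth[names(hs$authority)] <- as.numeric(hs$authority)
  }
  list(hub = hub / sqrt(sum(hub^2)), authority = auth / sqrt(sum(auth^2)))
}

#' Centrality table for a gene network
#'
#' @param net igraph gene network.
#' @return data.frame with columns \code{gene}, \code{betweenness},
#'   \code{closeness}, \code{hub}, \code{authority}, \code{degree}.
#' @export
centrality_table <- function(net) {
  b <- betweenness_centrality(net)
  cl <- closeness_centrality(net)
  h <- hits_scores_net(net)
  data.frame(gene = igraph::V(net)$name,
             betweenness = as.numeric(b),
             closeness = as.numeric(cl),
             hub = as.numeric(h$hub),
             authority = as.numeric(h$authority),
             degree = as.integer(igraph::degree(net)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the top central genes by combined betweenness and closeness
#'
#' Ranks genes by the mean of the two centralities' rank scores (each
#' column's ranks rescaled to [0, 1], ties averaged), descending. Using
#' ranks makes the selection invariant to any monotone rescaling of either
#' centrality. Ties are broken by higher degree, then by lexicographically
#' smaller symbol.
#'
#' @param cent a centrality table from [centrality_table()].
#' @param k number of genes to return (default 6, the per-strategy candidate
#'   count used in the published analysis this package operationalizes).
#' @param exclude genes to skip (e.g. the disease gene itself).
#' @return character vector of k gene symbols, best first.
#' @export
top_candidates <- function(cent, k = 6L, exclude = character()) {
  if (k <= 0L) stopf("k must be a positive integer")
  keep <- !(cent$gene %in% norm_symbols(exclude))
  cent <- cent[keep, , drop = FALSE]
  if (k > nrow(cent)) stopf("k (%d) exceeds available genes (%d)", k, nrow(cent))
  rank01 <- function(x) {
    r <- rank(x, ties.method = "average")
    if (max(r) == min(r)) return(rep(0.5, length(r)))
    (r - min(r)) / (max(r) - min(r))
  }
  score <- (rank01(cent$betweenness) + rank01(cent$closeness)) / 2
  ord <- order(-score, -cent$degree, cent$gene)
  cent$gene[ord][seq_len(k)]
}

#' Combine forward and reverse strategy candidates
#'
#' @param forward,reverse gene lists selected by the forward (gene-function)
#'   and reverse (phenotype-annotation) strategies.
#' @return data.frame with columns \code{gene}, \code{forward},
#'   \code{reverse} (logical provenance flags); one row per distinct gene,
#'   forward-strategy genes first.
#' @export
combine_strategies <- function(forward, reverse) {
  forward <- unique(toupper(forward))
  reverse <- unique(toupper(reverse))
  genes <- c(forward, setdiff(reverse, forward))
  data.frame(gene = genes,
             forward = genes %in% forward,
             reverse = genes %in% reverse,
             stringsAsFactors = FALSE)
}
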