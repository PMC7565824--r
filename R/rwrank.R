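#' Assemble a heterogeneous gene-phenotype network
#'
#' Joins the gene layer with phenotype nodes through bipartite
#' gene-phenotype links and builds the column-stochastic supra-transition
#' matrix of the inter-layer random walk: from a node with at least one
#' bipartite link the walker crosses layers with probability \code{jump}
#' (uniformly over its links) and otherwise moves within its layer
#' (uniformly over its neighbors); a node with links but no within-layer
#' neighbors always crosses, and vice versa.
#'
#' @param net igraph gene network (the gene layer).
#' @param links data.frame of bipartite pairs with columns \code{gene},
#'   \code{phenotype}; every gene must be a node of \code{net}.
#' @param jump layer-crossing probability in (0, 1), default 0.5.
#' @param restart restart probability used by [rwr_scores()], default 0.7.
#' @return a \code{hetero_network}: list with the transition matrix \code{W}
#'   (genes then phenotypes), \code{genes}, \code{phenotypes}, \code{links},
#'   \code{jump}, \code{restart}, and \code{graph}, the undirected
#'   heterogeneous graph used for step counting.
#' @export
build_hetero <- function(net, links, jump = 0.5, restart = 0.7) {
  if (NROW(links) == 0L) stopf("bipartite link table is empty")
  if (jump <= 0 || jump >= 1) stopf("jump must be in (0, 1)")
  links <- unique(data.frame(gene = toupper(links$gene),
                             phenotype = as.character(links$phenotype),
                             stringsAsFactors = FALSE))
  genes <- igraph::V(net)$name
  dangling <- setdiff(links$gene, genes)
  if (length(dangling) > 0L) {
    stopf("dangling bipartite endpoint(s) not in gene layer: %s",
          paste(dangling, collapse = ", "))
  }
  phenos <- sort(unique(links$phenotype))
  nodes <- c(genes, phenos)
  idx <- stats::setNames(seq_along(nodes), nodes)

  deg <- igraph::degree(net)
  nlink_g <- table(factor(links$gene, levels = genes))
  nlink_p <- table(factor(links$phenotype, levels = phenos))

  # gene -> gene moves
  el <- igraph::as_edgelist(net)
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  within_w <- ifelse(nlink_g[from] > 0, 1 - jump, 1) / deg[from]
  # gene -> phenotype and phenotype -> gene moves
  g2p_w <- as.numeric(ifelse(deg[links$gene] > 0, jump, 1) /
                        nlink_g[links$gene])
  p2g_w <- as.numeric(1 / nlink_p[links$phenotype])

  W <- Matrix::sparseMatrix(
    i = c(idx[to], idx[links$phenotype], idx[links$gene]),
    j = c(idx[from], idx[links$gene], idx[links$phenotype]),
    x = c(as.numeric(within_w), g2p_w, p2g_w),
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes))

  hg <- igraph::add_vertices(net, length(phenos), name = phenos)
  hg <- igraph::add_edges(hg, as.vector(t(as.matrix(
    links[, c("gene", "phenotype")]))))
  structure(list(W = W, genes = genes, phenotypes = phenos, links = links,
                 jump = jump, restart = restart, graph = hg),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("<hetero_network> %d genes, %d phenotypes, %d bipartite links (jump %.2f, restart %.2f)\n",
              length(x$genes), length(x$phenotypes), nrow(x$links),
              x$jump, x$restart))
  invisible(x)
}

#' Random walk with restart on a heterogeneous network
#'
#' Power-iterates p <- (1 - restart) W p + restart p0 with p0 concentrated
#' on the seed node, to an L1 tolerance of 1e-10 (at most 10^4 iterations,
#' error on non-convergence). The stationary vector sums to 1 and ranks all
#' nodes by diffusion proximity to the seed.
#'
#' @param h a \code{hetero_network} from [build_hetero()].
#' @param seed seed node: a gene symbol or a phenotype identifier.
#' @return named numeric vector over all nodes (genes then phenotypes).
#' @export
rwr_scores <- function(h, seed) {
  nodes <- rownames(h$W)
  if (!seed %in% nodes) stopf("seed node not in network: %s", seed)
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seed] <- 1
  rwr_iterate(h$W, p0, h$restart, tol = 1e-10, max_iter = 10000L)
}

#' Minimum steps between a gene and a phenotype
#'
#' Breadth-first shortest-path length in the undirected heterogeneous graph;
#' bipartite links count as steps. Unreachable pairs return \code{Inf}.
#'
#' @param h a \code{hetero_network}.
#' @param gene gene symbol.
#' @param phenotype phenotype identifier.
#' @return positive integer number of steps, or \code{Inf}.
#' @export
min_steps <- function(h, gene, phenotype) {
  gene <- toupper(gene)
  nodes <- igraph::V(h$graph)$name
  if (!gene %in% nodes) stopf("gene not in network: %s", gene)
  if (!phenotype %in% nodes) stopf("phenotype not in network: %s", phenotype)
  as.numeric(igraph::distances(h$graph, v = gene, to = phenotype,
                               weights = NA))
}

#' Rank candidate genes against a phenotype node
#'
#' Computes, for each candidate, the minimum number of steps to the
#' phenotype and its random-walk-with-restart score when the walk restarts
#' at the phenotype node, and sorts by (steps ascending, RWR score
#' descending, symbol).
#'
#' @param candidates character vector of gene symbols, or a data.frame with
#'   a \code{gene} column plus provenance flag columns (carried through).
#' @param h a \code{hetero_network}; all candidates must be in its gene layer.
#' @param phenotype phenotype identifier to rank against.
#' @return data.frame with the candidates' provenance columns (if any) plus
#'   \code{steps} and \code{rwr_score}, best candidate first.
#' @export
rank_candidates <- function(candidates, h, phenotype) {
  df <- if (is.data.frame(candidates)) candidates
        else data.frame(gene = candidates, stringsAsFactors = FALSE)
  df$gene <- toupper(df$gene)
  missing <- setdiff(df$gene, h$genes)
  if (length(missing) > 0L) {
    stopf("candidate(s) not in gene layer: %s", paste(missing, collapse = ", "))
  }
  scores <- rwr_scores(h, phenotype)
  df$steps <- vapply(df$gene, function(g) min_steps(h, g, phenotype),
                     numeric(1L))
  df$rwr_score <- as.numeric(scores[df$gene])
  df <- df[order(df$steps, -df$rwr_score, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a bipartite gene-phenotype link table
#'
#' @param path TSV with columns \code{gene} and \code{phenotype}.
#' @return data.frame with those two columns.
#' @export
read_pheno_links <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "phenotype") %in% names(df))) {
    stopf("schema error: need columns gene, phenotype")
  }
  data.frame(gene = toupper(df$gene), phenotype = df$phenotype,
             stringsAsFactors = FALSE)
}
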