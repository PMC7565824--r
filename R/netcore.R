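#' Read a STRING-dialect protein links table
#'
#' Reads a whitespace- or tab-separated table with per-channel scores
#' (integers 0--1000, or reals 0--1 which are auto-detected and scaled by
#' 1000). Rows are kept when the selected evidence channel is strictly
#' positive and the combined score passes the inclusive cutoff. Duplicate
#' unordered pairs (A--B vs B--A) collapse to a single edge, keeping the
#' highest combined score.
#'
#' @param path file path.
#' @param channel evidence channel column to require (default
#'   \code{"experimental"}).
#' @param min_score inclusive lower bound on \code{combined_score}
#'   (STRING default 400, i.e. 0.400).
#' @param cut_on apply the cutoff to the \code{"combined"} score (default,
#'   STRING UI semantics) or to the \code{"channel"} score itself.
#' @return data.frame with columns \code{protein1}, \code{protein2}, the
#'   channel column, and \code{combined_score}.
#' @export
read_string_links <- function(path, channel = "experimental",
                              min_score = 400L,
                              cut_on = c("combined", "channel")) {
  cut_on <- match.arg(cut_on)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  comb_col <- intersect(c("combined_score", "combined"), names(df))[1L]
  if (!channel %in% names(df)) {
    stopf("schema error: channel column '%s' not found (columns: %s)",
          channel, paste(names(df), collapse = ", "))
  }
  if (is.na(comb_col)) stopf("schema error: no combined_score column")
  score_cols <- names(df)[vapply(df, is.numeric, logical(1L))]
  if (length(score_cols) && max(unlist(df[score_cols]), na.rm = TRUE) <= 1) {
    df[score_cols] <- lapply(df[score_cols], function(x) round(x * 1000))
  }
  keep <- df[[channel]] > 0 & df[[comb_col]] >= min_score
  if (cut_on == "channel") keep <- df[[channel]] >= min_score
  df <- df[keep, , drop = FALSE]
  df$protein1 <- toupper(df$protein1)
  df$protein2 <- toupper(df$protein2)
  key <- paste(pmin(df$protein1, df$protein2), pmax(df$protein1, df$protein2))
  ord <- order(key, -df[[comb_col]])
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("protein1", "protein2", channel, comb_col)]
}

#' Build a gene network from a filtered edge table
#'
#' @param edges data.frame whose first two columns are gene symbols (e.g.
#'   from [read_string_links()]); a \code{combined_score} column, when
#'   present, becomes the edge weight (score / 1000).
#' @param restrict_to optional gene set; the result is the induced subgraph
#'   on those genes.
#' @param keep_seed_neighbors optional gene symbol; all its first neighbors
#'   (and itself) are retained even when outside \code{restrict_to},
#'   mirroring a seed-centred first-neighbor view.
#' @return undirected igraph with vertex attr \code{origin} (initially
#'   \code{"none"}) and edge attrs \code{weight}, \code{combined_score}.
#' @export
build_network <- function(edges, restrict_to = NULL, keep_seed_neighbors = NULL) {
  if (NROW(edges) == 0L) stopf("edge table is empty")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if ("combined_score" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight <- igraph::E(g)$combined_score / 1000
  }
  g <- igraph::simplify(g, edge.attr.comb = "max")
  if (!is.null(restrict_to)) {
    keep <- intersect(igraph::V(g)$name, norm_symbols(restrict_to))
    if (!is.null(keep_seed_neighbors)) {
      seed <- toupper(keep_seed_neighbors)
      if (seed %in% igraph::V(g)$name) {
        nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, seed))]
        keep <- union(keep, c(seed, nb))
      }
    }
    g <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name, keep))
  }
  if (igraph::vcount(g) == 0L) stopf("resulting network is empty")
  if (!"origin" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$origin <- "none"
  }
  g
}

#' Label nodes by their ontology selection origin
#'
#' Each node is labelled \code{GO_only}, \code{HPO_only}, \code{both} or
#' \code{none} according to its membership in the two selection gene sets.
#'
#' @param net igraph gene network.
#' @param go,hpo gene sets selected from the GO and HPO namespaces.
#' @return the network with an updated \code{origin} vertex attribute; label
#'   counts are available via \code{table(igraph::V(net)$origin)}.
#' @export
annotate_origin <- function(net, go, hpo) {
  go <- norm_symbols(go)
  hpo <- norm_symbols(hpo)
  nm <- igraph::V(net)$name
  origin <- rep("none", length(nm))
  origin[nm %in% go & !(nm %in% hpo)] <- "GO_only"
  origin[nm %in% hpo & !(nm %in% go)] <- "HPO_only"
  origin[nm %in% go & nm %in% hpo] <- "both"
  igraph::V(net)$origin <- origin
  net
}

#' First neighbors of a gene
#'
#' @param net igraph gene network.
#' @param gene gene symbol, must be a node.
#' @return sorted character vector of directly interacting genes (the gene
#'   itself excluded).
#' @export
first_neighbors <- function(net, gene) {
  gene <- toupper(gene)
  if (!gene %in% igraph::V(net)$name) stopf("gene not in network: %s", gene)
  nb <- igraph::V(net)$name[as.integer(igraph::neighbors(net, gene))]
  sort(setdiff(unique(nb), gene))
}

#' Write a network as an edge list plus node attribute table
#'
#' @param net igraph gene network.
#' @param edges_path,nodes_path output TSV paths.
#' @return \code{edges_path}, invisibly.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  el <- igraph::as_edgelist(net)
  ed <- data.frame(gene1 = el[, 1L], gene2 = el[, 2L])
  if ("combined_score" %in% igraph::edge_attr_names(net)) {
    ed$combined_score <- igraph::E(net)$combined_score
  }
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nd <- data.frame(gene = igraph::V(net)$name,
                   origin = igraph::V(net)$origin,
                   degree = igraph::degree(net))
  utils::write.table(nd, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges_path)
}
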