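# Independent oracles used to validate the package's graph statistics and
# multiple-testing decisions. These deliberately avoid the code paths (and,
# where feasible, the algorithms) used by the implementation.

# Brute-force betweenness: enumerate every simple path per pair, keep the
# shortest ones, and accumulate interior-node fractions; normalize by
# 2 / ((N - 1)(N - 2)).
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  b <- stats::setNames(numeric(n), nm)
  if (n < 3L) return(b)
  for (s in seq_len(n - 1L)) {
    for (t in seq((s + 1L), n)) {
      paths <- suppressWarnings(igraph::all_simple_paths(g, from = s, to = t))
      if (length(paths) == 0L) next
      lens <- vapply(paths, length, integer(1L))
      sp <- paths[lens == min(lens)]
      interior <- unlist(lapply(sp, function(p) {
        v <- as.integer(p)
        nm[v[-c(1L, length(v))]]
      }))
      if (length(interior)) {
        tab <- table(interior)
        b[names(tab)] <- b[names(tab)] + as.numeric(tab) / length(sp)
      }
    }
  }
  b * 2 / ((n - 1) * (n - 2))
}

# Plain-R Floyd-Warshall unweighted distances.
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  dimnames(d) <- list(igraph::V(g)$name, igraph::V(g)$name)
  d
}

# Wasserman-Faust closeness from Floyd-Warshall distances.
oracle_closeness <- function(g) {
  d <- fw_distances(g)
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) return(0)
    (length(di) / sum(di)) * (length(di) / (n - 1))
  }, numeric(1L))
}

# Classic Benjamini-Hochberg step-up decision set at level alpha.
bh_stepup <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# Random named graph for property batteries.
rand_graph <- function(n, p = 0.35) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# Small named graph from an edge vector like c("A","B", "B","C").
mini_graph <- function(edges, isolates = character()) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolates)) g <- igraph::add_vertices(g, length(isolates),
                                                  name = isolates)
  g
}
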