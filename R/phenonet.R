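#' Propagate phenotype association over the gene network
#'
#' Random walk with restart from the uniform distribution over the
#' phenotype-associated genes, on the column-normalized unweighted adjacency
#' of the gene network. The stationary vector is the per-gene phenotype
#' relevance; it is non-negative and sums to 1, and genes in components
#' containing no seed get relevance 0.
#'
#' @param net igraph gene network.
#' @param pheno_genes genes associated with the phenotype (at least one must
#'   be a node of the network).
#' @param restart restart probability in (0, 1), default 0.7.
#' @param tol L1 convergence tolerance.
#' @return named numeric relevance vector over the network's genes.
#' @export
propagate_phenotype <- function(net, pheno_genes, restart = 0.7, tol = 1e-10) {
  nodes <- igraph::V(net)$name
  seeds <- intersect(norm_symbols(pheno_genes), nodes)
  if (length(seeds) == 0L) stopf("no phenotype-associated gene is in the network")
  W <- column_stochastic(net)
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  rwr_iterate(W, p0, restart, tol)
}

#' Combine differential-expression evidence with phenotype relevance
#'
#' Per-gene signed evidence z = qnorm(1 - p / 2) * sign(logFC) (genes absent
#' from the DGE table get z = 0), the propagated phenotype \code{relevance},
#' and their signed product \code{combined}. The active-subnetwork search
#' aggregates an unsigned transform of these (see
#' [find_active_subnetworks()]) so that coherently perturbed neighborhoods
#' score high regardless of the direction of regulation.
#'
#' @param dge data.frame from [dge_contrast()] or [load_dge_table()].
#' @param relevance named relevance vector from [propagate_phenotype()].
#' @return data.frame with columns \code{gene}, \code{z}, \code{relevance},
#'   \code{combined}.
#' @export
node_scores <- function(dge, relevance) {
  genes <- names(relevance)
  z <- stats::setNames(numeric(length(genes)), genes)
  hit <- intersect(genes, dge$gene)
  i <- match(hit, dge$gene)
  zi <- stats::qnorm(1 - dge$p[i] / 2) * sign(dge$logFC[i])
  zi[!is.finite(zi)] <- 0
  z[hit] <- zi
  data.frame(gene = genes, z = as.numeric(z),
             relevance = as.numeric(relevance),
             combined = as.numeric(z * relevance),
             stringsAsFactors = FALSE)
}

# greedy seed-and-extend over a node-weight vector; returns deduplicated
# index sets with their normalized scores S = sum(w) / sqrt(|S|).
# Growth is unconditional (best neighbor) up to min_size, then gated on
# score improvement: a subnetwork must reach min_size before the size
# penalty can veto further extension.
grow_subnetworks <- function(adj, w, min_size, max_size) {
  n <- length(w)
  seeds <- order(-w)[seq_len(max(1L, ceiling(0.1 * n)))]
  found <- list()
  seen <- character()
  for (s in seeds) {
    set <- s
    total <- w[s]
    score <- total
    repeat {
      if (length(set) >= max_size) break
      cand <- setdiff(unique(unlist(adj[set])), set)
      if (length(cand) == 0L) break
      gains <- (total + w[cand]) / sqrt(length(set) + 1)
      j <- which.max(gains)
      if (length(set) >= min_size && gains[j] <= score) break
      total <- total + w[cand[j]]
      score <- gains[j]
      set <- c(set, cand[j])
    }
    if (length(set) >= min_size && score > 0) {
      key <- paste(sort(set), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        found[[length(found) + 1L]] <- list(idx = sort(set), score = score)
      }
    }
  }
  found
}

#' Find active subnetworks by greedy search with a permutation null
#'
#' Starting from each top-decile node by evidence weight
#' |z| * rank01(relevance) (the min-max-scaled relevance rank damps the
#' exponential decay of RWR probabilities with network distance), greedily
#' adds the neighbor that
#' maximizes the normalized subnetwork score S = (sum of weights) /
#' sqrt(size): growth is unconditional up to \code{min_size}, then continues
#' only while S increases, up to \code{max_size}. Significance is assessed
#' against a max-statistic permutation null:
#' for each permutation the z column is shuffled across nodes (relevance and
#' the network held fixed), the search is re-run, and the best score found is
#' recorded; a subnetwork's empirical p is the fraction of permutations whose
#' best score reaches its own. Retained subnetworks (empirical p < alpha)
#' with Jaccard overlap > 0.5 are merged.
#'
#' @param net igraph gene network.
#' @param scores data.frame from [node_scores()]; must cover all nodes.
#' @param min_size,max_size subnetwork size bounds (defaults 3 and 30).
#' @param n_perm number of permutations (default 1000; below 100 the
#'   empirical p is unstable and a warning is raised).
#' @param alpha retention level on the empirical p (default 0.05).
#' @param rng_seed integer seed for the permutations.
#' @return list of subnetworks, each a list with \code{genes}, \code{score},
#'   \code{empirical_p}, ordered by decreasing score.
#' @export
find_active_subnetworks <- function(net, scores, min_size = 3L, max_size = 30L,
                                    n_perm = 1000L, alpha = 0.05,
                                    rng_seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: empirical p-values are unstable")
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% scores$gene)) {
    stopf("scores must cover all network nodes (%d missing)",
          sum(!nodes %in% scores$gene))
  }
  i <- match(nodes, scores$gene)
  z <- scores$z[i]
  relevance <- scores$relevance[i]
  # Gate the DE evidence by the relevance *rank* rather than the raw RWR
  # probability: raw probabilities decay exponentially with distance from
  # the phenotype genes, so used directly the phenotype gene alone would
  # carry every subnetwork score (killing both recovery and permutation
  # power). The ordinal transform keeps phenotype proximity as a soft gate
  # while letting every perturbed member contribute comparably.
  rr <- rank(relevance, ties.method = "average")
  rel_rank <- if (max(rr) == min(rr)) rep(0.5, length(rr)) else {
    (rr - min(rr)) / (max(rr) - min(rr))
  }
  weight_of <- function(zv) abs(zv) * rel_rank
  w <- weight_of(z)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  obs <- grow_subnetworks(adj, w, min_size, max_size)
  if (length(obs) == 0L) return(list())

  null_max <- with_rng(rng_seed, {
    vapply(seq_len(n_perm), function(b) {
      wp <- weight_of(z[sample.int(length(z))])
      hits <- grow_subnetworks(adj, wp, min_size, max_size)
      if (length(hits) == 0L) 0
      else max(vapply(hits, `[[`, numeric(1L), "score"))
    }, numeric(1L))
  })
  subnets <- lapply(obs, function(s) {
    list(genes = nodes[s$idx], score = s$score,
         empirical_p = (1 + sum(null_max >= s$score)) / (n_perm + 1))
  })
  subnets <- Filter(function(s) s$empirical_p < alpha, subnets)

  # merge heavily overlapping results
  repeat {
    merged <- FALSE
    if (length(subnets) < 2L) break
    for (a in seq_len(length(subnets) - 1L)) {
      for (b in seq((a + 1L), length(subnets))) {
        ga <- subnets[[a]]$genes; gb <- subnets[[b]]$genes
        jac <- length(intersect(ga, gb)) / length(union(ga, gb))
        if (jac > 0.5) {
          genes <- sort(union(ga, gb))
          subnets[[a]] <- list(
            genes = genes,
            score = sum(w[match(genes, nodes)]) / sqrt(length(genes)),
            empirical_p = min(subnets[[a]]$empirical_p,
                              subnets[[b]]$empirical_p))
          subnets[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  subnets[order(-vapply(subnets, `[[`, numeric(1L), "score"))]
}

#' Expression-derived modifier candidates
#'
#' Genes satisfying all three of: significantly differentially expressed,
#' member of a retained active subnetwork, and first neighbor of the seed
#' (disease) gene. This is the rule by which a direct interactor with
#' perturbation-responsive expression joins the network-statistics
#' candidates.
#'
#' @param dge data.frame from [dge_contrast()] or [load_dge_table()].
#' @param net igraph gene network.
#' @param seed_gene the disease gene symbol (must be a node).
#' @param subnets list of subnetworks from [find_active_subnetworks()].
#' @param alpha FDR level for the significance condition.
#' @return data.frame with columns \code{gene}, \code{logFC}, \code{q},
#'   \code{subnetwork} (index of the first containing subnetwork).
#' @export
expression_candidates <- function(dge, net, seed_gene, subnets, alpha = 0.05) {
  seed_gene <- toupper(seed_gene)
  if (!seed_gene %in% igraph::V(net)$name) {
    stopf("seed gene not in network: %s", seed_gene)
  }
  sig <- dge$gene[dge$q < alpha]
  members <- unique(unlist(lapply(subnets, `[[`, "genes")))
  nbrs <- first_neighbors(net, seed_gene)
  hits <- sort(intersect(intersect(sig, members), nbrs))
  sub_idx <- vapply(hits, function(g) {
    which(vapply(subnets, function(s) g %in% s$genes, logical(1L)))[1L]
  }, integer(1L))
  i <- match(hits, dge$gene)
  data.frame(gene = hits, logFC = dge$logFC[i], q = dge$q[i],
             subnetwork = as.integer(sub_idx),
             stringsAsFactors = FALSE, row.names = NULL)
}
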