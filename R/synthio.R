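#' Generate a synthetic PPI network with planted modifier structure
#'
#' Builds an undirected, connected gene network made of preferential-attachment
#' communities that are joined only through designated bridge nodes, and plants
#' the two kinds of structure the downstream selection stages are meant to
#' find: modifier genes that are direct neighbors of a designated seed
#' (disease) gene, and bridge modifiers that are each the unique connector
#' between two communities, so their betweenness dominates their communities'
#' by construction.
#'
#' Edge scores mimic the STRING experimental channel: each edge carries an
#' integer \code{combined_score} in 700--999 (weight = score / 1000) and an
#' identical \code{experimental} channel score.
#'
#' @param n_genes total number of genes (nodes), including bridge nodes.
#' @param n_communities number of preferential-attachment communities.
#' @param attach edges added per new vertex during preferential attachment;
#'   also the number of anchor nodes a bridge attaches to on each side.
#' @param n_neighbor_mods number of planted modifier genes adjacent to the seed.
#' @param n_bridge_mods number of planted bridge modifiers; must be at least
#'   \code{n_communities - 1} (so the graph is connected) and at most
#'   \code{choose(n_communities, 2)} (so each bridge is the unique connector
#'   of its community pair).
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return list with \code{network} (igraph; vertex attrs \code{name},
#'   \code{community}, \code{origin}; edge attrs \code{weight},
#'   \code{combined_score}, \code{experimental}) and \code{truth}, a
#'   \code{truth_manifest} list: \code{seed_gene}, \code{neighbor_modifiers},
#'   \code{bridge_modifiers}, \code{de_genes}, \code{effect_log2},
#'   \code{phenotype_id}, \code{modifier_overlap}.
#' @export
gen_ppi_network <- function(n_genes, n_communities = 2L, attach = 2L,
                            n_neighbor_mods = 2L, n_bridge_mods = 1L,
                            rng_seed = 1L) {
  if (attach < 1L) stopf("sizing error: attach must be >= 1")
  if (n_genes < 3L * n_communities) {
    stopf("sizing error: n_genes (%d) must be >= 3 * n_communities (%d)",
          n_genes, n_communities)
  }
  if (n_bridge_mods < n_communities - 1L) {
    stopf("sizing error: need at least %d bridge modifiers to connect %d communities",
          n_communities - 1L, n_communities)
  }
  if (n_bridge_mods > choose(n_communities, 2L)) {
    stopf("sizing error: at most %d bridge modifiers fit %d communities",
          choose(n_communities, 2L), n_communities)
  }
  n_core <- n_genes - n_bridge_mods
  sizes <- rep(n_core %/% n_communities, n_communities)
  extra <- n_core %% n_communities
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 3L)) stopf("sizing error: a community would have < 3 genes")
  if (n_neighbor_mods > sizes[1L] - 1L) {
    stopf("sizing error: %d neighbor modifiers do not fit a community of %d genes",
          n_neighbor_mods, sizes[1L])
  }

  with_rng(rng_seed, {
    comms <- lapply(sizes, function(s) {
      igraph::sample_pa(s, power = 1, m = attach, directed = FALSE)
    })
    g <- do.call(igraph::disjoint_union, comms)
    membership <- rep(seq_len(n_communities), sizes)
    core_names <- sprintf("G%04d", seq_len(n_core))
    bridge_names <- sprintf("G%04d", n_core + seq_len(n_bridge_mods))
    igraph::V(g)$name <- core_names

    # seed gene: the hub (highest-degree node) of community 1
    in_c1 <- which(membership == 1L)
    deg <- igraph::degree(g)
    seed_gene <- core_names[in_c1[which.max(deg[in_c1])]]

    # neighbor modifiers: random community-1 genes wired to the seed
    pool <- setdiff(core_names[in_c1], seed_gene)
    neighbor_mods <- sort(sample_exact(pool, n_neighbor_mods))
    need <- !vapply(neighbor_mods, function(m) {
      igraph::are_adjacent(g, seed_gene, m)
    }, logical(1L))
    if (any(need)) {
      g <- igraph::add_edges(g, as.vector(rbind(seed_gene, neighbor_mods[need])))
    }

    # bridge modifiers: one per community pair, chain pairs first so the
    # graph is connected, each anchored to `attach` nodes on either side
    pairs <- cbind(seq_len(n_communities - 1L), seq_len(n_communities - 1L) + 1L)
    if (n_bridge_mods > nrow(pairs)) {
      all_pairs <- t(utils::combn(n_communities, 2L))
      key <- function(m) paste(m[, 1L], m[, 2L])
      rest <- all_pairs[!key(all_pairs) %in% key(pairs), , drop = FALSE]
      pairs <- rbind(pairs, rest[seq_len(n_bridge_mods - nrow(pairs)), , drop = FALSE])
    } else {
      pairs <- pairs[seq_len(n_bridge_mods), , drop = FALSE]
    }
    g <- igraph::add_vertices(g, n_bridge_mods, name = bridge_names)
    membership <- c(membership, rep(NA_integer_, n_bridge_mods))
    for (b in seq_len(n_bridge_mods)) {
      for (side in pairs[b, ]) {
        anchors <- sample_exact(core_names[membership[seq_len(n_core)] == side],
                                min(attach, sizes[side]))
        g <- igraph::add_edges(g, as.vector(rbind(bridge_names[b], unique(anchors))))
      }
    }
    g <- igraph::simplify(g)

    m <- igraph::ecount(g)
    score <- sample(700:999, m, replace = TRUE)
    igraph::E(g)$combined_score <- score
    igraph::E(g)$experimental <- score
    igraph::E(g)$weight <- score / 1000
    igraph::V(g)$community <- membership[match(igraph::V(g)$name,
                                               c(core_names, bridge_names))]
    igraph::V(g)$origin <- "none"

    truth <- structure(list(
      seed_gene = seed_gene,
      neighbor_modifiers = neighbor_mods,
      bridge_modifiers = bridge_names,
      de_genes = neighbor_mods,
      effect_log2 = 2,
      phenotype_id = "OMIM:162200",
      modifier_overlap = intersect(neighbor_mods, bridge_names)
    ), class = "truth_manifest")

    list(network = g, truth = truth)
  })
}

#' Generate a synthetic annotation namespace over a network's genes
#'
#' Draws \code{n_terms} terms of \code{genes_per_term} genes each from the
#' network's node set so that, when called once per namespace (\code{GO_BP}
#' and \code{HPO}) with the same \code{rng_seed} and \code{shared_fraction},
#' the Jaccard overlap of the two namespaces' gene unions equals
#' \code{shared_fraction} up to integer rounding. Each namespace's union has
#' size \code{u = min(floor(N (1 + f) / 2), n_terms * genes_per_term)} with a
#' shared block of \code{s = round(2 u f / (1 + f))} genes common to both.
#'
#' @param network igraph gene network.
#' @param namespace \code{"GO_BP"} or \code{"HPO"}.
#' @param n_terms,genes_per_term term count and term size.
#' @param shared_fraction target Jaccard overlap between the two namespaces'
#'   gene unions, in [0, 1].
#' @param rng_seed integer seed (use the same seed for both namespaces).
#' @param include optional genes forced into the shared block (hence into both
#'   unions), e.g. a disease gene and its planted modifiers; perturbs the
#'   exact overlap slightly.
#' @return an \code{annotation_set} (see [annotation_set()]).
#' @export
gen_annotations <- function(network, namespace = c("GO_BP", "HPO"),
                            n_terms, genes_per_term, shared_fraction,
                            rng_seed = 1L, include = NULL) {
  namespace <- match.arg(namespace)
  nodes <- sort(igraph::V(network)$name)
  n <- length(nodes)
  if (n == 0L) stopf("empty network")
  if (genes_per_term > n) stopf("genes_per_term (%d) exceeds node count (%d)",
                                genes_per_term, n)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stopf("shared_fraction must be in [0, 1]")
  }
  f <- shared_fraction
  u <- min(floor(n * (1 + f) / 2), n_terms * genes_per_term)
  u <- max(u, genes_per_term)
  s <- min(round(2 * u * f / (1 + f)), u)

  # pools are a function of rng_seed only, so both namespaces agree on them
  shuffled <- with_rng(rng_seed, sample(nodes))
  forced <- intersect(norm_symbols(include), nodes)
  shuffled <- c(forced, setdiff(shuffled, forced))
  s <- max(s, length(forced))
  shared_block <- shuffled[seq_len(s)]
  rest <- shuffled[setdiff(seq_len(n), seq_len(s))]
  private_pool <- if (namespace == "GO_BP") {
    rest[seq_along(rest) %% 2L == 1L]
  } else {
    rest[seq_along(rest) %% 2L == 0L]
  }
  n_private <- min(u - s, length(private_pool))
  union_genes <- c(shared_block, private_pool[seq_len(n_private)])

  ns_offset <- if (namespace == "GO_BP") 1L else 2L
  terms <- with_rng(rng_seed + ns_offset, {
    # round-robin coverage of the union, then fill terms up to size
    assigned <- split(sample(union_genes),
                      rep_len(seq_len(n_terms), length(union_genes)))
    lapply(seq_len(n_terms), function(i) {
      have <- assigned[[as.character(i)]] %||% character()
      short <- genes_per_term - length(have)
      if (short > 0L) {
        have <- c(have, sample_exact(setdiff(union_genes, have), short))
      }
      sort(have[seq_len(genes_per_term)])
    })
  })
  ids <- if (namespace == "GO_BP") {
    sprintf("GO:%07d", seq_len(n_terms))
  } else {
    sprintf("HP:%07d", seq_len(n_terms))
  }
  names(terms) <- ids
  annotation_set(namespace, terms, source = "synthetic")
}

#' Generate a synthetic two-group expression experiment
#'
#' Simulates a log2-scale expression matrix for a control group and a
#' knockdown group with Gaussian noise. Genes in \code{truth$de_genes} get a
#' planted group-mean difference of \code{truth$effect_log2} (knockdown minus
#' control), and the seed gene itself is shifted down by the same amount in
#' the knockdown group, emulating loss of the disease gene.
#'
#' @param network igraph gene network (defines the gene universe).
#' @param truth a \code{truth_manifest} from [gen_ppi_network()].
#' @param n_per_group samples per group (>= 2).
#' @param sigma Gaussian noise standard deviation on the log2 scale (> 0).
#' @param rng_seed integer seed.
#' @return list with \code{expr} (genes x 2*n_per_group matrix, log2 scale)
#'   and \code{groups} (character vector, "control"/"knockdown").
#' @export
gen_expression <- function(network, truth, n_per_group = 5L, sigma = 0.5,
                           rng_seed = 1L) {
  if (sigma <= 0) stopf("sigma must be > 0")
  if (n_per_group < 2L) stopf("n_per_group must be >= 2")
  genes <- igraph::V(network)$name
  n_s <- 2L * n_per_group
  with_rng(rng_seed, {
    baseline <- stats::runif(length(genes), 5, 10)
    expr <- matrix(stats::rnorm(length(genes) * n_s, mean = baseline, sd = sigma),
                   nrow = length(genes), ncol = n_s)
    rownames(expr) <- genes
    colnames(expr) <- c(sprintf("ctrl_%02d", seq_len(n_per_group)),
                        sprintf("kd_%02d", seq_len(n_per_group)))
    kd <- n_per_group + seq_len(n_per_group)
    de <- setdiff(intersect(truth$de_genes, genes), truth$seed_gene)
    expr[de, kd] <- expr[de, kd] + truth$effect_log2
    if (truth$seed_gene %in% genes) {
      expr[truth$seed_gene, kd] <- expr[truth$seed_gene, kd] - truth$effect_log2
    }
    list(expr = expr,
         groups = rep(c("control", "knockdown"), each = n_per_group))
  })
}

#' Generate bipartite gene-phenotype links with decoy phenotypes
#'
#' Always contains the link between the seed gene and the true phenotype node
#' (\code{truth$phenotype_id}); adds \code{n_extra_links} links from random
#' genes to distinct decoy phenotype nodes.
#'
#' @param network igraph gene network.
#' @param truth a \code{truth_manifest}.
#' @param n_extra_links number of decoy links to add.
#' @param rng_seed integer seed.
#' @return data.frame with columns \code{gene}, \code{phenotype}.
#' @export
gen_pheno_links <- function(network, truth, n_extra_links = 0L, rng_seed = 1L) {
  genes <- igraph::V(network)$name
  if (length(genes) == 0L) stopf("empty network")
  links <- data.frame(gene = truth$seed_gene,
                      phenotype = truth$phenotype_id,
                      stringsAsFactors = FALSE)
  if (n_extra_links > 0L) {
    extra <- with_rng(rng_seed, data.frame(
      gene = sample(genes, n_extra_links, replace = TRUE),
      phenotype = sprintf("HP:%07d", 9000000L + seq_len(n_extra_links)),
      stringsAsFactors = FALSE
    ))
    links <- rbind(links, extra)
  }
  links
}

#' Writers for the synthetic study bundle
#'
#' Serialize synthetic objects in the external dialects the readers consume:
#' STRING-style protein links, GAF 2.2, HPO genes_to_phenotype, expression
#' TSV plus group labels, and a JSON truth manifest.
#'
#' @param network,ann,expr,groups,truth,links objects produced by the
#'   generators in this module.
#' @param path output file path (\code{write_expression} also takes
#'   \code{groups_path}).
#' @param groups_path output path for the sample-to-group table.
#' @return the output path, invisibly.
#' @name synthio-writers
NULL

#' @rdname synthio-writers
#' @export
write_string_links <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(protein1 = el[, 1L], protein2 = el[, 2L],
                   experimental = igraph::E(network)$experimental,
                   combined_score = igraph::E(network)$combined_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthio-writers
#' @export
write_gaf <- function(ann, path) {
  lines <- c("!gaf-version: 2.2", "!generated by modnet (synthetic)")
  for (term in names(ann$terms)) {
    for (g in ann$terms[[term]]) {
      row <- c("MODNET", g, g, "involved_in", term, "MODNET:0001", "IEA", "",
               "P", g, "", "protein", "taxon:9606", "20200826", "MODNET")
      lines <- c(lines, paste(row, collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname synthio-writers
#' @export
write_hpo_assoc <- function(ann, path) {
  rows <- do.call(rbind, lapply(names(ann$terms), function(term) {
    data.frame(ncbi_gene_id = 0L, gene_symbol = ann$terms[[term]],
               hpo_id = term, hpo_name = paste("synthetic phenotype", term),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthio-writers
#' @export
write_expression <- function(expr, groups, path, groups_path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(expr), group = groups),
                     groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthio-writers
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname synthio-writers
#' @export
write_pheno_links <- function(links, path) {
  utils::write.table(links, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
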