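test_that("phenotype propagation matches closed forms and conserves mass", {
  ab <- mini_graph(c("A", "B"))
  rel <- propagate_phenotype(ab, "A", restart = 0.7)
  expect_equal(unname(rel), c(1 / 1.3, 0.3 / 1.3), tolerance = 1e-8)

  # restart -> 1 limit: relevance approaches the seed distribution
  rel99 <- propagate_phenotype(ab, "A", restart = 0.999)
  expect_gt(rel99[["A"]], 0.998)

  # components without seeds get zero relevance
  g <- mini_graph(c("A", "B", "C", "D"))
  rel2 <- propagate_phenotype(g, "A")
  expect_equal(unname(rel2[c("C", "D")]), c(0, 0))
  expect_equal(sum(rel2), 1)

  set.seed(5)
  for (i in 1:10) {
    g <- rand_graph(12, 0.3)
    rel <- propagate_phenotype(g, igraph::V(g)$name[1:2])
    expect_true(all(rel >= 0))
    expect_equal(sum(rel), 1, tolerance = 1e-9)
  }
  expect_error(propagate_phenotype(ab, "ZZ"), "no phenotype")
})

test_that("node scores combine signed DGE evidence with relevance", {
  dge <- data.frame(gene = c("A", "B"), logFC = c(2, -1),
                    p = c(0.01, 0.5), q = c(0.02, 0.5),
                    significant = c(TRUE, FALSE))
  rel <- c(A = 0.5, B = 0.3, C = 0.2)
  sc <- node_scores(dge, rel)
  expect_equal(sc$z[sc$gene == "A"], stats::qnorm(1 - 0.01 / 2))
  expect_equal(sc$z[sc$gene == "B"], -stats::qnorm(1 - 0.5 / 2))
  expect_equal(sc$z[sc$gene == "C"], 0)
  expect_equal(sc$combined, sc$z * sc$relevance)
})

test_that("no active subnetwork survives on zero evidence", {
  g <- rand_graph(20, 0.3)
  sc <- data.frame(gene = igraph::V(g)$name, z = 0,
                   relevance = 1 / 20, combined = 0)
  expect_warning(out <- find_active_subnetworks(g, sc, n_perm = 50,
                                                rng_seed = 1),
                 "unstable")
  expect_length(out, 0)
})

test_that("a planted perturbed module is recovered around the seed gene", {
  sim <- gen_ppi_network(50, 2, 2, 4, 1, rng_seed = 13)
  g <- sim$network
  tr <- sim$truth
  ex <- gen_expression(g, tr, 5, 0.5, rng_seed = 14)
  dge <- dge_contrast(ex$expr, ex$groups)
  rel <- propagate_phenotype(g, tr$seed_gene)
  sc <- node_scores(dge, rel)
  sn <- find_active_subnetworks(g, sc, n_perm = 199, rng_seed = 15)
  expect_gt(length(sn), 0)
  truth_mod <- c(tr$seed_gene, tr$neighbor_modifiers)
  jac <- length(intersect(sn[[1]]$genes, truth_mod)) /
    length(union(sn[[1]]$genes, truth_mod))
  expect_gte(jac, 0.6)
  expect_lt(sn[[1]]$empirical_p, 0.05)
  # subnetworks induce connected subgraphs within the size bounds
  for (s in sn) {
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, s$genes)))
    expect_gte(length(s$genes), 3)
    expect_lte(length(s$genes), 30)
  }
})

test_that("subnetwork scores are invariant to node relabeling", {
  sim <- gen_ppi_network(30, 2, 2, 2, 1, rng_seed = 21)
  g <- sim$network
  ex <- gen_expression(g, sim$truth, 5, 0.5, rng_seed = 22)
  dge <- dge_contrast(ex$expr, ex$groups)
  rel <- propagate_phenotype(g, sim$truth$seed_gene)
  sc <- node_scores(dge, rel)
  sn <- find_active_subnetworks(g, sc, n_perm = 120, rng_seed = 23)

  # apply a symbol permutation to graph and scores alike
  old <- igraph::V(g)$name
  new <- paste0("X", rev(old))
  map <- stats::setNames(new, old)
  g2 <- g
  igraph::V(g2)$name <- unname(map[old])
  sc2 <- sc
  sc2$gene <- unname(map[sc$gene])
  sn2 <- find_active_subnetworks(g2, sc2, n_perm = 120, rng_seed = 23)
  expect_equal(vapply(sn, `[[`, numeric(1), "score"),
               vapply(sn2, `[[`, numeric(1), "score"), tolerance = 1e-9)
  expect_equal(lapply(sn, function(s) sort(unname(map[s$genes]))),
               lapply(sn2, function(s) sort(s$genes)))
})

test_that("expression-derived candidates require all three evidence types", {
  # seed S with neighbors X (DE) and Y (not DE); Z is DE but far from S
  g <- mini_graph(c("S", "X", "S", "Y", "Y", "Z", "X", "Y"))
  dge <- data.frame(gene = c("S", "X", "Y", "Z"),
                    logFC = c(-2, 2, 0.1, 2),
                    p = c(1e-4, 1e-4, 0.9, 1e-4),
                    q = c(4e-4, 4e-4, 0.9, 4e-4),
                    significant = c(TRUE, TRUE, FALSE, TRUE))
  subnets <- list(list(genes = c("S", "X", "Y"), score = 3, empirical_p = 0.01))
  out <- expression_candidates(dge, g, "S", subnets)
  expect_equal(out$gene, "X")
  expect_equal(out$subnetwork, 1L)
  # Z is significant but not adjacent to the seed, and not in a subnetwork
  out2 <- expression_candidates(dge, g, "S",
                                list(list(genes = c("Y", "Z", "X"),
                                          score = 1, empirical_p = 0.01)))
  expect_false("Z" %in% out2$gene)
  expect_error(expression_candidates(dge, g, "Q", subnets), "seed gene")
})
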