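test_that("generated PPI network carries the planted structure", {
  sim <- gen_ppi_network(50, n_communities = 2, attach = 2,
                         n_neighbor_mods = 2, n_bridge_mods = 1, rng_seed = 7)
  g <- sim$network
  tr <- sim$truth
  expect_equal(igraph::vcount(g), 50)
  expect_true(igraph::is_connected(g))
  expect_false(igraph::any_loop(g))
  expect_false(igraph::any_multiple(g))
  expect_length(tr$neighbor_modifiers, 2)
  expect_length(tr$bridge_modifiers, 1)
  nb <- first_neighbors(g, tr$seed_gene)
  expect_true(all(tr$neighbor_modifiers %in% nb))
  expect_true(all(tr$de_genes %in% igraph::V(g)$name))
  expect_true(all(igraph::E(g)$weight >= 0 & igraph::E(g)$weight <= 1))
})

test_that("network generation is a pure function of its seed", {
  a <- gen_ppi_network(50, 2, 2, 2, 1, rng_seed = 7)
  b <- gen_ppi_network(50, 2, 2, 2, 1, rng_seed = 7)
  expect_identical(igraph::as_edgelist(a$network), igraph::as_edgelist(b$network))
  expect_identical(igraph::E(a$network)$combined_score,
                   igraph::E(b$network)$combined_score)
  expect_identical(a$truth, b$truth)
  d <- gen_ppi_network(50, 2, 2, 2, 1, rng_seed = 8)
  expect_false(identical(igraph::as_edgelist(a$network),
                         igraph::as_edgelist(d$network)))
  # the caller's RNG stream is untouched
  set.seed(123); x1 <- stats::runif(1)
  set.seed(123); invisible(gen_ppi_network(30, 2, 2, 1, 1, rng_seed = 3))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("bridge modifiers dominate betweenness in their communities", {
  # betweenness_centrality itself is validated against the brute-force
  # oracle elsewhere; here it probes the planted contrast on several seeds
  for (s in c(7, 11, 23)) {
    sim <- gen_ppi_network(50, 2, 2, 2, 1, rng_seed = s)
    b <- betweenness_centrality(sim$network)
    bridge <- sim$truth$bridge_modifiers
    expect_gte(b[bridge], max(b[setdiff(names(b), bridge)]))
  }
})

test_that("infeasible sizing requests are rejected", {
  expect_error(gen_ppi_network(5, 2, 2, 2, 1, rng_seed = 1), "sizing")
  expect_error(gen_ppi_network(50, 2, 0, 2, 1, rng_seed = 1), "sizing")
  expect_error(gen_ppi_network(50, 3, 2, 2, 1, rng_seed = 1), "sizing")
  expect_error(gen_ppi_network(50, 2, 2, 40, 1, rng_seed = 1), "sizing")
})

test_that("annotation namespaces have controllable overlap", {
  sim <- gen_ppi_network(50, 2, 2, 2, 1, rng_seed = 7)
  g <- sim$network
  go <- gen_annotations(g, "GO_BP", n_terms = 5, genes_per_term = 10,
                        shared_fraction = 0.5, rng_seed = 1)
  expect_length(go$terms, 5)
  expect_true(all(vapply(go$terms, length, integer(1)) == 10))

  union_of <- function(ann) sort(unique(unlist(ann$terms)))
  for (f in c(0, 0.5, 1)) {
    a <- gen_annotations(g, "GO_BP", 5, 10, f, rng_seed = 1)
    b <- gen_annotations(g, "HPO", 5, 10, f, rng_seed = 1)
    ua <- union_of(a); ub <- union_of(b)
    jac <- length(intersect(ua, ub)) / length(union(ua, ub))
    if (f == 1) expect_identical(ua, ub)
    else if (f == 0) expect_length(intersect(ua, ub), 0)
    else expect_lt(abs(jac - f), 0.1)
  }
  expect_error(gen_annotations(igraph::make_empty_graph(0), "GO_BP", 2, 2, 0.5, 1),
               "empty")
})

test_that("forced include genes appear in both namespace unions", {
  sim <- gen_ppi_network(50, 2, 2, 2, 1, rng_seed = 7)
  keep <- c(sim$truth$seed_gene, sim$truth$neighbor_modifiers)
  for (ns in c("GO_BP", "HPO")) {
    ann <- gen_annotations(sim$network, ns, 5, 10, 0.5, rng_seed = 1,
                           include = keep)
    expect_true(all(keep %in% unlist(ann$terms)))
  }
})

test_that("expression simulation plants the requested effects", {
  sim <- gen_ppi_network(50, 2, 2, 2, 1, rng_seed = 7)
  tr <- sim$truth
  ex <- gen_expression(sim$network, tr, n_per_group = 5, sigma = 0.5,
                       rng_seed = 3)
  expect_equal(dim(ex$expr), c(50, 10))
  expect_equal(ex$groups, rep(c("control", "knockdown"), each = 5))
  kd <- ex$groups == "knockdown"
  # seed gene is down-shifted in the knockdown group
  expect_lt(mean(ex$expr[tr$seed_gene, kd]) - mean(ex$expr[tr$seed_gene, !kd]), 0)

  # null model: with no planted effects the mean |logFC| vanishes at large n
  tr0 <- tr; tr0$de_genes <- character(0); tr0$effect_log2 <- 0
  big <- gen_expression(sim$network, tr0, n_per_group = 500, sigma = 0.5,
                        rng_seed = 4)
  kd <- big$groups == "knockdown"
  lfc <- rowMeans(big$expr[, kd]) - rowMeans(big$expr[, !kd])
  expect_lt(mean(abs(lfc)), 0.1)

  # planted effect: sample logFC lands in 2 +/- 1 in >= 95/100 simulations
  # (normal theory: sd(logFC) = sigma * sqrt(2/5) ~ 0.32, so ~3 sd)
  hit <- 0
  for (s in 1:100) {
    e <- gen_expression(sim$network, tr, n_per_group = 5, sigma = 0.5,
                        rng_seed = 100 + s)
    kd <- e$groups == "knockdown"
    lfc <- rowMeans(e$expr[tr$de_genes, kd, drop = FALSE]) -
      rowMeans(e$expr[tr$de_genes, !kd, drop = FALSE])
    hit <- hit + all(abs(lfc - 2) < 1)
  }
  expect_gte(hit, 95)
  expect_error(gen_expression(sim$network, tr, 5, sigma = 0), "sigma")
  expect_error(gen_expression(sim$network, tr, 1, sigma = 0.5), "n_per_group")
})

test_that("phenotype links always include the seed-phenotype edge", {
  sim <- gen_ppi_network(30, 2, 2, 1, 1, rng_seed = 2)
  l0 <- gen_pheno_links(sim$network, sim$truth, 0, rng_seed = 1)
  expect_equal(nrow(l0), 1)
  expect_equal(l0$gene, sim$truth$seed_gene)
  expect_equal(l0$phenotype, sim$truth$phenotype_id)
  l5 <- gen_pheno_links(sim$network, sim$truth, 5, rng_seed = 1)
  expect_equal(nrow(l5), 6)
  expect_identical(l5, gen_pheno_links(sim$network, sim$truth, 5, rng_seed = 1))
})

test_that("the synthetic bundle round-trips through its file dialects", {
  dir <- withr::local_tempdir()
  sim <- gen_ppi_network(30, 2, 2, 1, 1, rng_seed = 5)
  ann <- gen_annotations(sim$network, "GO_BP", 3, 5, 0.5, rng_seed = 1)
  hpo <- gen_annotations(sim$network, "HPO", 3, 5, 0.5, rng_seed = 1)
  ex <- gen_expression(sim$network, sim$truth, 3, 0.5, rng_seed = 1)

  write_string_links(sim$network, file.path(dir, "links.tsv"))
  edges <- read_string_links(file.path(dir, "links.tsv"))
  g2 <- build_network(edges)
  expect_true(igraph::is_isomorphic_to(sim$network, g2))
  expect_setequal(igraph::V(g2)$name, igraph::V(sim$network)$name)

  write_gaf(ann, file.path(dir, "go.gaf"))
  expect_equal(read_gaf(file.path(dir, "go.gaf"))$terms, ann$terms)
  write_hpo_assoc(hpo, file.path(dir, "hpo.tsv"))
  expect_equal(read_hpo_assoc(file.path(dir, "hpo.tsv"))$terms, hpo$terms)

  write_expression(ex$expr, ex$groups, file.path(dir, "expr.tsv"),
                   file.path(dir, "groups.tsv"))
  back <- utils::read.delim(file.path(dir, "expr.tsv"), check.names = FALSE)
  m <- as.matrix(back[-1]); rownames(m) <- back[[1]]
  expect_equal(m, ex$expr, tolerance = 1e-8)
})
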