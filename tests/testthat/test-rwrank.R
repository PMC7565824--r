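toy_hetero <- function() {
  # gene triangle A-B, A-C plus phenotype P linked to A
  g <- mini_graph(c("A", "B", "A", "C"))
  build_hetero(g, data.frame(gene = "A", phenotype = "P"), jump = 0.5)
}

test_that("supra-transition matrix follows the layer-jump rule", {
  # single gene, single phenotype, one link: off-diagonals are 1
  g1 <- mini_graph(character(), isolates = "A")
  h1 <- build_hetero(g1, data.frame(gene = "A", phenotype = "P"))
  W <- as.matrix(h1$W)
  expect_equal(W, matrix(c(0, 1, 1, 0), 2, 2,
                         dimnames = list(c("A", "P"), c("A", "P"))))

  # gene with two within-layer neighbors and one link, jump 0.5
  h <- toy_hetero()
  colA <- as.numeric(h$W[, "A"])
  expect_equal(stats::setNames(colA, rownames(h$W)),
               c(A = 0, B = 0.25, C = 0.25, P = 0.5))
  expect_equal(unname(Matrix::colSums(h$W)), rep(1, 4))

  # column-stochastic on random instances
  for (s in 1:10) {
    set.seed(s)
    g <- rand_graph(10, 0.3)
    g <- igraph::add_edges(g, c(rbind(sprintf("N%02d", 1:9),
                                      sprintf("N%02d", 2:10))))
    g <- igraph::simplify(g)
    links <- data.frame(gene = sprintf("N%02d", sample(10, 3)),
                        phenotype = c("P1", "P1", "P2"))
    h <- build_hetero(g, links)
    expect_equal(unname(Matrix::colSums(h$W)), rep(1, nrow(h$W)),
                 tolerance = 1e-12)
  }
  expect_error(build_hetero(mini_graph(c("A", "B")),
                            data.frame(gene = "Z", phenotype = "P")),
               "dangling")
  expect_error(build_hetero(mini_graph(c("A", "B")),
                            data.frame(gene = character(),
                                       phenotype = character())),
               "empty")
})

test_that("RWR scores solve the restart fixed point", {
  # two-node closed form (single gene - single phenotype, restart 0.7)
  g1 <- mini_graph(character(), isolates = "A")
  h1 <- build_hetero(g1, data.frame(gene = "A", phenotype = "P"),
                     restart = 0.7)
  p <- rwr_scores(h1, "A")
  expect_equal(unname(p), c(1 / 1.3, 0.3 / 1.3), tolerance = 1e-8)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # restart -> 1: all mass stays on the seed
  h99 <- build_hetero(g1, data.frame(gene = "A", phenotype = "P"),
                      restart = 0.999)
  expect_gt(rwr_scores(h99, "A")[["A"]], 0.998)

  # agreement with a dense direct solve on <= 20-node instances
  set.seed(17)
  for (i in 1:10) {
    g <- rand_graph(sample(8:16, 1), 0.3)
    n <- igraph::vcount(g)
    g <- igraph::add_edges(g, c(rbind(sprintf("N%02d", 1:(n - 1)),
                                      sprintf("N%02d", 2:n))))
    g <- igraph::simplify(g)
    links <- data.frame(gene = sprintf("N%02d", sample(n, 2)),
                        phenotype = c("P1", "P2"))
    h <- build_hetero(g, links)
    p <- rwr_scores(h, "N01")
    W <- as.matrix(h$W)
    p0 <- as.numeric(rownames(W) == "N01")
    direct <- solve(diag(nrow(W)) - (1 - h$restart) * W, h$restart * p0)
    expect_equal(unname(p), unname(direct), tolerance = 1e-8)
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("minimum steps is BFS distance in the heterogeneous graph", {
  h <- toy_hetero()
  expect_equal(min_steps(h, "A", "P"), 1)  # direct gene-phenotype link
  expect_equal(min_steps(h, "B", "P"), 2)  # first neighbor, no own link
  g <- mini_graph(c("A", "B"), isolates = "Z")
  h2 <- build_hetero(g, data.frame(gene = "A", phenotype = "P"))
  expect_equal(min_steps(h2, "Z", "P"), Inf)
  expect_error(min_steps(h, "NOPE", "P"), "not in network")

  # equals a Floyd-Warshall oracle on small random instances, and
  # deleting an edge never shortens any path
  set.seed(23)
  for (i in 1:10) {
    g <- rand_graph(7, 0.35)
    links <- data.frame(gene = c("N01", "N04"), phenotype = c("P", "P"))
    h <- build_hetero(g, links)
    d <- fw_distances(h$graph)
    for (gene in sprintf("N%02d", 1:7)) {
      expect_equal(min_steps(h, gene, "P"), unname(d[gene, "P"]))
    }
    if (igraph::ecount(g) > 1) {
      g_less <- igraph::delete_edges(g, 1)
      h_less <- build_hetero(g_less, links)
      for (gene in sprintf("N%02d", 1:7)) {
        expect_gte(min_steps(h_less, gene, "P"), min_steps(h, gene, "P"))
      }
    }
  }
})

test_that("step counts satisfy the triangle inequality over sampled triples", {
  set.seed(31)
  g <- rand_graph(10, 0.3)
  links <- data.frame(gene = c("N01", "N05"), phenotype = c("P1", "P2"))
  h <- build_hetero(g, links)
  d <- igraph::distances(h$graph, weights = NA)
  nodes <- rownames(d)
  for (i in 1:50) {
    tri <- sample(nodes, 3)
    expect_lte(d[tri[1], tri[3]],
               d[tri[1], tri[2]] + d[tri[2], tri[3]])
  }
})

test_that("candidates rank by steps then RWR score", {
  h <- toy_hetero()
  out <- rank_candidates(c("B", "C", "A"), h, "P")
  expect_equal(out$gene[1], "A")
  expect_equal(out$steps, c(1, 2, 2))
  # equal steps resolved by higher RWR score, then symbol: B and C are
  # symmetric here so the symbol breaks the tie
  expect_equal(out$gene[2:3], c("B", "C"))

  single <- rank_candidates("B", h, "P")
  expect_equal(nrow(single), 1)
  expect_error(rank_candidates("NOPE", h, "P"), "not in gene layer")

  # provenance columns are carried through
  cands <- data.frame(gene = c("B", "C"), forward = c(TRUE, FALSE),
                      reverse = c(FALSE, TRUE))
  out2 <- rank_candidates(cands, h, "P")
  expect_true(all(c("forward", "reverse", "steps", "rwr_score") %in%
                    names(out2)))
})
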