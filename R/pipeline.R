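#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with the
#' input paths, the selected ontology term IDs, and the analysis parameters.
#' Required paths must exist; parameters must lie in their documented ranges.
#'
#' @param config a named list or a YAML file path.
#' @return the validated, default-filled configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(channel = "experimental", min_score = 400L, k = 6L,
                   alpha = 0.05, restart = 0.7, jump = 0.5,
                   min_size = 3L, max_size = 30L, n_perm = 1000L,
                   go_terms = "all", hpo_terms = "all", rng_seed = 1L,
                   control_group = NULL, dge_method = "moderated",
                   out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  needed <- c("links", "go_gaf", "hpo_assoc", "expression", "groups",
              "pheno_links")
  for (field in needed) {
    if (is.null(config[[field]])) stopf("config error: '%s' is required", field)
    if (!file.exists(config[[field]])) {
      stopf("config error: file not found for '%s': %s", field, config[[field]])
    }
  }
  for (field in c("seed_gene", "phenotype")) {
    if (is.null(config[[field]])) stopf("config error: '%s' is required", field)
  }
  stopifnot(config$restart > 0, config$restart < 1,
            config$jump > 0, config$jump < 1,
            config$alpha > 0, config$alpha < 1,
            config$k >= 1, config$min_score >= 0)
  config
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full modifier-gene prioritization pipeline
#'
#' Executes, in order: ontology gene-set selection (GO and HPO), PPI network
#' construction and origin labelling, forward (GO network) and reverse (HPO
#' network) centrality-based candidate selection, differential expression,
#' phenotype propagation with active-subnetwork search and the
#' expression-derived candidate rule, candidate consolidation, and
#' random-walk-with-restart ranking against the phenotype node on the
#' heterogeneous network. The run is deterministic given an identical
#' configuration.
#'
#' @param config a configuration list or YAML path (see [validate_config()]).
#' @return a report list: parameters, per-stage sizes, Venn counts, the
#'   forward/reverse/expression candidate sets, and the final ranked
#'   candidate table (\code{$final}); written to \code{out_dir} (JSON report
#'   plus TSVs) when \code{out_dir} is set.
#' @export
run_all <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  save_tsv <- function(df, name) {
    if (!is.null(out)) {
      utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }

  ann_go <- run_stage("ontology", read_gaf(config$go_gaf))
  ann_hpo <- run_stage("ontology", read_hpo_assoc(config$hpo_assoc))
  pick_terms <- function(ann, sel) {
    if (identical(sel, "all")) names(ann$terms) else sel
  }
  go_genes <- run_stage("ontology",
                        genes_for_terms(ann_go, pick_terms(ann_go, config$go_terms)))
  hpo_genes <- run_stage("ontology",
                         genes_for_terms(ann_hpo, pick_terms(ann_hpo, config$hpo_terms)))
  venn <- venn_counts(go_genes, hpo_genes)

  edges <- run_stage("network", read_string_links(
    config$links, channel = config$channel, min_score = config$min_score))
  full_net <- run_stage("network", build_network(edges))
  full_net <- annotate_origin(full_net, go_genes, hpo_genes)
  go_net <- run_stage("network", build_network(
    edges, restrict_to = go_genes, keep_seed_neighbors = config$seed_gene))
  hpo_net <- run_stage("network", build_network(
    edges, restrict_to = hpo_genes, keep_seed_neighbors = config$seed_gene))

  cent_go <- run_stage("centrality", centrality_table(go_net))
  cent_hpo <- run_stage("centrality", centrality_table(hpo_net))
  forward <- run_stage("centrality", top_candidates(
    cent_go, k = config$k, exclude = config$seed_gene))
  reverse <- run_stage("centrality", top_candidates(
    cent_hpo, k = config$k, exclude = config$seed_gene))
  strategy <- combine_strategies(forward, reverse)
  save_tsv(cent_go, "centrality_go.tsv")
  save_tsv(cent_hpo, "centrality_hpo.tsv")

  expr_df <- run_stage("dge", utils::read.delim(config$expression,
                                                check.names = FALSE))
  expr <- as.matrix(expr_df[-1L])
  rownames(expr) <- toupper(expr_df[[1L]])
  groups_df <- run_stage("dge", utils::read.delim(config$groups))
  groups <- groups_df$group[match(colnames(expr), groups_df$sample)]
  dge <- run_stage("dge", dge_contrast(expr, groups, alpha = config$alpha,
                                       control = config$control_group,
                                       method = config$dge_method))
  save_tsv(dge, "dge.tsv")

  links <- run_stage("phenonet", read_pheno_links(config$pheno_links))
  pheno_genes <- union(links$gene[links$phenotype == config$phenotype],
                       toupper(config$seed_gene))
  relevance <- run_stage("phenonet", propagate_phenotype(
    full_net, pheno_genes, restart = config$restart))
  scores <- node_scores(dge, relevance)
  subnets <- run_stage("phenonet", find_active_subnetworks(
    full_net, scores, min_size = config$min_size, max_size = config$max_size,
    n_perm = config$n_perm, alpha = config$alpha, rng_seed = config$rng_seed))
  expr_cands <- run_stage("phenonet", expression_candidates(
    dge, full_net, config$seed_gene, subnets, alpha = config$alpha))
  save_tsv(scores, "node_scores.tsv")

  candidates <- strategy
  candidates$expression <- candidates$gene %in% expr_cands$gene
  new_expr <- setdiff(expr_cands$gene, candidates$gene)
  if (length(new_expr) > 0L) {
    candidates <- rbind(candidates, data.frame(
      gene = new_expr, forward = FALSE, reverse = FALSE, expression = TRUE,
      stringsAsFactors = FALSE))
  }
  stopifnot(nrow(candidates) == nrow(strategy) + length(new_expr))

  h <- run_stage("rwrank", build_hetero(full_net, links, jump = config$jump,
                                        restart = config$restart))
  final <- run_stage("rwrank", rank_candidates(candidates, h,
                                               config$phenotype))
  save_tsv(final, "final_candidates.tsv")

  report <- list(
    parameters = config[c("channel", "min_score", "k", "alpha", "restart",
                          "jump", "min_size", "max_size", "n_perm",
                          "rng_seed", "seed_gene", "phenotype")],
    inputs = config[c("links", "go_gaf", "hpo_assoc", "expression",
                      "groups", "pheno_links")],
    sizes = list(go_genes = length(go_genes), hpo_genes = length(hpo_genes),
                 full_network_nodes = igraph::vcount(full_net),
                 full_network_edges = igraph::ecount(full_net),
                 go_network_nodes = igraph::vcount(go_net),
                 hpo_network_nodes = igraph::vcount(hpo_net),
                 n_subnetworks = length(subnets)),
    venn = as.list(venn),
    forward = forward, reverse = reverse,
    strategy_union = strategy$gene,
    expression_candidates = expr_cands$gene,
    n_candidates = nrow(candidates),
    final = final)
  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Generate a self-contained synthetic demo study
#'
#' Writes a complete synthetic input bundle (STRING-dialect links, GAF, HPO
#' associations, expression matrix with groups, bipartite phenotype links,
#' truth manifest) plus a matching pipeline configuration YAML into a
#' directory, and returns the configuration path. The planted truth
#' (seed-adjacent modifiers and inter-community bridges) is recoverable by
#' [run_all()].
#'
#' @param dir output directory (created if needed).
#' @param rng_seed integer seed controlling every generated input.
#' @param n_genes,n_per_group scale of the synthetic study.
#' @param n_perm permutations used by the subnetwork search stage.
#' @return path to the written \code{config.yaml}.
#' @export
demo_config <- function(dir, rng_seed = 42L, n_genes = 60L, n_per_group = 5L,
                        n_perm = 199L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- gen_ppi_network(n_genes, n_communities = 2L, attach = 2L,
                         n_neighbor_mods = 2L, n_bridge_mods = 1L,
                         rng_seed = rng_seed)
  truth <- sim$truth
  keep <- c(truth$seed_gene, truth$neighbor_modifiers, truth$bridge_modifiers)
  ann_go <- gen_annotations(sim$network, "GO_BP", n_terms = 6L,
                            genes_per_term = 12L, shared_fraction = 0.6,
                            rng_seed = rng_seed, include = keep)
  ann_hpo <- gen_annotations(sim$network, "HPO", n_terms = 6L,
                             genes_per_term = 12L, shared_fraction = 0.6,
                             rng_seed = rng_seed, include = keep)
  ex <- gen_expression(sim$network, truth, n_per_group = n_per_group,
                       sigma = 0.5, rng_seed = rng_seed + 1L)
  links <- gen_pheno_links(sim$network, truth, n_extra_links = 3L,
                           rng_seed = rng_seed + 2L)

  paths <- list(links = "string_links.tsv", go_gaf = "annotations.gaf",
                hpo_assoc = "genes_to_phenotype.tsv",
                expression = "expression.tsv", groups = "groups.tsv",
                pheno_links = "pheno_links.tsv", truth = "truth.json")
  paths <- lapply(paths, function(p) file.path(dir, p))
  write_string_links(sim$network, paths$links)
  write_gaf(ann_go, paths$go_gaf)
  write_hpo_assoc(ann_hpo, paths$hpo_assoc)
  write_expression(ex$expr, ex$groups, paths$expression, paths$groups)
  write_pheno_links(links, paths$pheno_links)
  write_truth(truth, paths$truth)

  config <- c(paths[c("links", "go_gaf", "hpo_assoc", "expression",
                      "groups", "pheno_links")],
              list(seed_gene = truth$seed_gene,
                   phenotype = truth$phenotype_id,
                   control_group = "control",
                   k = 3L, n_perm = n_perm, rng_seed = rng_seed,
                   out_dir = file.path(dir, "out")))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_path
}
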