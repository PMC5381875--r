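# End-to-end orchestration: alpha -> beta -> composition -> environment
# association -> co-occurrence network, from one declarative config.

#' Build a pipeline run configuration
#'
#' Defaults mirror the published analysis settings: normalization to the
#' smallest library, dominance thresholds 5%/1%, abundant-genus cutoff 1%,
#' pooled network filter 0.12%, edge rules rho > 0.6 with P < 0.01
#' (positive) and rho < -0.6 with P < 0.05 (negative), hub degree >= 8.
#'
#' @param counts,taxonomy,env paths to the input TSVs.
#' @param tree optional newick tree path (enables weighted UniFrac).
#' @param out_dir output directory.
#' @param depth rarefaction depth or `"min"`.
#' @param iterations rarefaction draws for alpha indices.
#' @param dominant_min,subdominant_min dominance thresholds (percent).
#' @param top_k per-sample top genera retained for the heatmap matrix.
#' @param abundant_min_pct abundance cutoff (percent) for RDA genera.
#' @param rda_variables environmental columns used as RDA constraints; the
#'   default keeps the six chemistry variables so the constraint count stays
#'   below a seven-sample design.
#' @param n_perm permutations for RDA term tests.
#' @param min_pooled_pct pooled-abundance cutoff (percent) for the network.
#' @param pos_rho,pos_p,neg_rho,neg_p network edge thresholds.
#' @param hub_min_degree hub degree threshold.
#' @param p_method `"auto"`, `"exact"` or `"approx"` Spearman P-values.
#' @param seed global integer seed; stages derive sub-streams from it.
#' @return list of class `"rhizo_config"`.
#' @export
run_config <- function(counts, taxonomy, env, tree = NULL, out_dir = tempfile("rhizonet"),
                       depth = "min", iterations = 100,
                       dominant_min = 5, subdominant_min = 1, top_k = 15,
                       abundant_min_pct = 1,
                       rda_variables = c("pH", "SOC", "AP", "TP", "NO3", "NH4"),
                       n_perm = 999,
                       min_pooled_pct = 0.12, pos_rho = 0.6, pos_p = 0.01,
                       neg_rho = -0.6, neg_p = 0.05, hub_min_degree = 8,
                       p_method = "auto", seed = 1) {
  cfg <- list(counts = counts, taxonomy = taxonomy, env = env, tree = tree,
              out_dir = out_dir, depth = depth, iterations = iterations,
              dominant_min = dominant_min, subdominant_min = subdominant_min,
              top_k = top_k, abundant_min_pct = abundant_min_pct,
              rda_variables = rda_variables,
              n_perm = n_perm, min_pooled_pct = min_pooled_pct,
              pos_rho = pos_rho, pos_p = pos_p, neg_rho = neg_rho,
              neg_p = neg_p, hub_min_degree = hub_min_degree,
              p_method = p_method, seed = seed)
  class(cfg) <- "rhizo_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  check_that(cfg$dominant_min > 0 && cfg$dominant_min < 100, "dominant_min",
             "must lie in (0, 100)")
  check_that(cfg$subdominant_min > 0 && cfg$subdominant_min < 100,
             "subdominant_min", "must lie in (0, 100)")
  check_that(cfg$min_pooled_pct >= 0, "min_pooled_pct", "must be >= 0")
  check_that(abs(cfg$pos_rho) < 1 && abs(cfg$neg_rho) < 1, "pos_rho",
             "correlation thresholds must satisfy |rho| < 1")
  check_that(cfg$hub_min_degree >= 1, "hub_min_degree", "must be >= 1")
  check_that(cfg$iterations >= 1, "iterations", "must be >= 1")
  as_seed(cfg$seed, "seed")
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return a `"rhizo_config"` for the reader; `path` for the writer.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg configuration from [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "rhizo_config"))
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))], path)
  invisible(path)
}

#' Run the full downstream pipeline
#'
#' Executes alpha diversity, beta ordination, composition, environment
#' association and co-occurrence network stages in order, writes every
#' stage's outputs under `cfg$out_dir`, and returns a machine-readable run
#' report (also written as `report.json`). Identical config + seed gives an
#' identical report.
#'
#' @param cfg configuration from [run_config()].
#' @return report list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- read_count_table(cfg$counts)
  taxonomy <- read_taxonomy(cfg$taxonomy)
  env <- read_env_table(cfg$env)
  tree <- if (!is.null(cfg$tree)) ape::read.tree(cfg$tree)

  miss_env <- setdiff(colnames(counts), env$sample)
  miss_cnt <- setdiff(env$sample, colnames(counts))
  if (length(miss_env) || length(miss_cnt)) {
    stop("sample-id mismatch between counts and env: ",
         paste(c(sprintf("missing from env: %s", paste(miss_env, collapse = ",")),
                 sprintf("missing from counts: %s", paste(miss_cnt, collapse = ","))
         )[c(length(miss_env) > 0, length(miss_cnt) > 0)], collapse = "; "),
         call. = FALSE)
  }
  env <- env[match(colnames(counts), env$sample), , drop = FALSE]

  report <- list(package_version = as.character(utils::packageVersion("rhizonet")),
                 config = unclass(cfg), stages = list())
  out <- function(f) file.path(cfg$out_dir, f)

  # alpha
  alpha <- alpha_summary(counts, depth = cfg$depth, iterations = cfg$iterations,
                         seed = stage_seed(cfg$seed, "alpha"))
  utils::write.table(alpha, out("alpha.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report$stages$alpha <- list(depth = alpha$depth[1],
                              shannon = stats::setNames(alpha$shannon, alpha$sample))

  # beta (distances computed on one seeded rarefaction draw at the alpha depth)
  rare <- counts
  for (s in seq_len(ncol(counts))) {
    rare[, s] <- rarefy(counts[, s], alpha$depth[1],
                        seed = stage_seed(cfg$seed, paste0("beta", s)))
  }
  bc <- bray_curtis(rare)
  write_square_tsv(bc, out("bray_curtis.tsv"))
  metric <- "bray_curtis"
  d <- bc
  if (!is.null(tree)) {
    d <- weighted_unifrac(rare, tree)
    write_square_tsv(d, out("weighted_unifrac.tsv"))
    metric <- "weighted_unifrac"
  }
  ord <- pcoa(d)
  utils::write.table(data.frame(sample = rownames(ord$coordinates),
                                ord$coordinates, check.names = FALSE),
                     out("pcoa_coordinates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(metric = metric, eigenvalues = ord$eigenvalues,
                            percent_explained = ord$percent_explained),
                       out("pcoa.json"), auto_unbox = TRUE, digits = NA)
  report$stages$beta <- list(metric = metric,
                             pco1_percent = ord$percent_explained[1])

  # composition
  comp_summary <- list()
  for (rank in c("phylum", "class", "genus")) {
    agg <- aggregate_rank(counts, taxonomy, rank)
    rel <- relative_abundance(agg)
    write_count_table(agg, out(paste0(rank, "_counts.tsv")), id_col = rank)
    if (rank == "phylum") {
      dom <- classify_dominance(rel, cfg$dominant_min, cfg$subdominant_min)
      utils::write.table(data.frame(phylum = names(dom), class = as.character(dom)),
                         out("phylum_dominance.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      comp_summary$dominant_phyla <- names(dom)[dom == "dominant"]
    }
    if (rank == "genus") {
      genus_counts <- agg
      shared <- shared_taxa(agg)
      comp_summary$shared_genera <- length(shared$taxa)
      comp_summary$shared_percent_range <- range(shared$percent)
      top <- top_k_union(agg, k = cfg$top_k)
      utils::write.table(data.frame(genus = top$taxa, top$percent,
                                    check.names = FALSE),
                         out("top_genera_heatmap.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      comp_summary$top_union_size <- length(top$taxa)
    }
  }
  report$stages$composition <- comp_summary

  # environment association
  reg <- diversity_env_regression(alpha, env)
  genus_rel <- relative_abundance(genus_counts)
  abundant <- select_abundant_genera(
    genus_rel[rownames(genus_rel) != "unclassified", , drop = FALSE],
    cfg$abundant_min_pct)
  rda_vars <- intersect(cfg$rda_variables, names(env))
  rda <- rda_fit(t(abundant), env[, rda_vars, drop = FALSE],
                 n_perm = cfg$n_perm, seed = stage_seed(cfg$seed, "rda"))
  jsonlite::write_json(list(
    regression = reg,
    rda = list(eigenvalues = rda$eigenvalues,
               percent_of_total = rda$percent_of_total,
               cumulative_first_two = rda$cumulative_first_two,
               pseudo_canonical_correlation = rda$pseudo_canonical_correlation,
               term_effects = rda$term_effects)),
    out("env_assoc.json"), auto_unbox = TRUE, digits = NA)
  report$stages$env_assoc <- list(shannon_ph_r_squared = reg$r_squared,
                                  n_abundant_genera = nrow(abundant),
                                  rda_first_two_percent = rda$cumulative_first_two)

  # co-occurrence network
  net_counts <- filter_genera(
    genus_counts[rownames(genus_counts) != "unclassified", , drop = FALSE],
    cfg$min_pooled_pct)
  cm <- spearman_matrix(net_counts, method = cfg$p_method)
  net <- build_network(cm, taxonomy, cfg$pos_rho, cfg$pos_p, cfg$neg_rho, cfg$neg_p)
  export_graph(net, out("network.graphml"), "graphml")
  export_graph(net, out("network_edges.tsv"), "edgelist")
  net_summary <- list(genera_considered = nrow(net_counts),
                      nodes = nrow(net$nodes),
                      positive_edges = sum(net$edges$sign == "positive"),
                      negative_edges = sum(net$edges$sign == "negative"))
  if (net_summary$positive_edges > 0) {
    st <- network_stats(net, "positive", cfg$hub_min_degree,
                        seed = stage_seed(cfg$seed, "network"))
    inc <- phylum_incidence(net, "positive")
    net_summary <- c(net_summary, list(
      hubs = st$hubs, average_path_length = st$average_path_length,
      diameter = st$diameter, modularity = st$modularity,
      interphylum_percent = inc$inter_total))
    jsonlite::write_json(list(stats = unclass(st), incidence = inc),
                         out("network_stats.json"), auto_unbox = TRUE, digits = NA)
  }
  report$stages$network <- net_summary

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

write_square_tsv <- function(m, path) {
  utils::write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the fixture-only stages on the packaged study tables
#'
#' The stages that only need the published per-sample summaries are run:
#' the effective-sequence total check and the Shannon-pH regression. Stages
#' that would need the study's unpublished genus table are skipped with an
#' explicit notice.
#'
#' @return report list with `effective_sequence_total`, `regression`
#'   (Shannon on pH across the 7 samples) and `skipped` notices.
#' @export
run_paper_fixture <- function() {
  rich <- study_fixture("richness")
  env <- study_fixture("env")
  reg <- diversity_env_regression(rich, env, index = "shannon", variable = "pH")
  list(effective_sequence_total = sum(rich$effective_sequences),
       samples = rich$sample,
       regression = reg,
       skipped = c("beta_ordination: requires the study's genus table (unpublished)",
                   "composition: requires the study's genus table (unpublished)",
                   "rda: requires the study's genus table (unpublished)",
                   "cooccurrence_network: requires the study's genus table (unpublished)"))
}
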