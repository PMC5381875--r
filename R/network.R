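# Thresholded signed co-occurrence networks over genera, with topology,
# hub, modularity and phylum-incidence statistics.

#' Filter genera by pooled relative abundance
#'
#' Default reading: keep a genus if its pooled counts across all samples are
#' at least `min_pooled_pct` percent of the grand total. The alternative
#' per-sample reading (`mode = "each_sample"`) requires the threshold in
#' every sample.
#'
#' @param counts genus-by-sample count matrix.
#' @param min_pooled_pct threshold in percent (default 0.12).
#' @param mode `"pooled"` (default) or `"each_sample"`.
#' @return row-subset of `counts`.
#' @export
filter_genera <- function(counts, min_pooled_pct = 0.12,
                          mode = c("pooled", "each_sample")) {
  mode <- match.arg(mode)
  validate_count_table(counts)
  stopifnot(min_pooled_pct >= 0)
  if (mode == "pooled") {
    share <- rowSums(counts) / sum(counts) * 100
    keep <- share >= min_pooled_pct
  } else {
    rel <- relative_abundance(counts)
    keep <- apply(rel >= min_pooled_pct, 1, all)
  }
  counts[keep, , drop = FALSE]
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' A genus pair is a positive (co-occurrence) edge when `rho > pos_rho` and
#' `P < pos_p`, and a negative (exclusion) edge when `rho < neg_rho` and
#' `P < neg_p` — strict inequalities throughout. Nodes are the genera
#' incident to at least one edge; isolated genera are dropped.
#'
#' @param cm a [spearman_matrix()] result.
#' @param taxonomy taxonomy data.frame used to label nodes with phyla.
#' @param pos_rho,pos_p thresholds for positive edges (defaults 0.6, 0.01).
#' @param neg_rho,neg_p thresholds for negative edges (defaults -0.6, 0.05).
#' @return object of class `"rhizo_network"`: `nodes` (data.frame genus,
#'   phylum) and `edges` (data.frame from, to, rho, p, sign).
#' @export
build_network <- function(cm, taxonomy, pos_rho = 0.6, pos_p = 0.01,
                          neg_rho = -0.6, neg_p = 0.05) {
  stopifnot(inherits(cm, "rhizo_cormat"))
  if (abs(pos_rho) >= 1 || abs(neg_rho) >= 1) {
    stop("correlation thresholds must satisfy |rho| < 1", call. = FALSE)
  }
  validate_taxonomy(taxonomy)
  idx <- which(upper.tri(cm$rho), arr.ind = TRUE)
  rho <- cm$rho[idx]
  p <- cm$p[idx]
  defined <- !is.na(rho) & !is.na(p)
  pos <- defined & rho > pos_rho & p < pos_p
  neg <- defined & rho < neg_rho & p < neg_p
  keep <- pos | neg
  edges <- data.frame(from = cm$genera[idx[keep, 1]],
                      to = cm$genera[idx[keep, 2]],
                      rho = rho[keep], p = p[keep],
                      sign = ifelse(pos[keep], "positive", "negative"),
                      stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(edges$from, edges$to)))
  phyla <- taxonomy$phylum[match(node_ids, taxonomy$genus)]
  phyla[is.na(phyla)] <- taxonomy$phylum[match(node_ids, taxonomy$taxon)][is.na(phyla)]
  nodes <- data.frame(genus = node_ids, phylum = phyla, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 thresholds = c(pos_rho = pos_rho, pos_p = pos_p,
                                neg_rho = neg_rho, neg_p = neg_p)),
            class = "rhizo_network")
}

# igraph object for one signed subgraph; isolated nodes are absent by
# construction (nodes are edge-incident).
signed_igraph <- function(net, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  e <- net$edges[net$edges$sign == sign, , drop = FALSE]
  if (nrow(e) == 0) stop("the ", sign, " network has no edges", call. = FALSE)
  ids <- sort(unique(c(e$from, e$to)))
  v <- net$nodes[match(ids, net$nodes$genus), , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("from", "to", "rho", "p")],
                                directed = FALSE,
                                vertices = data.frame(name = v$genus,
                                                      phylum = v$phylum))
}

#' Topology, hub and modularity statistics of a signed network
#'
#' Average path length is the mean shortest-path length over connected
#' (ordered) node pairs; the diameter is the longest shortest path.
#' Communities come from deterministic greedy modularity maximization
#' (Clauset-Newman-Moore); modularity is
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)`.
#'
#' @param net a [build_network()] result.
#' @param sign `"positive"` or `"negative"` subnetwork.
#' @param hub_min_degree minimum degree for a node to count as a hub
#'   (default 8).
#' @param seed integer seed (community detection is deterministic; the seed
#'   guards any stochastic plug-in algorithm).
#' @return object of class `"rhizo_netstats"`: node/edge counts, `degree`,
#'   `hubs`, `average_path_length`, `diameter`, `modularity`, `communities`,
#'   `n_components`, `component_sizes`.
#' @export
network_stats <- function(net, sign = c("positive", "negative"),
                          hub_min_degree = 8, seed = 1) {
  sign <- match.arg(sign)
  g <- signed_igraph(net, sign)
  deg <- igraph::degree(g)
  comm <- with_seed(seed, igraph::cluster_fast_greedy(g))
  mem <- igraph::membership(comm)
  membership <- stats::setNames(as.integer(mem), names(mem))
  comps <- igraph::components(g)
  structure(list(sign = sign,
                 node_count = igraph::vcount(g),
                 edge_count = igraph::ecount(g),
                 degree = deg,
                 hubs = names(deg)[deg >= hub_min_degree],
                 average_path_length = igraph::mean_distance(g, unconnected = TRUE),
                 diameter = igraph::diameter(g, unconnected = TRUE, weights = NA),
                 modularity = igraph::modularity(g, membership),
                 communities = membership,
                 n_components = comps$no,
                 component_sizes = unname(comps$csize)),
            class = "rhizo_netstats")
}

#' @export
print.rhizo_netstats <- function(x, ...) {
  cat(sprintf("%s network: %d nodes, %d edges, %d hubs\n", x$sign,
              x$node_count, x$edge_count, length(x$hubs)))
  cat(sprintf("average path length %.3f, diameter %d, modularity %.3f (%d communities)\n",
              x$average_path_length, x$diameter, x$modularity,
              length(unique(x$communities))))
  invisible(x)
}

#' Phylum-pair incidence of network edges
#'
#' Assigns each edge of the chosen sign to its unordered phylum pair and
#' reports the percentage of edges per pair, plus intra-/inter-phylum
#' totals (summing to 100).
#'
#' @param net a [build_network()] result; every node must carry a phylum.
#' @param sign `"positive"` (default) or `"negative"`.
#' @return list with `by_pair` (data.frame phylum_a, phylum_b, edges,
#'   percent), `intra_total`, `inter_total`.
#' @export
phylum_incidence <- function(net, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  e <- net$edges[net$edges$sign == sign, , drop = FALSE]
  if (nrow(e) == 0) stop("the ", sign, " network has no edges", call. = FALSE)
  ph <- stats::setNames(net$nodes$phylum, net$nodes$genus)
  if (anyNA(ph)) stop("unlabeled node: ", paste(names(ph)[is.na(ph)], collapse = ", "),
                      call. = FALSE)
  pa <- ph[e$from]; pb <- ph[e$to]
  a <- pmin(pa, pb); b <- pmax(pa, pb)
  tab <- table(paste(a, b, sep = " | "))
  pairs <- do.call(rbind, strsplit(names(tab), " | ", fixed = TRUE))
  by_pair <- data.frame(phylum_a = pairs[, 1], phylum_b = pairs[, 2],
                        edges = as.integer(tab),
                        percent = 100 * as.integer(tab) / nrow(e),
                        stringsAsFactors = FALSE)
  by_pair <- by_pair[order(-by_pair$percent), ]
  rownames(by_pair) <- NULL
  intra <- sum(by_pair$percent[by_pair$phylum_a == by_pair$phylum_b])
  list(by_pair = by_pair, intra_total = intra, inter_total = 100 - intra)
}

#' Export a co-occurrence network
#'
#' GraphML (nodes carry genus, phylum and degree; edges carry rho, P and
#' sign) or a flat TSV edge list that [import_network()] round-trips.
#'
#' @param net a [build_network()] result.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "rhizo_network"))
  if (format == "graphml") {
    e <- net$edges
    g <- igraph::graph_from_data_frame(
      e[, c("from", "to", "rho", "p", "sign")], directed = FALSE,
      vertices = data.frame(name = net$nodes$genus, phylum = net$nodes$phylum))
    igraph::V(g)$degree <- igraph::degree(g)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ph <- stats::setNames(net$nodes$phylum, net$nodes$genus)
    df <- data.frame(from = net$edges$from, to = net$edges$to,
                     from_phylum = ph[net$edges$from],
                     to_phylum = ph[net$edges$to],
                     rho = net$edges$rho, p = net$edges$p,
                     sign = net$edges$sign, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a network written by [export_graph()]
#'
#' @param path file written by [export_graph()].
#' @param format `"graphml"` or `"edgelist"`.
#' @return a `"rhizo_network"` object.
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    vs <- igraph::as_data_frame(g, what = "vertices")
    nodes <- data.frame(genus = vs$name, phylum = vs$phylum,
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = el$from, to = el$to, rho = el$rho, p = el$p,
                        sign = el$sign, stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_strict(path)
    edges <- df[, c("from", "to", "rho", "p", "sign")]
    nodes <- unique(data.frame(
      genus = c(df$from, df$to), phylum = c(df$from_phylum, df$to_phylum),
      stringsAsFactors = FALSE))
  }
  ord <- order(nodes$genus)
  structure(list(nodes = nodes[ord, , drop = FALSE],
                 edges = edges, thresholds = NULL),
            class = "rhizo_network")
}

#' @export
print.rhizo_network <- function(x, ...) {
  cat("Co-occurrence network:", nrow(x$nodes), "genera,",
      sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative edges\n")
  invisible(x)
}
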