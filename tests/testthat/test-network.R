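test_that("pooled abundance filtering applies >= at the threshold", {
  # grand total 100000; shares: 0.12%, 0.119%, and the rest
  m <- matrix(c(120L, 119L, 99761L), ncol = 1,
              dimnames = list(c("keep", "drop", "big"), "s1"))
  m <- cbind(m, m)  # two identical samples keep shares unchanged
  colnames(m) <- c("s1", "s2")
  kept <- rownames(filter_genera(m, 0.12))
  expect_true("keep" %in% kept)
  expect_false("drop" %in% kept)
  expect_identical(nrow(filter_genera(m, 0)), 3L)
})

test_that("edge rules follow the signed threshold semantics strictly", {
  genera <- c("gA", "gB", "gC", "gD")
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.65
  rho[1, 3] <- rho[3, 1] <- 0.65
  rho[2, 3] <- rho[3, 2] <- -0.7
  rho[1, 4] <- rho[4, 1] <- 0.99
  rho[2, 4] <- rho[4, 2] <- -0.55   # inside (-0.6, 0.6): never an edge
  rho[3, 4] <- rho[4, 3] <- 0.6     # not > 0.6: no edge
  p <- matrix(1, 4, 4)
  p[1, 2] <- p[2, 1] <- 0.005
  p[1, 3] <- p[3, 1] <- 0.02   # positive needs P < 0.01
  p[2, 3] <- p[3, 2] <- 0.03   # negative allows P < 0.05
  p[1, 4] <- p[4, 1] <- 0.04   # strong rho but P too large for positive
  p[3, 4] <- p[4, 3] <- 0.001
  cm <- manual_cormat(genera, rho, p)
  tx <- toy_taxonomy(genera, c("P1", "P1", "P2", "P2"))
  net <- build_network(cm, tx)
  key <- paste(net$edges$from, net$edges$to, net$edges$sign)
  expect_setequal(key, c("gA gB positive", "gB gC negative"))
  expect_setequal(net$nodes$genus, c("gA", "gB", "gC"))  # gD is isolated
  expect_error(build_network(cm, tx, pos_rho = 1), "rho")
})

test_that("path-graph topology statistics match hand enumeration", {
  genera <- c("a", "b", "c")
  rho <- diag(3); rho[1, 2] <- rho[2, 1] <- 0.95; rho[2, 3] <- rho[3, 2] <- 0.95
  p <- matrix(1, 3, 3); p[1, 2] <- p[2, 1] <- 1e-4; p[2, 3] <- p[3, 2] <- 1e-4
  net <- build_network(manual_cormat(genera, rho, p),
                       toy_taxonomy(genera, rep("P1", 3)))
  st <- network_stats(net, "positive", hub_min_degree = 2)
  expect_equal(st$average_path_length, 4 / 3)  # pairs {1,1,2}
  expect_equal(st$diameter, 2)
  expect_identical(st$hubs, "b")
})

test_that("two disjoint triangles have modularity 1/2", {
  genera <- paste0("g", 1:6)
  rho <- diag(6); p <- matrix(1, 6, 6)
  link <- function(i, j) {
    rho[i, j] <<- rho[j, i] <<- 0.95
    p[i, j] <<- p[j, i] <<- 1e-4
  }
  link(1, 2); link(2, 3); link(1, 3)
  link(4, 5); link(5, 6); link(4, 6)
  net <- build_network(manual_cormat(genera, rho, p),
                       toy_taxonomy(genera, rep("P1", 6)))
  st <- network_stats(net, "positive")
  expect_equal(st$modularity, 0.5)
  expect_equal(st$n_components, 2)
  # cross-check against the hand formula on the detected partition
  pos <- net$edges[net$edges$sign == "positive", ]
  expect_equal(brute_modularity(pos, st$communities), st$modularity,
               tolerance = 1e-12)
})

test_that("hub threshold is a strict degree cutoff at >= 8", {
  genera <- c("hub", paste0("leaf", 1:8), "g7", paste0("x", 1:7))
  n <- length(genera)
  rho <- diag(n); p <- matrix(1, n, n)
  dimnames(rho) <- dimnames(p) <- list(genera, genera)
  for (l in paste0("leaf", 1:8)) {      # degree 8
    rho["hub", l] <- rho[l, "hub"] <- 0.95
    p["hub", l] <- p[l, "hub"] <- 1e-4
  }
  for (xx in paste0("x", 1:7)) {        # degree 7
    rho["g7", xx] <- rho[xx, "g7"] <- 0.95
    p["g7", xx] <- p[xx, "g7"] <- 1e-4
  }
  net <- build_network(manual_cormat(genera, rho, p),
                       toy_taxonomy(genera, rep("P1", n)))
  st <- network_stats(net, "positive", hub_min_degree = 8)
  expect_identical(st$hubs, "hub")
})

test_that("phylum incidence partitions edges into intra and inter shares", {
  genera <- c("A1", "A2", "B1")
  rho <- diag(3); rho[1, 2] <- rho[2, 1] <- 0.9; rho[1, 3] <- rho[3, 1] <- 0.9
  p <- matrix(1, 3, 3); p[1, 2] <- p[2, 1] <- 1e-3; p[1, 3] <- p[3, 1] <- 1e-3
  net <- build_network(manual_cormat(genera, rho, p),
                       toy_taxonomy(genera, c("PA", "PA", "PB")))
  inc <- phylum_incidence(net, "positive")
  expect_equal(inc$intra_total, 50)
  expect_equal(inc$inter_total, 50)
  expect_equal(sum(inc$by_pair$percent), 100)

  net2 <- build_network(manual_cormat(genera, rho, p),
                        toy_taxonomy(genera, c("PA", "PA", "PA")))
  expect_equal(phylum_incidence(net2, "positive")$intra_total, 100)
})

test_that("graph exports round-trip in both formats", {
  sim <- generate_community(simulation_spec(n_phyla = 4, genera_per_phylum = 15,
                                            block_specs = list(c(6, 2)),
                                            noise_sd = 0.2, seed = 31))
  cm <- spearman_matrix(filter_genera(sim$counts, 0.12))
  net <- build_network(cm, sim$taxonomy)
  expect_gt(nrow(net$edges), 0)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_setequal(back$nodes$genus, net$nodes$genus)
  ord <- order(back$edges$from, back$edges$to)
  ord0 <- order(net$edges$from, net$edges$to)
  expect_equal(back$edges[ord, ], net$edges[ord0, ], ignore_attr = TRUE)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(net, tsv, "edgelist")
  back2 <- import_network(tsv, "edgelist")
  expect_equal(back2$edges[order(back2$edges$from, back2$edges$to), ],
               net$edges[ord0, ], ignore_attr = TRUE)
  expect_setequal(back2$nodes$phylum, net$nodes$phylum)
})

test_that("modularity stays within bounds and detection is deterministic", {
  set.seed(77)
  for (i in 1:5) {
    sim <- generate_community(simulation_spec(n_phyla = 3, genera_per_phylum = 12,
                                              block_specs = list(c(5, 2)),
                                              noise_sd = 0.3, seed = 300 + i))
    cm <- spearman_matrix(sim$counts)
    net <- build_network(cm, sim$taxonomy)
    if (!any(net$edges$sign == "positive")) next
    s1 <- network_stats(net, "positive", seed = 1)
    s2 <- network_stats(net, "positive", seed = 1)
    expect_identical(s1$communities, s2$communities)
    expect_gte(s1$modularity, -0.5)
    expect_lte(s1$modularity, 1)
    expect_gte(s1$diameter, s1$average_path_length)
  }
})
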