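# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately re-derive every quantity from first
# principles, by routes different from the package's implementations.

brute_shannon <- function(x) {
  p <- x / sum(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

brute_chao1 <- function(x) {
  s <- 0; f1 <- 0; f2 <- 0
  for (xi in x) {
    if (xi > 0) s <- s + 1
    if (xi == 1) f1 <- f1 + 1
    if (xi == 2) f2 <- f2 + 1
  }
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

brute_coverage <- function(x) {
  (1 - sum(x == 1) / sum(x)) * 100
}

brute_bray <- function(a, b) {
  num <- 0
  for (i in seq_along(a)) num <- num + min(a[i], b[i])
  1 - 2 * num / (sum(a) + sum(b))
}

# All permutations of the elements of v, one per row, by selection recursion
# (a different construction from the package's insertion recursion).
all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# Exact two-sided Spearman P by looping over every permutation and calling
# R's own Spearman estimator.
brute_spearman_p <- function(x, y) {
  rho_obs <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  perms <- all_perms(seq_along(y))
  hits <- 0
  for (k in seq_len(nrow(perms))) {
    r <- suppressWarnings(stats::cor(x, y[perms[k, ]], method = "spearman"))
    if (abs(r) >= abs(rho_obs) - 1e-9) hits <- hits + 1
  }
  list(rho = rho_obs, p = hits / nrow(perms))
}

# Hand modularity: Q = sum_c (e_c/m - (d_c/2m)^2) from an edge list and a
# membership vector.
brute_modularity <- function(edges, membership) {
  m <- nrow(edges)
  comms <- unique(membership)
  q <- 0
  for (cm in comms) {
    inside <- sum(membership[edges$from] == cm & membership[edges$to] == cm)
    deg <- sum(membership[edges$from] == cm) + sum(membership[edges$to] == cm)
    q <- q + inside / m - (deg / (2 * m))^2
  }
  q
}

# Small deterministic count table used by several files.
toy_counts <- function() {
  m <- matrix(c(10L, 5L, 0L, 3L,
                2L, 8L, 1L, 0L,
                4L, 4L, 4L, 4L), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("A", "B", "C", "D")))
  m
}

toy_taxonomy <- function(taxa, phyla) {
  data.frame(taxon = taxa, phylum = phyla,
             class = paste0("c_", phyla), genus = taxa,
             stringsAsFactors = FALSE)
}

# Correlation-matrix object built by hand, for exercising edge rules
# without running the estimator.
manual_cormat <- function(genera, rho, p, n = 7) {
  dimnames(rho) <- list(genera, genera)
  dimnames(p) <- list(genera, genera)
  structure(list(genera = genera, rho = rho, p = p, n = n,
                 constant = character(0), method = "exact"),
            class = "rhizo_cormat")
}
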