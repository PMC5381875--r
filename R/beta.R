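# Between-sample dissimilarity and principal coordinates analysis.

#' Bray-Curtis dissimilarity matrix
#'
#' `d(A, B) = 1 - 2 * sum(min(a_i, b_i)) / (sum(a) + sum(b))`.
#'
#' @param counts taxon-by-sample count matrix (every sample total > 0).
#' @return symmetric sample-by-sample matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
bray_curtis <- function(counts) {
  validate_count_table(counts)
  if (any(colSums(counts) == 0)) stop("empty sample (zero column sum)", call. = FALSE)
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- counts[, i]; b <- counts[, j]
      d[i, j] <- d[j, i] <- 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
    }
  }
  d
}

#' Weighted UniFrac distance matrix
#'
#' Phylogenetic dissimilarity: each branch is weighted by its length times
#' the absolute difference in the proportion of reads descending from it.
#' The normalized form divides by the maximum attainable value given the
#' two samples' tip placements, `sum_j (p_Aj + p_Bj) * depth_j` with
#' `depth_j` the root-to-tip path length, so distances lie in \[0, 1\].
#'
#' @param counts taxon-by-sample count matrix; every taxon must be a tree tip.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param normalized return the normalized form (default TRUE).
#' @return symmetric sample-by-sample distance matrix.
#' @export
weighted_unifrac <- function(counts, tree, normalized = TRUE) {
  validate_count_table(counts)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length in tree", call. = FALSE)
  missing <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(tree$tip.label, rownames(counts))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  if (any(colSums(counts) == 0)) stop("empty sample (zero column sum)", call. = FALSE)

  n_tip <- length(tree$tip.label)
  n_s <- ncol(counts)
  prop <- sweep(counts[tree$tip.label, , drop = FALSE], 2, colSums(counts), "/")

  # Per-node descendant proportions by postorder accumulation.
  tree <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tree$Nnode
  node_prop <- matrix(0, n_node, n_s)
  node_prop[seq_len(n_tip), ] <- prop
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    node_prop[par, ] <- node_prop[par, ] + node_prop[child, ]
  }
  edge_prop <- node_prop[tree$edge[, 2], , drop = FALSE]
  len <- tree$edge.length
  tip_depth <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]

  d <- matrix(0, n_s, n_s, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n_s - 1)) {
    for (j in seq(i + 1, n_s)) {
      raw <- sum(len * abs(edge_prop[, i] - edge_prop[, j]))
      if (normalized) {
        denom <- sum((prop[, i] + prop[, j]) * tip_depth)
        raw <- if (denom > 0) raw / denom else 0
      }
      d[i, j] <- d[j, i] <- raw
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues are reported
#' but excluded from the percent-variance-explained denominator. For
#' reproducibility each eigenvector's sign is fixed so its first nonzero
#' loading is positive.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param correction `"none"` (default) or `"lingoes"` (adds the smallest
#'   constant to squared off-diagonal distances that makes all eigenvalues
#'   non-negative).
#' @return list of class `"rhizo_pcoa"` with `coordinates` (samples x axes,
#'   positive-eigenvalue axes only), `eigenvalues` (all, non-increasing) and
#'   `percent_explained` (per positive axis, summing to 100).
#' @export
pcoa <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(d)
  d2 <- d^2
  if (correction == "lingoes") {
    ev <- eigen(gower_center(d2), symmetric = TRUE, only.values = TRUE)$values
    c_min <- max(0, -min(ev))
    if (c_min > 0) d2 <- d2 + 2 * c_min * (1 - diag(n))
  }
  B <- gower_center(d2)
  es <- eigen(B, symmetric = TRUE)
  vals <- es$values
  vecs <- es$vectors
  # deterministic sign: first loading of non-negligible magnitude positive
  for (k in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, k]) > 1e-10)[1]
    if (!is.na(nz) && vecs[nz, k] < 0) vecs[, k] <- -vecs[, k]
  }
  tol <- max(abs(vals)) * 1e-10
  pos <- which(vals > tol)
  coords <- vecs[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_along(pos)))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 percent_explained = 100 * vals[pos] / sum(vals[pos])),
            class = "rhizo_pcoa")
}

gower_center <- function(d2) {
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% d2 %*% J
}

#' @export
print.rhizo_pcoa <- function(x, ...) {
  cat("Principal coordinates analysis:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "positive axes\n")
  cat("Percent explained:", paste0(sprintf("%.2f", x$percent_explained), "%",
                                   collapse = ", "), "\n")
  invisible(x)
}
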