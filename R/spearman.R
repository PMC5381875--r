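# Spearman rank correlation with exact permutation P-values for small n.
#
# At the survey's sample sizes (n = 7) the usual t/AS89 approximations for
# Spearman significance are unreliable, so for n <= 8 the two-sided P is
# computed exactly by enumerating all n! orderings of one variable's
# observed (possibly tied, midranked) ranks. The null distribution of |rho|
# depends only on the two rank multisets, so it is cached by tie pattern.

# Environment-level caches: permutation matrices by n, null distributions by
# tie-pattern key.
.spearman_cache <- new.env(parent = emptyenv())

# All n! permutations of 1..n as an integer matrix (rows = permutations).
permutations_of <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  rec <- function(m) {
    if (m == 1) return(matrix(1L, 1, 1))
    p <- rec(m - 1)
    do.call(rbind, lapply(seq_len(m), function(k) {
      left <- ifelse(p >= k, p + 1L, p)
      cbind(rep(k, nrow(p)), left)
    }))
  }
  out <- rec(n)
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  .spearman_cache[[key]] <- out
  out
}

# Sorted (ascending) null distribution of |rho| for the pair of rank
# multisets carried by rx and ry, over all n! orderings of ry.
spearman_null_abs <- function(rx, ry) {
  key <- paste(paste(sort(rx), collapse = ","), paste(sort(ry), collapse = ","),
               sep = "|")
  alt <- paste(paste(sort(ry), collapse = ","), paste(sort(rx), collapse = ","),
               sep = "|")
  hit <- .spearman_cache[[key]] %||% .spearman_cache[[alt]]
  if (!is.null(hit)) return(hit)
  n <- length(rx)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  if (denom == 0) return(NULL)  # constant variable: rho undefined
  perms <- permutations_of(n)
  Yp <- matrix(ry[perms], nrow = nrow(perms))
  vals <- sort(abs((Yp %*% rxc) / denom)[, 1])
  .spearman_cache[[key]] <- vals
  vals
}

# Two-sided exact P for an observed rho against a sorted null of |rho|.
exact_tail_p <- function(null_abs, rho_obs) {
  n_all <- length(null_abs)
  (n_all - findInterval(abs(rho_obs) - 1e-9, null_abs)) / n_all
}

#' Exact two-sided Spearman permutation P-value
#'
#' Enumerates all `length(x)!` orderings of `y`'s midranks and reports the
#' proportion with `|rho|` at least the observed value.
#'
#' @param x,y numeric vectors of equal length (n <= 8 recommended; the
#'   enumeration grows as n!).
#' @return list with `rho` (midrank Spearman correlation) and `p` (exact
#'   two-sided P); `rho` is `NA` when either variable is constant.
#' @export
spearman_exact <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  null_abs <- spearman_null_abs(rx, ry)
  if (is.null(null_abs)) return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = exact_tail_p(null_abs, rho))
}

#' Pairwise Spearman correlation matrix with significance
#'
#' All pairwise midrank Spearman correlations among the rows of a
#' genus-by-sample table. P-values are exact (full n! enumeration of rank
#' orderings) when the sample count is at most `exact_max_n`, otherwise the
#' usual t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. Rows with
#' zero variance are flagged and get `NA` correlations (they can form no
#' edges).
#'
#' @param counts genus-by-sample numeric matrix with at least 4 samples.
#' @param method `"auto"` (exact when feasible), `"exact"`, or `"approx"`.
#' @param exact_max_n largest n for which full enumeration is used (default 8).
#' @param normalize rank per-sample relative abundances rather than raw
#'   counts (default TRUE). Library sizes vary between samples, so raw-count
#'   ranks share a depth component across all genera that inflates positive
#'   correlations; set FALSE only for input that is already depth-free.
#' @return object of class `"rhizo_cormat"`: `genera`, `rho`, `p`
#'   (symmetric, `NA` diagonal), `n`, `constant` (zero-variance genera),
#'   `method` actually used.
#' @export
spearman_matrix <- function(counts, method = c("auto", "exact", "approx"),
                            exact_max_n = 8, normalize = TRUE) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), is.numeric(counts))
  n <- ncol(counts)
  if (n < 4) stop("need at least 4 samples for correlation analysis", call. = FALSE)
  if (normalize) {
    cs <- colSums(counts)
    if (any(cs == 0)) stop("empty sample (zero column sum)", call. = FALSE)
    counts <- sweep(counts, 2, cs, "/")
  }
  g <- nrow(counts)
  genera <- rownames(counts) %||% paste0("g", seq_len(g))
  ranks <- t(apply(counts, 1, rank))
  constant <- apply(counts, 1, function(r) length(unique(r)) == 1)
  rho <- suppressWarnings(stats::cor(t(ranks)))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  dimnames(rho) <- list(genera, genera)

  use_exact <- method == "exact" || (method == "auto" && n <= exact_max_n)
  if (method == "exact" && n > exact_max_n) {
    stop(sprintf("exact enumeration requested but n = %d exceeds exact_max_n = %d",
                 n, exact_max_n), call. = FALSE)
  }
  p <- matrix(NA_real_, g, g, dimnames = list(genera, genera))
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  ok <- !constant[pairs[, 1]] & !constant[pairs[, 2]]
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs)) {
    if (use_exact) {
      # group pairs sharing a tie-pattern pair so each null is built once
      keys <- apply(ranks, 1, function(r) paste(sort(r), collapse = ","))
      k1 <- keys[pairs[, 1]]; k2 <- keys[pairs[, 2]]
      grp <- paste(pmin(k1, k2), pmax(k1, k2), sep = "|")
      for (ids in split(seq_len(nrow(pairs)), grp)) {
        i0 <- pairs[ids[1], 1]; j0 <- pairs[ids[1], 2]
        null_abs <- spearman_null_abs(ranks[i0, ], ranks[j0, ])
        v <- rho[pairs[ids, , drop = FALSE]]
        p[pairs[ids, , drop = FALSE]] <- exact_tail_p(null_abs, v)
      }
    } else {
      r <- rho[pairs]
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      p[pairs] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(genera = genera, rho = rho, p = p, n = n,
                 constant = genera[constant],
                 method = if (use_exact) "exact" else "approx"),
            class = "rhizo_cormat")
}

#' Critical |rho| for the exact Spearman test
#'
#' Smallest attainable `|rho|` (untied ranks) whose exact two-sided P is
#' strictly below `alpha` at sample size `n`.
#'
#' @param n sample count (enumeration is over n! permutations; n <= 8).
#' @param alpha significance level (default 0.01).
#' @return scalar critical value.
#' @export
spearman_critical_rho <- function(n, alpha = 0.01) {
  stopifnot(n >= 4, n <= 9)
  null_abs <- spearman_null_abs(rank(seq_len(n)), rank(seq_len(n)))
  vals <- sort(unique(round(null_abs, 12)), decreasing = TRUE)
  pv <- vapply(vals, function(v) exact_tail_p(null_abs, v), numeric(1))
  if (!any(pv < alpha)) return(NA_real_)
  min(vals[pv < alpha])
}

#' @export
print.rhizo_cormat <- function(x, ...) {
  cat("Spearman correlation matrix:", length(x$genera), "genera, n =", x$n,
      "samples,", x$method, "P-values\n")
  if (length(x$constant)) cat("Zero-variance genera:", length(x$constant), "\n")
  invisible(x)
}
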