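# Within-sample diversity, computed on rarefaction-normalized counts so
# unequal library sizes do not bias comparisons.

#' Rarefy one sample's counts to a fixed depth
#'
#' Subsamples reads without replacement, so the returned column sums to
#' `depth` exactly.
#'
#' @param x non-negative integer count vector for one sample.
#' @param depth target number of reads; must not exceed `sum(x)`.
#' @param seed optional integer seed for a reproducible draw.
#' @return integer vector of the same length (and names) as `x`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  stopifnot(is.numeric(x), all(x >= 0), all(x == round(x)))
  total <- sum(x)
  if (depth > total) {
    stop(sprintf("rarefaction depth %d exceeds the sample total %d; lower the normalization depth",
                 depth, total), call. = FALSE)
  }
  out <- integer(length(x))
  names(out) <- names(x)
  if (depth == 0) return(out)
  if (depth == total) {
    out[] <- as.integer(x)
    return(out)
  }
  reads <- rep.int(seq_along(x), x)
  kept <- with_seed(seed, sample(reads, depth))
  tab <- tabulate(kept, nbins = length(x))
  out[] <- tab
  out
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over nonzero proportions; natural log by
#' default (the convention consistent with published values of 5-7 for
#' communities of thousands of taxa).
#'
#' @param x count (or proportion) vector for one sample.
#' @param base logarithm base; `exp(1)` for nats.
#' @return non-negative scalar.
#' @export
shannon <- function(x, base = exp(1)) {
  stopifnot(all(x >= 0))
  total <- sum(x)
  if (total == 0) stop("cannot compute Shannon index of an all-zero column", call. = FALSE)
  p <- x[x > 0] / total
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` by default,
#' where F1 and F2 are singleton and doubleton counts; the classic
#' `S_obs + F1^2 / (2 * F2)` is available (undefined when F2 = 0, in which
#' case it falls back to the bias-corrected form, the standard convention).
#'
#' @param x count vector for one sample.
#' @param bias_corrected use the bias-corrected estimator (default TRUE).
#' @return estimated richness, always `>= sum(x > 0)`.
#' @export
chao1 <- function(x, bias_corrected = TRUE) {
  stopifnot(all(x >= 0), all(x == round(x)))
  if (sum(x) == 0) stop("cannot estimate richness of an all-zero column", call. = FALSE)
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

#' Good's coverage
#'
#' `C = (1 - F1 / N) * 100`: the estimated percentage of the community
#' captured by a sample of N reads with F1 singletons.
#'
#' @param x count vector for one sample.
#' @return percentage in \[0, 100\].
#' @export
goods_coverage <- function(x) {
  stopifnot(all(x >= 0), all(x == round(x)))
  n <- sum(x)
  if (n == 0) stop("cannot compute coverage of an all-zero column", call. = FALSE)
  (1 - sum(x == 1) / n) * 100
}

#' Rarefaction curve for one sample
#'
#' Mean observed richness over repeated random subsamples at each depth.
#'
#' @param x count vector for one sample.
#' @param depths increasing vector of subsampling depths (each `<= sum(x)`).
#' @param iterations number of independent rarefaction draws per depth.
#' @param seed integer seed.
#' @return data.frame with columns `depth` and `observed_taxa`.
#' @export
rarefaction_curve <- function(x, depths, iterations = 10, seed = 1) {
  stopifnot(iterations >= 1)
  mean_rich <- vapply(seq_along(depths), function(i) {
    draws <- vapply(seq_len(iterations), function(j) {
      sum(rarefy(x, depths[i], seed = stage_seed(seed, paste0("rc", i, "_", j))) > 0)
    }, numeric(1))
    mean(draws)
  }, numeric(1))
  data.frame(depth = depths, observed_taxa = mean_rich)
}

#' Alpha-diversity summary for a count table
#'
#' Rarefies every sample to a common depth and reports observed richness,
#' Good's coverage, Chao1 and Shannon index, averaged over `iterations`
#' independent rarefaction draws (indices are computed per draw, then
#' averaged). `iterations = 1` reproduces single-subsample behaviour.
#'
#' @param counts taxon-by-sample count matrix.
#' @param depth common depth, or `"min"` for the smallest library size.
#' @param iterations number of rarefaction draws.
#' @param seed integer seed.
#' @param base log base for the Shannon index.
#' @return data.frame with one row per sample (order preserved) and columns
#'   `sample`, `depth`, `observed_taxa`, `coverage`, `chao1`, `shannon`.
#' @export
alpha_summary <- function(counts, depth = "min", iterations = 100, seed = 1,
                          base = exp(1)) {
  validate_count_table(counts)
  totals <- colSums(counts)
  if (identical(depth, "min")) depth <- min(totals)
  stopifnot(depth >= 1, iterations >= 1)
  if (depth > min(totals)) {
    stop(sprintf("depth %d exceeds the smallest library (%d); lower the normalization depth",
                 depth, min(totals)), call. = FALSE)
  }
  rows <- lapply(seq_len(ncol(counts)), function(s) {
    draws <- vapply(seq_len(iterations), function(i) {
      y <- rarefy(counts[, s], depth, seed = stage_seed(seed, paste0("a", s, "_", i)))
      c(observed_taxa = sum(y > 0), coverage = goods_coverage(y),
        chao1 = chao1(y), shannon = shannon(y, base = base))
    }, numeric(4))
    colMeans(t(draws))
  })
  out <- data.frame(sample = colnames(counts), depth = depth,
                    do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
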