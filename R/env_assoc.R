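# Diversity-environment regression and redundancy analysis (RDA) of
# abundant genera against soil variables.

#' Regress a diversity index on an environmental variable
#'
#' Ordinary least squares of one alpha-diversity index on one soil variable
#' across the samples common to both tables, with a two-sided t-test on the
#' slope.
#'
#' @param alpha alpha-diversity summary (data.frame with a `sample` column),
#'   e.g. from [alpha_summary()] or [study_fixture()].
#' @param env environment table (data.frame with a `sample` column).
#' @param index diversity column to use (default `"shannon"`).
#' @param variable environmental column to use (default `"pH"`).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
diversity_env_regression <- function(alpha, env, index = "shannon", variable = "pH") {
  stopifnot(is.data.frame(alpha), is.data.frame(env))
  if (!index %in% names(alpha)) stop("index column not found: ", index, call. = FALSE)
  if (!variable %in% names(env)) stop("variable column not found: ", variable, call. = FALSE)
  common <- intersect(alpha$sample, env$sample)
  if (length(common) < 3) stop("need at least 3 common samples", call. = FALSE)
  y <- alpha[[index]][match(common, alpha$sample)]
  x <- env[[variable]][match(common, env$sample)]
  if (stats::sd(x) == 0) stop("constant predictor: ", variable, call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(common))
}

#' Select abundant genera
#'
#' Keeps a genus if its relative abundance reaches `min_pct` in at least one
#' sample (`>=`, matching the usual "abundant genera" convention).
#'
#' @param rel relative-abundance matrix (percent, genera x samples).
#' @param min_pct threshold in percent (default 1).
#' @return row-subset of `rel`.
#' @export
select_abundant_genera <- function(rel, min_pct = 1) {
  stopifnot(is.matrix(rel), min_pct >= 0)
  rel[apply(rel, 1, max) >= min_pct, , drop = FALSE]
}

#' Redundancy analysis of a community matrix against soil variables
#'
#' Constrained ordination: the community matrix Y (samples x genera,
#' column-centered; optionally Hellinger-transformed) is regressed on the
#' standardized constraint matrix X, and the canonical axes are the
#' principal axes of the fitted values. Eigenvalues are sums of squares
#' divided by n - 1, so their total over all axes equals the total variance
#' of centered Y. Per-axis pseudo-canonical correlations are the
#' correlations between linear-combination site scores and weighted-average
#' site scores. Each variable's marginal (solo-constraint) share of variance
#' is tested by free permutation of the community rows.
#'
#' @param Y samples x genera numeric matrix (e.g. percent abundances).
#' @param X data.frame or matrix of environmental variables (samples x vars).
#' @param hellinger apply the Hellinger transform to Y first (default FALSE).
#' @param n_perm permutations for marginal term tests (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `"rhizo_rda"`: `eigenvalues` (canonical),
#'   `total_variance`, `percent_of_total`, `cumulative_first_two`,
#'   `site_scores` (linear combinations), `wa_scores`, `species_scores`,
#'   `biplot_scores`, `pseudo_canonical_correlation`, `term_effects`.
#' @export
rda_fit <- function(Y, X, hellinger = FALSE, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  stopifnot(is.numeric(Y), is.numeric(X))
  if (nrow(Y) != nrow(X)) stop("Y and X must have aligned samples", call. = FALSE)
  n <- nrow(Y)
  if (ncol(X) >= n) stop("number of constraints must be below the number of samples",
                         call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (hellinger) Y <- sqrt(sweep(Y, 1, rowSums(Y), "/"))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant constraint: ",
                          paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  Xs <- scale(X)
  qrx <- qr(Xs)
  if (qrx$rank < ncol(Xs)) {
    dropped <- colnames(Xs)[qrx$pivot[seq(qrx$rank + 1, ncol(Xs))]]
    stop("collinear constraints: ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- qr.fitted(qrx, Yc)
  sv <- svd(fit)
  tol <- max(sv$d) * 1e-9
  keep <- which(sv$d > tol)
  eig <- sv$d[keep]^2 / (n - 1)
  total <- sum(Yc^2) / (n - 1)
  axes <- paste0("RDA", seq_along(keep))

  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # deterministic axis signs: first species loading positive
  for (k in seq_along(keep)) {
    nz <- which(abs(V[, k]) > 1e-10)[1]
    if (!is.na(nz) && V[nz, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  site_lc <- U %*% diag(sv$d[keep], length(keep)) / sqrt(n - 1)
  wa <- Yc %*% V
  species <- V %*% diag(sqrt(eig), length(keep))
  dimnames(site_lc) <- list(rownames(Y), axes)
  dimnames(wa) <- list(rownames(Y), axes)
  dimnames(species) <- list(colnames(Y), axes)
  pseudo_cc <- vapply(seq_along(keep), function(k) {
    if (stats::sd(wa[, k]) == 0 || stats::sd(site_lc[, k]) == 0) return(NA_real_)
    abs(stats::cor(site_lc[, k], wa[, k]))
  }, numeric(1))
  biplot <- stats::cor(Xs, site_lc)

  pct <- 100 * eig / total
  term_effects <- marginal_terms(Yc, Xs, total, n_perm, seed)

  structure(list(eigenvalues = stats::setNames(eig, axes),
                 total_variance = total,
                 percent_of_total = stats::setNames(pct, axes),
                 cumulative_first_two = sum(pct[seq_len(min(2, length(pct)))]),
                 site_scores = site_lc, wa_scores = wa,
                 species_scores = species, biplot_scores = biplot,
                 pseudo_canonical_correlation = stats::setNames(pseudo_cc, axes),
                 term_effects = term_effects, n = n),
            class = "rhizo_rda")
}

# Solo-constraint variance share per variable, with a free-permutation test
# (rows of Y permuted; P = (1 + #{perm >= obs}) / (1 + n_perm)).
marginal_terms <- function(Yc, Xs, total, n_perm, seed) {
  solo_var <- function(y, x) {
    qrx <- qr(x)
    sum(qr.fitted(qrx, y)^2) / (nrow(y) - 1)
  }
  n <- nrow(Yc)
  out <- lapply(seq_len(ncol(Xs)), function(j) {
    x <- Xs[, j, drop = FALSE]
    obs <- solo_var(Yc, x)
    p <- NA_real_
    if (n_perm > 0) {
      hits <- with_seed(stage_seed(seed, paste0("term", j)), {
        sum(vapply(seq_len(n_perm), function(i) {
          solo_var(Yc[sample(n), , drop = FALSE], x) >= obs - 1e-12
        }, logical(1)))
      })
      p <- (1 + hits) / (1 + n_perm)
    }
    c(percent_explained = 100 * obs / total, p_value = p)
  })
  df <- data.frame(variable = colnames(Xs), do.call(rbind, out),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df[order(-df$percent_explained), ]
}

#' @export
print.rhizo_rda <- function(x, ...) {
  cat("Redundancy analysis:", x$n, "samples,", length(x$eigenvalues), "canonical axes\n")
  cat(sprintf("First two axes explain %.1f%% of total variance\n",
              x$cumulative_first_two))
  cat("Pseudo-canonical correlations:",
      paste(sprintf("%.3f", x$pseudo_canonical_correlation), collapse = ", "), "\n")
  invisible(x)
}
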