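# Rank aggregation, relative abundance, dominance classes, shared-taxon
# accounting and top-k genus selection.

#' Aggregate a count table to a taxonomic rank
#'
#' Sums taxon counts within each phylum/class/genus. Taxa absent from the
#' taxonomy map fall into an explicit `"unclassified"` bucket; column sums
#' are conserved exactly.
#'
#' @param counts taxon-by-sample count matrix.
#' @param taxonomy taxonomy data.frame (taxon, phylum, class, genus).
#' @param rank `"phylum"`, `"class"` or `"genus"`.
#' @return aggregated count matrix (rank groups x samples).
#' @export
aggregate_rank <- function(counts, taxonomy, rank = c("phylum", "class", "genus")) {
  rank <- match.arg(rank)
  validate_count_table(counts)
  validate_taxonomy(taxonomy)
  key <- taxonomy[[rank]][match(rownames(counts), taxonomy$taxon)]
  key[is.na(key)] <- "unclassified"
  out <- rowsum(counts, group = key, reorder = FALSE)
  storage.mode(out) <- "integer"
  out
}

#' Relative abundance (percent per sample)
#'
#' @param counts taxon-by-sample count matrix; every sample total > 0.
#' @return matrix of percentages; every column sums to 100.
#' @export
relative_abundance <- function(counts) {
  validate_count_table(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("empty sample: ", paste(colnames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 100
}

#' Classify taxa as dominant, subdominant or rare
#'
#' A taxon is dominant if its relative abundance exceeds `dominant_min` in
#' every sample considered; otherwise subdominant if it exceeds
#' `subdominant_min` in at least one; otherwise rare. Thresholds are strict
#' (`>`).
#'
#' @param rel relative-abundance matrix (percent, taxa x samples).
#' @param dominant_min dominance threshold in percent (default 5).
#' @param subdominant_min subdominance threshold in percent (default 1).
#' @param samples optional character vector restricting the sample set the
#'   rule is applied over (default: all samples).
#' @return named factor with levels dominant, subdominant, rare.
#' @export
classify_dominance <- function(rel, dominant_min = 5, subdominant_min = 1,
                               samples = NULL) {
  stopifnot(is.matrix(rel))
  for (th in c(dominant_min, subdominant_min)) {
    if (th <= 0 || th >= 100) stop("thresholds must lie in (0, 100)", call. = FALSE)
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(rel))
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "),
                              call. = FALSE)
    rel <- rel[, samples, drop = FALSE]
  }
  lab <- ifelse(apply(rel > dominant_min, 1, all), "dominant",
                ifelse(apply(rel > subdominant_min, 1, any), "subdominant", "rare"))
  factor(stats::setNames(lab, rownames(rel)),
         levels = c("dominant", "subdominant", "rare"))
}

#' Taxa shared by all samples
#'
#' @param counts taxon-by-sample count matrix.
#' @return list with `taxa` (present, i.e. nonzero, in every sample) and
#'   `percent` (per-sample percentage of counts carried by the shared taxa).
#' @export
shared_taxa <- function(counts) {
  validate_count_table(counts)
  shared <- rownames(counts)[apply(counts > 0, 1, all)]
  pct <- colSums(counts[shared, , drop = FALSE]) / colSums(counts) * 100
  list(taxa = shared, percent = pct)
}

#' Union of per-sample top-k taxa
#'
#' Selects, for each sample, the `k` most abundant taxa by relative
#' abundance, and returns the union together with its percent matrix (the
#' usual heatmap input). Ties at rank k are broken by total abundance, then
#' by name. `"unclassified"` buckets are excluded by default.
#'
#' @param counts taxon-by-sample count matrix.
#' @param k taxa retained per sample (default 15).
#' @param exclude_unclassified drop rows named `"unclassified"` first.
#' @return list with `taxa` (union, ordered by decreasing total abundance)
#'   and `percent` (taxa x samples matrix of relative abundances).
#' @export
top_k_union <- function(counts, k = 15, exclude_unclassified = TRUE) {
  validate_count_table(counts)
  stopifnot(k >= 1)
  if (exclude_unclassified) {
    keep <- rownames(counts) != "unclassified"
    counts <- counts[keep, , drop = FALSE]
  }
  rel <- relative_abundance(counts)
  totals <- rowSums(counts)
  union <- character(0)
  for (s in seq_len(ncol(rel))) {
    ord <- order(-rel[, s], -totals, rownames(rel))
    union <- union(union, rownames(rel)[ord[seq_len(min(k, nrow(rel)))]])
  }
  union <- union[order(-totals[union], union)]
  list(taxa = union, percent = rel[union, , drop = FALSE])
}
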