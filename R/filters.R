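# Phase 2-1: ensemble filter scoring. All three criteria (information gain,
# chi-square, symmetrical uncertainty) are computed from one shared
# discretization so they see identical bin-by-class contingency tables.

#' Fit an equal-width discretizer
#'
#' Each feature is min-shifted to zero and cut into `B` equal-width bins over
#' its training range; values outside the training range clamp to the boundary
#' bins. Constant features occupy a single bin.
#'
#' @param Z_train numeric matrix (training rows).
#' @param B number of bins, >= 2 (default 10).
#' @return object of class `hfsof_discretizer` (`min`, `width`, `B`).
#' @export
fit_discretizer <- function(Z_train, B = 10L) {
  if (B < 2L) stop("B must be >= 2")
  Z_train <- as.matrix(Z_train)
  mn <- apply(Z_train, 2L, min)
  rg <- apply(Z_train, 2L, max) - mn
  structure(list(min = mn, width = rg / B, B = as.integer(B)),
            class = "hfsof_discretizer")
}

#' Discretize a matrix with a fitted model
#'
#' @param model an `hfsof_discretizer`.
#' @param Z numeric matrix with matching columns.
#' @return integer matrix of bin ids in `0..B-1`.
#' @export
discretize <- function(model, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != length(model$min)) stop("feature count mismatch")
  B <- model$B
  D <- matrix(0L, nrow(Z), ncol(Z))
  for (j in seq_len(ncol(Z))) {
    w <- model$width[j]
    if (w <= 0) next  # constant feature: all bin 0
    b <- floor((Z[, j] - model$min[j]) / w)
    D[, j] <- as.integer(pmin(pmax(b, 0), B - 1L))
  }
  colnames(D) <- colnames(Z)
  D
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mutual_info_nat <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  p <- tab / n
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
}

contingency <- function(x, y) table(factor(x), factor(y))

#' Information-gain (mutual information) filter scores
#'
#' Plug-in mutual information (natural log) between each discretized feature
#' and the class label.
#'
#' @param D integer matrix of bin ids from [discretize()].
#' @param y integer class labels.
#' @return numeric vector of non-negative scores, one per feature.
#' @export
information_gain_scores <- function(D, y) {
  apply(as.matrix(D), 2L, function(x) mutual_info_nat(contingency(x, y)))
}

#' Chi-square filter scores
#'
#' Pearson chi-square statistic of the bin-by-class contingency table;
#' cells with zero expected count contribute zero.
#'
#' @inheritParams information_gain_scores
#' @return numeric vector of non-negative scores.
#' @export
chi_square_scores <- function(D, y) {
  apply(as.matrix(D), 2L, function(x) {
    tab <- contingency(x, y)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- E > 0
    sum((tab[idx] - E[idx])^2 / E[idx])
  })
}

#' Symmetrical-uncertainty filter scores
#'
#' `SU = 2 I(X;Y) / (H(X) + H(Y))`, in \[0, 1\]; defined as 0 when the
#' denominator vanishes.
#'
#' @inheritParams information_gain_scores
#' @return numeric vector of scores in \[0, 1\].
#' @export
symmetrical_uncertainty_scores <- function(D, y) {
  hy <- entropy_nat(table(y))
  apply(as.matrix(D), 2L, function(x) {
    tab <- contingency(x, y)
    hx <- entropy_nat(rowSums(tab))
    den <- hx + hy
    if (den <= 0) return(0)
    2 * mutual_info_nat(tab) / den
  })
}

#' Convert scores to relevance ranks
#'
#' Descending scores map to ascending ranks starting at 1 (smaller rank =
#' more relevant); ties get the average of their covered positions.
#'
#' @param scores finite numeric vector.
#' @return numeric rank vector (sums to `p(p+1)/2`).
#' @export
rank_features <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  rank(-scores, ties.method = "average")
}

#' Median rank fusion
#'
#' Elementwise median of the three per-filter rank vectors.
#'
#' @param r_ig,r_cs,r_su equal-length rank vectors.
#' @return fused rank vector.
#' @export
median_fuse <- function(r_ig, r_cs, r_su) {
  if (length(r_ig) != length(r_cs) || length(r_cs) != length(r_su)) {
    stop("rank vectors must have equal length")
  }
  apply(cbind(r_ig, r_cs, r_su), 1L, stats::median)
}

#' Mean rank fusion (ablation variant)
#'
#' @inheritParams median_fuse
#' @return fused rank vector (elementwise arithmetic mean).
#' @export
mean_fuse <- function(r_ig, r_cs, r_su) {
  if (length(r_ig) != length(r_cs) || length(r_cs) != length(r_su)) {
    stop("rank vectors must have equal length")
  }
  (r_ig + r_cs + r_su) / 3
}

#' Build the full filter rank table
#'
#' Computes the three filter scores on a shared discretization, their rank
#' vectors, and the fused rank according to `mode`.
#'
#' @param Z_train embedded training matrix.
#' @param y training labels.
#' @param B bin count for the shared discretizer.
#' @param mode one of `fusion_median` (default), `fusion_mean`, `ig_only`,
#'   `cs_only`, `su_only`. Single-filter modes bypass fusion: the fused rank
#'   is exactly that filter's rank vector.
#' @return a data.frame of class `hfsof_rank_table`: `feature_id`, `ig`,
#'   `chi2`, `su`, `r_ig`, `r_cs`, `r_su`, `r_fused`.
#' @export
filter_rank_table <- function(Z_train, y, B = 10L,
                              mode = c("fusion_median", "fusion_mean",
                                       "ig_only", "cs_only", "su_only")) {
  mode <- match.arg(mode)
  disc <- fit_discretizer(Z_train, B)
  D <- discretize(disc, Z_train)
  ig <- information_gain_scores(D, y)
  cs <- chi_square_scores(D, y)
  su <- symmetrical_uncertainty_scores(D, y)
  r_ig <- rank_features(ig)
  r_cs <- rank_features(cs)
  r_su <- rank_features(su)
  r_fused <- switch(mode,
    fusion_median = median_fuse(r_ig, r_cs, r_su),
    fusion_mean = mean_fuse(r_ig, r_cs, r_su),
    ig_only = r_ig, cs_only = r_cs, su_only = r_su)
  out <- data.frame(feature_id = seq_along(ig), ig = ig, chi2 = cs, su = su,
                    r_ig = r_ig, r_cs = r_cs, r_su = r_su, r_fused = r_fused,
                    row.names = NULL)
  if (!is.null(colnames(Z_train))) out$feature <- colnames(Z_train)
  class(out) <- c("hfsof_rank_table", class(out))
  attr(out, "mode") <- mode
  out
}

#' Select the candidate pool from fused ranks
#'
#' Indices of the `m` smallest fused ranks; ties at the cutoff broken by
#' ascending feature index. Output ordered by fused rank, then index.
#'
#' @param fused fused rank vector.
#' @param m pool size, `1 <= m <= length(fused)`.
#' @return integer vector of feature indices.
#' @export
select_candidate_pool <- function(fused, m) {
  p <- length(fused)
  if (m < 1L || m > p) stop("pool size m must be in 1..", p)
  ord <- order(fused, seq_len(p))
  ord[seq_len(m)]
}
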