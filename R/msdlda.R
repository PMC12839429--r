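# Phase 2-2: maximum-scatter-difference discriminant thresholding. Each
# pooled feature j gets the univariate score MS_j = SB(j) - SW(j), where
#   SB(j) = sum_c n_c (mu_{j,c} - mu_j)^2   (support-weighted between-class)
#   SW(j) = sum_c sum_{i in c} (x_{i,j} - mu_{j,c})^2  (unnormalized within)
# and features at or above the (1 - alpha) quantile of MS survive. Using the
# scatter *difference* avoids the matrix inversion of Fisher-ratio LDA.

#' Scatter components and scatter-difference scores
#'
#' @param Z_pool numeric N x m matrix (the filter-selected candidate pool).
#' @param y integer labels with at least two classes present.
#' @return data.frame with columns `sb`, `sw`, `ms` (one row per feature).
#' @export
msdlda_components <- function(Z_pool, y) {
  Z_pool <- as.matrix(Z_pool)
  cls <- sort(unique(y))
  if (length(cls) < 2L) stop("MSDLDA needs at least two classes")
  mu <- colMeans(Z_pool)
  sb <- numeric(ncol(Z_pool))
  sw <- numeric(ncol(Z_pool))
  for (c in cls) {
    rows <- y == c
    nc <- sum(rows)
    muc <- colMeans(Z_pool[rows, , drop = FALSE])
    sb <- sb + nc * (muc - mu)^2
    sw <- sw + colSums(sweep(Z_pool[rows, , drop = FALSE], 2L, muc)^2)
  }
  data.frame(sb = sb, sw = sw, ms = sb - sw)
}

#' Scatter-difference scores only
#'
#' @inheritParams msdlda_components
#' @return numeric vector `MS_j = SB(j) - SW(j)`; larger = more discriminative.
#' @export
msdlda_scores <- function(Z_pool, y) msdlda_components(Z_pool, y)$ms

#' Threshold scatter-difference scores at the (1 - alpha) quantile
#'
#' The threshold is the empirical `(1 - alpha)` quantile of the scores under
#' the linear-interpolation convention (`stats::quantile` type 7); features
#' with `MS >= tau` survive. Smaller `alpha` prunes harder.
#'
#' @param MS numeric score vector.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return list with `tau` (threshold) and `S0` (ascending surviving indices).
#' @export
threshold_select <- function(MS, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tau <- unname(stats::quantile(MS, probs = 1 - alpha, type = 7))
  S0 <- which(MS >= tau)
  if (length(S0) < 2L) {
    stop("wrapper needs >= 2 candidate features above the MSDLDA threshold")
  }
  list(tau = tau, S0 = S0)
}

#' Full MSDLDA stage
#'
#' @inheritParams msdlda_components
#' @inheritParams threshold_select
#' @return object of class `hfsof_msdlda`: the component table plus `tau`,
#'   `alpha`, `S0` (indices into the pool columns), and a `selected` flag.
#' @export
msdlda_select <- function(Z_pool, y, alpha = 0.05) {
  comp <- msdlda_components(Z_pool, y)
  sel <- threshold_select(comp$ms, alpha)
  comp$selected <- seq_len(nrow(comp)) %in% sel$S0
  structure(list(table = comp, tau = sel$tau, alpha = alpha, S0 = sel$S0),
            class = "hfsof_msdlda")
}
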