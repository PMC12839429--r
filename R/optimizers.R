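# Phase 3: wrapper search over binary feature masks on the MSDLDA survivors.
# Individuals live in [0,1]^d; masks are position > 1/2, repaired to keep at
# least two features. The Whale Migration Algorithm splits the ranked
# population into leaders (random exploratory steps) and followers (moves
# toward the leader mean and global best), with strictly-greedy acceptance.
# A canonical global-best PSO is provided as the comparison baseline.

#' Binarize a position vector into a feature mask
#'
#' Strict threshold `b_j = 1` iff `p_j > 1/2`. If fewer than two features
#' result, the two largest-position indices are forced to 1 (ties broken by
#' lower index).
#'
#' @param position numeric vector with entries in \[0, 1\].
#' @return integer 0/1 mask with `sum(mask) >= 2`.
#' @export
binarize_position <- function(position) {
  mask <- as.integer(position > 0.5)
  if (sum(mask) < 2L) {
    top2 <- order(-position, seq_along(position))[1:2]
    mask[top2] <- 1L
  }
  mask
}

new_trace <- function() {
  list(iteration = integer(0), best_fitness = numeric(0),
       mean_fitness = numeric(0), n_selected = integer(0))
}

push_trace <- function(tr, it, fit_vec, best_mask) {
  tr$iteration <- c(tr$iteration, it)
  tr$best_fitness <- c(tr$best_fitness, max(fit_vec))
  tr$mean_fitness <- c(tr$mean_fitness, mean(fit_vec))
  tr$n_selected <- c(tr$n_selected, sum(best_mask))
  tr
}

finish_trace <- function(tr, best_position, best_mask, best_fitness, spec) {
  structure(list(trace = as.data.frame(tr), best_position = best_position,
                 best_mask = best_mask, best_fitness = best_fitness,
                 n_evaluations = spec$n_eval$count %||% 0L,
                 n_cache_hits = spec$n_eval$hits %||% 0L),
            class = "hfsof_trace")
}

#' @export
print.hfsof_trace <- function(x, ...) {
  cat(sprintf("<hfsof_trace> %d iterations, best fitness %.4f, %d features, %d evaluations (%d cache hits)\n",
              nrow(x$trace), x$best_fitness, sum(x$best_mask),
              x$n_evaluations, x$n_cache_hits))
  invisible(x)
}

#' Whale Migration Algorithm wrapper search
#'
#' Positions start uniform in `[0,1]^d`. Each (synchronous) iteration ranks
#' the population by fitness; the top `ceiling(n_pop/2)` are leaders. A
#' leader proposes `clip(p + u * v, 0, 1)` with `u ~ U(-1,1)^d`,
#' `v ~ U(0,1)^d`; a follower proposes
#' `clip(m + r1 * (p_prev - p) + r2 * (p_best - m), 0, 1)` with
#' `r1, r2 ~ U(0,1)^d`, where `m` is the start-of-iteration mean leader
#' position, `p_best` the start-of-iteration best individual, and `p_prev`
#' the individual's own position one iteration earlier. A move is accepted
#' only if its mask's fitness strictly improves, so the best fitness is
#' non-decreasing.
#'
#' @param spec an [fitness_spec()].
#' @param n_pop population size (>= 2; method default 45).
#' @param iterations iteration budget T (method default 100).
#' @param seed integer seed (all randomness flows from it).
#' @return an `hfsof_trace`: per-iteration trace data.frame, `best_position`,
#'   `best_mask`, `best_fitness`, evaluation/cache counters.
#' @export
run_wma <- function(spec, n_pop = 45L, iterations = 100L, seed = 1L) {
  d <- ncol(spec$Z)
  if (d < 2L) stop("wrapper needs >= 2 candidate features")
  if (n_pop < 2L || iterations < 1L) stop("need n_pop >= 2 and iterations >= 1")
  withr::with_seed(seed, {
    P <- matrix(runif(n_pop * d), n_pop, d)
    P_prev <- P
    fit <- apply(P, 1L, function(p) evaluate_fitness(binarize_position(p), spec))
    tr <- push_trace(new_trace(), 0L, fit, binarize_position(P[which.max(fit), ]))
    for (t in seq_len(iterations)) {
      ord <- order(-fit, seq_len(n_pop))   # rank by fitness, stable
      n_lead <- ceiling(n_pop / 2)
      leaders <- ord[seq_len(n_lead)]
      m_t <- colMeans(P[leaders, , drop = FALSE])
      p_star <- P[ord[1L], ]
      P_old <- P
      for (i in seq_len(n_pop)) {
        if (i %in% leaders) {
          u <- runif(d, -1, 1); v <- runif(d)
          cand <- P[i, ] + u * v
        } else {
          r1 <- runif(d); r2 <- runif(d)
          cand <- m_t + r1 * (P_prev[i, ] - P[i, ]) + r2 * (p_star - m_t)
        }
        cand <- pmin(pmax(cand, 0), 1)
        f_new <- evaluate_fitness(binarize_position(cand), spec)
        if (f_new > fit[i]) {   # strict greedy acceptance
          P[i, ] <- cand
          fit[i] <- f_new
        }
      }
      P_prev <- P_old
      tr <- push_trace(tr, t, fit, binarize_position(P[which.max(fit), ]))
    }
    best <- which.max(fit)
    finish_trace(tr, P[best, ], binarize_position(P[best, ]), fit[best], spec)
  })
}

#' Global-best PSO wrapper search (comparison baseline)
#'
#' Canonical global-best particle swarm over the same `[0,1]^d` space with
#' inertia 0.729, cognitive = social = 1.49445, velocity clamp 0.5, and the
#' same binarization/repair/fitness as [run_wma()]. Personal and global bests
#' never worsen, so the reported best fitness is non-decreasing.
#'
#' @inheritParams run_wma
#' @return an `hfsof_trace`.
#' @export
run_pso <- function(spec, n_pop = 45L, iterations = 100L, seed = 1L) {
  d <- ncol(spec$Z)
  if (d < 2L) stop("wrapper needs >= 2 candidate features")
  if (n_pop < 2L || iterations < 1L) stop("need n_pop >= 2 and iterations >= 1")
  w <- 0.729; c1 <- 1.49445; c2 <- 1.49445; vmax <- 0.5
  withr::with_seed(seed, {
    P <- matrix(runif(n_pop * d), n_pop, d)
    V <- matrix(runif(n_pop * d, -vmax, vmax), n_pop, d)
    fit <- apply(P, 1L, function(p) evaluate_fitness(binarize_position(p), spec))
    Pbest <- P; fbest <- fit
    g <- which.max(fbest)
    gbest <- Pbest[g, ]; gfit <- fbest[g]
    tr <- push_trace(new_trace(), 0L, fbest, binarize_position(gbest))
    for (t in seq_len(iterations)) {
      for (i in seq_len(n_pop)) {
        r1 <- runif(d); r2 <- runif(d)
        V[i, ] <- w * V[i, ] + c1 * r1 * (Pbest[i, ] - P[i, ]) +
          c2 * r2 * (gbest - P[i, ])
        V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
        P[i, ] <- pmin(pmax(P[i, ] + V[i, ], 0), 1)
        f_new <- evaluate_fitness(binarize_position(P[i, ]), spec)
        if (f_new > fbest[i]) {
          Pbest[i, ] <- P[i, ]
          fbest[i] <- f_new
        }
        if (f_new > gfit) {
          gbest <- P[i, ]
          gfit <- f_new
        }
      }
      tr <- push_trace(tr, t, fbest, binarize_position(gbest))
    }
    finish_trace(tr, gbest, binarize_position(gbest), gfit, spec)
  })
}

#' Exhaustive search over all admissible masks (test oracle)
#'
#' Enumerates every mask with at least two selected features (there are
#' `2^d - 1 - d` of them) and returns the maximum-fitness mask, ties broken
#' by lexicographically smallest mask.
#'
#' @param spec an [fitness_spec()].
#' @param d mask length; refused above 15.
#' @return list with `best_mask` and `best_fitness`.
#' @export
exhaustive_search <- function(spec, d = ncol(spec$Z)) {
  if (d > 15L) stop("exhaustive search refused for d > 15")
  best_mask <- NULL
  best_fit <- -Inf
  for (code in 0:(2^d - 1)) {
    # first mask bit as most-significant digit => ascending code enumerates
    # masks in lexicographic order, so first-max retention = lex tie-break
    mask <- rev(as.integer(intToBits(code)[1:d]))
    if (sum(mask) < 2L) next
    f <- evaluate_fitness(mask, spec)
    if (f > best_fit) {   # enumeration order = lexicographic tie-break
      best_fit <- f
      best_mask <- mask
    }
  }
  list(best_mask = best_mask, best_fitness = best_fit)
}
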