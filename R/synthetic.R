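# Synthetic data generators: (a) ultrasound-like grayscale phantoms with
# class-dependent intensity/lesion structure, multiplicative Rayleigh speckle
# and additive Gaussian noise, mimicking a strongly imbalanced six-class
# clinical archive; (b) feature tables with planted informative columns for
# selection-recovery tests. Everything is driven by one seeded generator per
# call; no global RNG state leaks.

# Rayleigh with unit mean: scale sigma = 1/sqrt(pi/2)
rrayleigh_unit <- function(n) sqrt(2 / pi) * sqrt(-2 * log(runif(n)))

default_phantom_counts <- function(scale = 0.1) {
  # the clinical archive's imbalance profile (238..3464 per class) scaled down
  pmax(4L, as.integer(round(c(1183, 660, 238, 1392, 743, 3464) * scale)))
}

#' Specification for phantom image generation
#'
#' @param n_class number of classes (default 6).
#' @param counts per-class image counts; default mimics a strongly imbalanced
#'   clinical archive scaled by `scale`.
#' @param scale down-scaling factor applied to the default counts.
#' @param size image size `c(height, width)`, at least 16 x 16.
#' @param speckle Rayleigh speckle mixing weight in \[0, 1\] (0 = no speckle).
#' @param noise_sd additive Gaussian noise SD.
#' @param contrast multiplier on all class-dependent structure; 0 makes all
#'   classes identical in expectation (null generator).
#' @param seed integer seed fixing the full output.
#' @return a `hfsof_phantom_spec` list.
#' @export
phantom_spec <- function(n_class = 6L, counts = NULL, scale = 0.1,
                         size = c(32L, 32L), speckle = 0.35, noise_sd = 0.03,
                         contrast = 1, seed = 1L) {
  if (is.null(counts)) counts <- default_phantom_counts(scale)[seq_len(n_class)]
  if (length(counts) != n_class) stop("counts length must equal n_class")
  if (any(counts < 1L)) stop("counts must be >= 1")
  if (any(size < 16L)) stop("image size must be at least 16 x 16")
  structure(list(n_class = as.integer(n_class), counts = as.integer(counts),
                 size = as.integer(size), speckle = speckle,
                 noise_sd = noise_sd, contrast = contrast,
                 seed = as.integer(seed)),
            class = "hfsof_phantom_spec")
}

phantom_one <- function(spec, class_id) {
  h <- spec$size[1]; w <- spec$size[2]
  k <- spec$contrast
  C <- spec$n_class
  # class-specific mean band: evenly spaced base levels, pulled toward a
  # common gray as contrast -> 0
  base0 <- 0.5
  base <- base0 + k * (0.15 + 0.7 * class_id / max(1L, C - 1L) - base0)
  img <- matrix(base, h, w)
  # horizontal echo band whose vertical position/width depends on the class
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  band_c <- h * (0.25 + 0.5 * ((class_id * 2L) %% C) / C)
  band_w <- h * (0.08 + 0.05 * (class_id %% 3L))
  img <- img + k * 0.25 * exp(-((yy - band_c)^2) / (2 * band_w^2))
  # 0..3 elliptical "lesions", count and contrast class-dependent
  n_les <- class_id %% 4L
  if (n_les > 0L) {
    for (l in seq_len(n_les)) {
      cy <- runif(1, 0.25 * h, 0.75 * h)
      cx <- runif(1, 0.25 * w, 0.75 * w)
      ry <- runif(1, 0.08, 0.18) * h
      rx <- runif(1, 0.08, 0.18) * w
      amp <- k * (if (class_id %% 2L == 0L) -0.35 else 0.3)
      img <- img + amp * exp(-(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2))
    }
  }
  # first-order ultrasound speckle surrogate: unit-mean Rayleigh factor,
  # mixed in with weight `speckle`, plus additive Gaussian noise
  fac <- (1 - spec$speckle) + spec$speckle * rrayleigh_unit(h * w)
  img <- img * matrix(fac, h, w) + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
  pmin(pmax(img, 0), 1)
}

#' Generate an ultrasound-like phantom image set
#'
#' Each image is a class-dependent base pattern (mean intensity level, an
#' echo band, 0-3 elliptical lesions with class-specific polarity) corrupted
#' by multiplicative unit-mean Rayleigh speckle and additive Gaussian noise.
#' Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @return an `hfsof_imageset` (consumable by [to_feature_dataset()]).
#' @export
generate_phantoms <- function(spec) {
  stopifnot(inherits(spec, "hfsof_phantom_spec"))
  withr::with_seed(stage_seed(spec$seed, "phantom"), {
    images <- list(); labels <- integer(0)
    for (c in seq_len(spec$n_class) - 1L) {
      for (i in seq_len(spec$counts[c + 1L])) {
        images[[length(images) + 1L]] <- phantom_one(spec, c)
        labels <- c(labels, c)
      }
    }
    structure(list(images = images, labels = labels,
                   class_names = sprintf("lesion_%d", seq_len(spec$n_class) - 1L),
                   source_paths = rep(NA_character_, length(images))),
              class = "hfsof_imageset")
  })
}

#' Write an image set to the directory layout the loader reads
#'
#' One subdirectory per class, ASCII PGM files.
#'
#' @param raw an `hfsof_imageset`.
#' @param out_dir output root directory.
#' @export
write_image_dataset <- function(raw, out_dir) {
  for (ci in seq_along(raw$class_names)) {
    d <- file.path(out_dir, raw$class_names[ci])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    idx <- which(raw$labels == ci - 1L)
    for (k in seq_along(idx)) {
      write_pgm(raw$images[[idx[k]]], file.path(d, sprintf("img_%04d.pgm", k)))
    }
  }
  invisible(out_dir)
}

#' Generate a feature table with planted informative columns
#'
#' Informative columns are `Normal(mu_c, 1)` with class means spaced `delta`
#' standard deviations apart; the rest are label-independent `Normal(0, 1)`
#' noise. Labels honor the requested class proportions within one sample.
#'
#' @param n samples, @param d features, @param k planted informative columns.
#' @param delta class-mean separation in SD units (0 = null data).
#' @param n_class number of classes (default 4).
#' @param proportions per-class proportions (default balanced).
#' @param seed integer seed.
#' @return list with `dataset` (an [hfsof_dataset]) and `truth` (the planted
#'   column indices).
#' @export
generate_planted_features <- function(n = 300L, d = 50L, k = 5L, delta = 3,
                                      n_class = 4L, proportions = NULL,
                                      seed = 1L) {
  if (k >= d) stop("k must be < d")
  if (delta < 0) stop("delta must be >= 0")
  if (is.null(proportions)) proportions <- rep(1 / n_class, n_class)
  proportions <- proportions / sum(proportions)
  withr::with_seed(stage_seed(seed, "planted"), {
    counts <- floor(n * proportions)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(n * proportions - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    y <- rep(seq_len(n_class) - 1L, counts)
    X <- matrix(rnorm(n * d), n, d)
    truth <- seq_len(k)
    for (j in truth) {
      # class means evenly spaced over a total spread of delta SDs, in a
      # per-column random class order so planted columns are not redundant;
      # a single column is informative but not sufficient, so recovering all
      # classes genuinely needs several planted columns
      mu <- sample(seq_len(n_class) - 1L) / (n_class - 1L) * delta
      X[, j] <- X[, j] + mu[y + 1L]
    }
    perm <- sample(n)  # shuffle row order
    ds <- hfsof_dataset(X[perm, , drop = FALSE], y[perm],
                        feature_names = sprintf("f%04d", seq_len(d)))
    list(dataset = ds, truth = truth)
  })
}
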