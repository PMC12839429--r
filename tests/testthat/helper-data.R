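# Shared in-code fixtures. Everything is generated at test time; no files.

# two well-separated Gaussian blobs in 2-D (margin >> 1)
make_separable_2class <- function(n_per = 30L, gap = 8, seed = 101L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per, -gap / 2, 0.5), n_per, 2),
               matrix(rnorm(2 * n_per, gap / 2, 0.5), n_per, 2))
    y <- rep(0:1, each = n_per)
    list(X = X, y = y)
  })
}

# labels with requested per-class counts, plus pure-noise features
make_noise_dataset <- function(n = 80L, d = 6L, C = 2L, seed = 202L) {
  withr::with_seed(seed, {
    y <- rep_len(0:(C - 1L), n)
    X <- matrix(rnorm(n * d), n, d)
    list(X = X, y = y)
  })
}

random_confusion <- function(C, max_count = 40L) {
  matrix(sample(0:max_count, C * C, replace = TRUE), C, C)
}

# tiny in-memory image set for flatten/IO tests
make_tiny_imageset <- function() {
  structure(list(
    images = list(matrix(c(0, 255, 255, 0), 2, 2, byrow = TRUE),
                  matrix(0, 2, 2),
                  matrix(c(255, 255, 0, 0), 2, 2, byrow = TRUE)),
    labels = c(0L, 0L, 1L),
    class_names = c("a", "b"),
    source_paths = rep(NA_character_, 3)), class = "hfsof_imageset")
}
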