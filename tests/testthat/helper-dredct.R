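# Shared fixtures, built in code. The small dataset (8 images/class at side
# 64) is generated once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixtures$manifest)) {
    dir <- file.path(tempdir(), "dredct-small-dataset")
    .fixtures$manifest <- generate_dataset(8, side = 64, seed = 11, dir = dir)
    .fixtures$dir <- dir
  }
  .fixtures$manifest
}

small_train_config <- function(seed = 5L, side = 64L) {
  train_config(learning_rate = 0.05, batch_size = 16, epochs = 10,
               input_side = side, seed = seed)
}

# Independent DCT-II basis built from the textbook formula, for oracles.
ref_dct_basis <- function(n) {
  C <- matrix(0, n, n)
  for (k in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      a <- if (k == 0) 1 / sqrt(2) else 1
      C[k + 1, j + 1] <- sqrt(2 / n) * a * cos((2 * j + 1) * k * pi / (2 * n))
    }
  }
  C
}

random_image <- function(side = 32, seed = 1) {
  withr::with_seed(seed, rgb_image(array(stats::runif(side * side * 3, 0, 255),
                                         dim = c(side, side, 3))))
}
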