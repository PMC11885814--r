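# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a small two-class dataset with images, used across NN tests
small_dataset <- function() {
  fixture("small_dataset", function() {
    make_dataset(complementarity_config(n_per_class = c(A = 40, B = 40),
                                        seed = 11))
  })
}

small_encoder_config <- function() {
  encoder_config(input_size = c(32, 32), base_filters = 8)
}

small_miml_config <- function() {
  miml_config(encoder = small_encoder_config())
}

# labelled feature table with fold assignments, no images
feature_table <- function(n_per_class = 300, seed = 1, gap = 0.06) {
  with_seed <- mimlr:::with_seed
  with_seed(seed, {
    n <- n_per_class
    tibble::tibble(
      DI = c(stats::rnorm(n, 0.5 - gap / 2, 0.09),
             stats::rnorm(n, 0.5 + gap / 2, 0.09)),
      TT = stats::runif(2 * n),
      vmax = stats::runif(2 * n),
      label = factor(rep(c("A", "B"), each = n)),
      fold = rep_len(1:5, 2 * n))
  })
}

expect_setequal_num <- function(a, b, tol = 1e-12) {
  expect_equal(sort(a), sort(b), tolerance = tol)
}
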