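# Independent oracles and fixture builders used across the suite.

# Brute-force Pincus ApEn: explicit embedding + Chebyshev distance matrix
# via stats::dist. Self-matches are on the diagonal of the full matrix.
apen_bruteforce <- function(x, m = 2, r = 0.2 * sd(x)) {
  phi <- function(mm) {
    emb <- stats::embed(x, mm)[, mm:1, drop = FALSE]
    d <- as.matrix(stats::dist(emb, method = "maximum"))
    mean(log(rowMeans(d <= r)))
  }
  phi(m) - phi(m + 1)
}

# Inverse-CDF draw from a Pareto density ~ x^-mu truncated to [a, b],
# written independently of the package internals.
draw_trunc_powerlaw <- function(n, mu, a, b) {
  u <- stats::runif(n)
  e <- 1 - mu
  (a^e + u * (b^e - a^e))^(1 / e)
}

# Two well-separated classes of short synthetic electromes: quiet
# low-amplitude noise vs high-amplitude spiky signal.
separable_electromes <- function(n_per_class = 10, n_samples = 5000,
                                 seed = 1) {
  quiet <- lapply(seq_len(n_per_class), function(i) {
    generate_colored_noise(n_samples, beta = 1.7, sigma = 0.02, seed = seed + i)
  })
  spiky <- lapply(seq_len(n_per_class), function(i) {
    base <- generate_colored_noise(n_samples,
      beta = 1.7, sigma = 0.02,
      seed = seed + 1000 + i
    )
    base + 4 * sin(2 * pi * seq_len(n_samples) / 500)
  })
  list(
    series = c(quiet, spiky),
    labels = rep(c("quiet", "spiky"), each = n_per_class)
  )
}

# Balanced random-label interval-feature dataset: class labels carry no
# information about the features.
null_dataset <- function(n_samples, n_classes, n_features = 9, seed = 1) {
  set.seed(seed)
  labels <- sample(rep(letters[seq_len(n_classes)], length.out = n_samples))
  df <- as.data.frame(matrix(rnorm(n_samples * n_features), n_samples))
  names(df) <- paste0("f", seq_len(n_features))
  cbind(data.frame(label = labels), df)
}
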