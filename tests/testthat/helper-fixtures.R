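# Shared fixtures, all built in code at test time.

# small random autoencoder with reproducible weights
tiny_ae <- function(d = 3L, h = 4L, seed = 1L, scale = 0.8) {
  set.seed(seed)
  autoencoder_params(
    W = matrix(runif(d * h, -scale, scale), d, h),
    b1 = runif(h, -scale, scale),
    V = matrix(runif(h * d, -scale, scale), h, d),
    b2 = runif(d, -scale, scale))
}

# random binary matrix
random_binary <- function(n, d, seed = 1L) {
  set.seed(seed)
  matrix(rbinom(n * d, 1L, 0.5), n, d)
}

# two well-separated Gaussian blobs in code space
two_blobs <- function(n_per = 20L, h = 2L, sep = 5, sd = 0.1, seed = 1L) {
  set.seed(seed)
  centers <- rbind(rep(0, h), rep(sep, h))
  X <- rbind(
    matrix(rnorm(n_per * h, 0, sd), n_per, h) +
      centers[rep(1L, n_per), , drop = FALSE],
    matrix(rnorm(n_per * h, 0, sd), n_per, h) +
      centers[rep(2L, n_per), , drop = FALSE])
  list(X = X, means = centers,
       labels = rep(0:1, each = n_per))
}

# published evaluation confusion matrices shipped as plain CSV
read_confusion_fixture <- function(name) {
  path <- system.file("extdata", name, package = "lissarbf")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  as_confusion(as.matrix(utils::read.csv(path, header = FALSE)))
}

# printed per-activity accuracy rows (integer percent) of the two
# published OrdonezB confusion matrices, verified by hand before freezing
PRINTED_ACC_LISSA_RBF <- c(36, 27, 88, 100, 23, 100, 93, 68, 99, 97)
PRINTED_ACC_RBF_LGEM  <- c(36, 0, 88, 100, 31, 100, 93, 64, 97, 97)

# brute-force Monte-Carlo estimate of the sensitivity measure, the
# independent oracle for the Halton-based estimator
mc_sensitivity <- function(params, X, Q, n_samples = 10000L, seed = 1L) {
  set.seed(seed)
  n <- nrow(X); d <- ncol(X)
  Y0 <- ae_forward(X, params)$Y
  total <- 0
  for (j in seq_len(n_samples)) {
    dx <- runif(d, -Q, Q)
    Yj <- ae_forward(X + rep(dx, each = n), params)$Y
    total <- total + sum((Y0 - Yj)^2) / n
  }
  total / n_samples
}
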