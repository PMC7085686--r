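# Sigmoid autoencoder and its stochastic-sensitivity-regularized training.
#
# The model is a single-hidden-layer autoencoder
#   C = sigmoid(X W + b1),  Y = sigmoid(C V + b2)
# trained by full-batch gradient descent on
#   R + w * STSM
# where R is the mean squared reconstruction error and STSM is the
# stochastic sensitivity measure: the mean squared change of the
# reconstruction under perturbations of the input drawn from the
# Q-neighborhood [-Q, Q]^d by a deterministic Halton point set.

#' Numerically stable logistic sigmoid
#'
#' Computes `1 / (1 + exp(-x))` elementwise without overflow for large
#' negative arguments.
#'
#' @param x numeric vector or matrix.
#' @return Same shape as `x`, entries in (0, 1).
#' @export
sigmoid <- function(x) {
  stats::plogis(x)
}

#' Construct autoencoder parameters
#'
#' @param W d x h encoder weight matrix.
#' @param b1 length-h encoder bias.
#' @param V h x d decoder weight matrix.
#' @param b2 length-d decoder bias.
#' @return An `autoencoder` object (list of the four arrays plus `d`, `h`).
#' @export
autoencoder_params <- function(W, b1, V, b2) {
  W <- as.matrix(W); V <- as.matrix(V)
  b1 <- as.numeric(b1); b2 <- as.numeric(b2)
  d <- nrow(W); h <- ncol(W)
  if (nrow(V) != h || ncol(V) != d)
    stop("decoder matrix must be h x d to match the encoder")
  if (length(b1) != h || length(b2) != d)
    stop("bias lengths must match hidden and input widths")
  if (!all(is.finite(W)) || !all(is.finite(V)) ||
      !all(is.finite(b1)) || !all(is.finite(b2)))
    stop("autoencoder parameters must be finite")
  structure(list(W = W, b1 = b1, V = V, b2 = b2, d = d, h = h),
            class = "autoencoder")
}

#' Autoencoder forward pass
#'
#' @param X numeric matrix, N x d.
#' @param params an `autoencoder` object.
#' @return List with `C` (N x h hidden codes) and `Y` (N x d
#'   reconstructions), all entries in (0, 1).
#' @export
ae_forward <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != params$d)
    stop("X has ", ncol(X), " columns but the autoencoder expects ", params$d)
  C <- sigmoid(add_bias(X %*% params$W, params$b1))
  Y <- sigmoid(add_bias(C %*% params$V, params$b2))
  list(C = C, Y = Y)
}

#' Encode instances to hidden codes
#'
#' The feature-extraction map used by the downstream RBF classifier.
#'
#' @inheritParams ae_forward
#' @return N x h matrix of hidden codes in (0, 1).
#' @export
encode <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != params$d)
    stop("X has ", ncol(X), " columns but the autoencoder expects ", params$d)
  sigmoid(add_bias(X %*% params$W, params$b1))
}

# add a row vector to every row without sweep()'s copies
add_bias <- function(M, b) M + rep(b, each = nrow(M))

#' Mean squared reconstruction error
#'
#' `R = (1/N) sum_i ||Y_i - X_i||^2`, the plain autoencoder training loss.
#'
#' @param Y reconstruction matrix.
#' @param X input matrix of the same shape.
#' @return Non-negative scalar; zero iff `Y == X`.
#' @export
reconstruction_mse <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (!all(dim(Y) == dim(X))) stop("Y and X must have identical shape")
  sum((Y - X)^2) / nrow(X)
}

#' Halton low-discrepancy point set
#'
#' Coordinate m of the sequence is the van der Corput sequence in the m-th
#' prime base (2, 3, 5, ...), starting at index 1 with no burn-in or
#' scrambling. The construction is deterministic.
#'
#' @param J number of points.
#' @param d dimension.
#' @return J x d matrix with entries in `[0, 1)`.
#' @examples
#' halton_points(3, 2)   # base-2 and base-3 van der Corput columns
#' @export
halton_points <- function(J, d) {
  J <- as.integer(J); d <- as.integer(d)
  if (J < 1L || d < 1L) stop("J and d must be at least 1")
  bases <- first_primes(d)
  out <- matrix(0, J, d)
  for (m in seq_len(d)) {
    b <- bases[m]
    for (j in seq_len(J)) {
      n <- j; f <- 1 / b; x <- 0
      while (n > 0L) {
        x <- x + f * (n %% b)
        n <- n %/% b
        f <- f / b
      }
      out[j, m] <- x
    }
  }
  out
}

first_primes <- function(k) {
  out <- integer(0)
  n <- 1L
  while (length(out) < k) {
    n <- n + 1L
    if (all(n %% out != 0L)) out <- c(out, n)
  }
  out
}

#' Q-neighborhood perturbation set
#'
#' Maps Halton points from the unit cube onto `[-Q, Q]^d`, giving the J
#' fixed offsets used by the stochastic sensitivity estimator. The same
#' set is shared across instances and epochs.
#'
#' @param Q neighborhood half-width, in feature units (non-negative).
#' @param J number of perturbation points (default 50).
#' @param d input dimension.
#' @return A `perturbation_set`: list with `Q`, `J`, `d` and `offsets`
#'   (J x d, entries in `[-Q, Q]`).
#' @export
perturbation_set <- function(Q, J = 50L, d) {
  if (Q < 0) stop("Q must be non-negative")
  offsets <- 2 * Q * halton_points(J, d) - Q
  structure(list(Q = Q, J = as.integer(J), d = as.integer(d),
                 offsets = offsets),
            class = "perturbation_set")
}

#' Stochastic sensitivity measure of an autoencoder
#'
#' Quasi-Monte-Carlo estimate of the expected squared output change over
#' the Q-neighborhood:
#' `STSM = (1/(N J)) sum_i sum_j ||g(X_i) - g(X_i + dX_j)||^2`
#' with `g` the full encode-decode map. `scaling = "sum"` drops the `1/J`
#' factor and returns the raw per-instance sum over perturbations.
#'
#' @param params an `autoencoder`.
#' @param X N x d input matrix.
#' @param perts a [perturbation_set()].
#' @param scaling `"mean"` (expectation over the neighborhood, default) or
#'   `"sum"` (raw sum over the J points).
#' @return Non-negative scalar; exactly 0 when `Q = 0`.
#' @export
stsm <- function(params, X, perts, scaling = c("mean", "sum")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (ncol(X) != perts$d)
    stop("perturbation set dimension does not match X")
  Y0 <- ae_forward(X, params)$Y
  n <- nrow(X); J <- perts$J
  Xs <- X[rep(seq_len(n), times = J), , drop = FALSE] +
    perts$offsets[rep(seq_len(J), each = n), , drop = FALSE]
  Ys <- ae_forward(Xs, params)$Y
  total <- sum((Y0[rep(seq_len(n), times = J), , drop = FALSE] - Ys)^2)
  if (scaling == "mean") total / (n * J) else total / n
}

#' Combined training objective
#'
#' `R + stsm_weight * STSM`: reconstruction error plus the weighted
#' sensitivity penalty. With `stsm_weight = 0` this is the plain
#' autoencoder loss.
#'
#' @inheritParams stsm
#' @param stsm_weight non-negative weight on the sensitivity term
#'   (1 recovers the unweighted sum that defines the method).
#' @return Non-negative scalar.
#' @export
lissa_objective <- function(params, X, perts, stsm_weight = 1,
                            scaling = c("mean", "sum")) {
  scaling <- match.arg(scaling)
  R <- reconstruction_mse(ae_forward(X, params)$Y, X)
  if (stsm_weight == 0 || perts$Q == 0) return(R)
  R + stsm_weight * stsm(params, X, perts, scaling)
}

#' Training configuration for the sensitivity-regularized autoencoder
#'
#' @param hidden_units hidden width h (default 20).
#' @param learning_rate step size for full-batch gradient descent.
#' @param epochs number of gradient steps.
#' @param Q neighborhood half-width (default 0.1; small relative to the
#'   0/1 feature gap).
#' @param J number of Halton perturbation points (default 50).
#' @param stsm_weight weight on the sensitivity term; 1 is the method's
#'   objective, 0 gives a plain autoencoder.
#' @param init_scale weights initialized uniformly in
#'   `[-init_scale, init_scale]`; `NULL` means `1/sqrt(d)` at fit time.
#' @param seed integer seed for weight initialization.
#' @param scaling sensitivity estimator scaling, see [stsm()].
#' @return A `lissa_config` list.
#' @export
lissa_config <- function(hidden_units = 20L, learning_rate = 0.05,
                         epochs = 500L, Q = 0.1, J = 50L, stsm_weight = 1,
                         init_scale = NULL, seed = 1L,
                         scaling = c("mean", "sum")) {
  scaling <- match.arg(scaling)
  stopifnot(hidden_units >= 1L, learning_rate > 0, epochs >= 1L,
            Q >= 0, J >= 1L, stsm_weight >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 Q = Q, J = as.integer(J), stsm_weight = stsm_weight,
                 init_scale = init_scale, seed = as.integer(seed),
                 scaling = scaling),
            class = "lissa_config")
}

# Objective value and analytic gradients in one pass. Gradients flow
# through both the unperturbed reconstruction g(X) and every perturbed
# reconstruction g(X + dX_j).
lissa_grad <- function(params, X, perts, stsm_weight = 1,
                       scaling = "mean") {
  n <- nrow(X); d <- ncol(X)
  fw <- ae_forward(X, params)
  C <- fw$C; Y <- fw$Y
  R <- sum((Y - X)^2) / n

  # reconstruction term
  gY <- 2 * (Y - X) / n
  use_stsm <- stsm_weight > 0 && perts$Q > 0
  stsm_val <- 0
  if (use_stsm) {
    J <- perts$J
    scale <- if (scaling == "mean") 1 / (n * J) else 1 / n
    rep_i <- rep(seq_len(n), times = J)
    Xs <- X[rep_i, , drop = FALSE] +
      perts$offsets[rep(seq_len(J), each = n), , drop = FALSE]
    fws <- ae_forward(Xs, params)
    Cs <- fws$C; Ys <- fws$Y
    D <- Y[rep_i, , drop = FALSE] - Ys
    stsm_val <- scale * sum(D^2)
    w <- stsm_weight * scale
    gY <- gY + 2 * w * rowsum(D, rep_i, reorder = TRUE)
    gYs <- -2 * w * D
    # backprop the stacked perturbed pass
    dZ2s <- gYs * Ys * (1 - Ys)
    gV <- crossprod(Cs, dZ2s)
    gb2 <- colSums(dZ2s)
    dCs <- dZ2s %*% t(params$V)
    dZ1s <- dCs * Cs * (1 - Cs)
    gW <- crossprod(Xs, dZ1s)
    gb1 <- colSums(dZ1s)
  } else {
    gV <- matrix(0, params$h, d); gb2 <- numeric(d)
    gW <- matrix(0, d, params$h); gb1 <- numeric(params$h)
  }
  # backprop the unperturbed pass (carries both R and the STSM g(X) route)
  dZ2 <- gY * Y * (1 - Y)
  gV <- gV + crossprod(C, dZ2)
  gb2 <- gb2 + colSums(dZ2)
  dC <- dZ2 %*% t(params$V)
  dZ1 <- dC * C * (1 - C)
  gW <- gW + crossprod(X, dZ1)
  gb1 <- gb1 + colSums(dZ1)

  list(objective = R + stsm_weight * stsm_val, R = R, stsm = stsm_val,
       gW = gW, gb1 = gb1, gV = gV, gb2 = gb2)
}

#' Analytic gradient of the training objective
#'
#' Returns the objective value, its reconstruction and sensitivity parts,
#' and the gradients with respect to all four parameter arrays. Exposed so
#' the gradients can be verified against finite differences.
#'
#' @inheritParams lissa_objective
#' @return List with `objective`, `R`, `stsm`, `gW`, `gb1`, `gV`, `gb2`.
#' @export
lissa_gradient <- function(params, X, perts, stsm_weight = 1,
                           scaling = c("mean", "sum")) {
  scaling <- match.arg(scaling)
  lissa_grad(params, as.matrix(X), perts, stsm_weight, scaling)
}

#' Train the sensitivity-regularized autoencoder
#'
#' Full-batch gradient descent on the combined objective, with one fixed
#' Halton perturbation set shared across instances and epochs. Weights are
#' initialized uniformly in `[-init_scale, init_scale]` from the config
#' seed, so a given (data, config) pair is exactly reproducible.
#'
#' @param dataset a [binary_dataset()] or plain N x d numeric matrix.
#' @param config a [lissa_config()].
#' @return An `autoencoder` with attached `history`: a data frame with one
#'   row per epoch and columns `epoch`, `R`, `stsm`, `objective`
#'   (objective measured before each step, plus a final row after the last
#'   step).
#' @export
train_autoencoder <- function(dataset, config = lissa_config()) {
  X <- if (inherits(dataset, "binary_dataset")) dataset$features
       else as.matrix(dataset)
  d <- ncol(X); h <- config$hidden_units
  scale0 <- if (is.null(config$init_scale)) 1 / sqrt(d) else config$init_scale
  params <- with_seed(config$seed, {
    autoencoder_params(
      W = matrix(stats::runif(d * h, -scale0, scale0), d, h),
      b1 = stats::runif(h, -scale0, scale0),
      V = matrix(stats::runif(h * d, -scale0, scale0), h, d),
      b2 = stats::runif(d, -scale0, scale0))
  })
  perts <- perturbation_set(config$Q, config$J, d)
  lr <- config$learning_rate
  hist <- matrix(NA_real_, config$epochs + 1L, 3L)
  for (e in seq_len(config$epochs)) {
    g <- lissa_grad(params, X, perts, config$stsm_weight, config$scaling)
    if (!is.finite(g$objective))
      stop("training diverged (non-finite objective) at epoch ", e)
    hist[e, ] <- c(g$R, g$stsm, g$objective)
    params$W <- params$W - lr * g$gW
    params$b1 <- params$b1 - lr * g$gb1
    params$V <- params$V - lr * g$gV
    params$b2 <- params$b2 - lr * g$gb2
  }
  g <- lissa_grad(params, X, perts, config$stsm_weight, config$scaling)
  hist[config$epochs + 1L, ] <- c(g$R, g$stsm, g$objective)
  history <- data.frame(epoch = 0:config$epochs, R = hist[, 1],
                        stsm = hist[, 2], objective = hist[, 3])
  attr(params, "history") <- history
  attr(params, "config") <- config
  params
}

#' Localized generalization error bound (reporting)
#'
#' Combines training error, the sensitivity measure and the problem
#' constants into the upper bound
#' `(sqrt(R) + sqrt(STSM) + sqrt(A))^2 + B * sqrt(ln(eta) / (-2 N))`,
#' which holds with probability `1 - eta`. The bound is reported for
#' diagnostics only; training minimizes `R + STSM` directly.
#'
#' @param R mean squared training error.
#' @param stsm_value stochastic sensitivity measure.
#' @param A maximum output difference (non-negative).
#' @param B maximum possible mean squared error (non-negative).
#' @param eta confidence parameter in (0, 1).
#' @param N number of training samples.
#' @return Scalar bound value.
#' @export
lge_bound <- function(R, stsm_value, A, B, eta, N) {
  if (eta <= 0 || eta >= 1) stop("eta must lie strictly between 0 and 1")
  if (A < 0 || B < 0 || R < 0 || stsm_value < 0)
    stop("R, stsm_value, A and B must be non-negative")
  (sqrt(R) + sqrt(stsm_value) + sqrt(A))^2 + B * sqrt(log(eta) / (-2 * N))
}

#' Save or load a trained autoencoder as JSON
#'
#' Stores shapes, row-major weight arrays and the training config echo so
#' a model reloads exactly.
#'
#' @param params an `autoencoder`.
#' @param path JSON file path.
#' @return `save_autoencoder` returns `path` invisibly; `load_autoencoder`
#'   returns the `autoencoder`.
#' @export
save_autoencoder <- function(params, path) {
  stopifnot(inherits(params, "autoencoder"))
  cfg <- attr(params, "config")
  obj <- list(d = params$d, h = params$h,
              W = as.vector(t(params$W)), b1 = params$b1,
              V = as.vector(t(params$V)), b2 = params$b2,
              config = if (is.null(cfg)) NULL else unclass(cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- autoencoder_params(
    W = matrix(x$W, x$d, x$h, byrow = TRUE),
    b1 = x$b1,
    V = matrix(x$V, x$h, x$d, byrow = TRUE),
    b2 = x$b2)
  if (!is.null(x$config))
    attr(params, "config") <- do.call(lissa_config, x$config[
      setdiff(names(x$config), character(0))])
  params
}
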