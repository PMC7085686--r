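# RBF classifier over the autoencoder code space: k-means centers with
# RMS widths, Gaussian hidden layer, ridge-regularized linear one-hot
# output, and the greedy unit-count search.

#' Fit RBF centers and widths by k-means
#'
#' Runs seeded k-means (k-means++ initialization, Lloyd iterations,
#' convergence tolerance 1e-6 on center movement, at most 300 iterations;
#' a cluster left empty is re-seeded from the point farthest from its
#' center) and sets each unit's width to the root-mean-square distance of
#' its members from the center. An empty or singleton cluster, whose RMS
#' distance is undefined or zero, falls back to the mean width of the
#' other clusters, or 0.1 if every cluster is degenerate.
#'
#' @param codes N x h matrix of hidden codes.
#' @param r number of RBF units (clusters); at most N.
#' @param seed integer seed for the k-means initialization.
#' @return An `rbf_layer`: list with `centers` (r x h), `widths`
#'   (length r, positive) and `r`.
#' @export
fit_centers <- function(codes, r, seed = 1L) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  r <- as.integer(r)
  if (r < 1L) stop("r must be at least 1")
  if (r > n) stop("r (", r, ") exceeds the number of samples (", n, ")")
  km <- with_seed(as.integer(seed), kmeans_lloyd(codes, r))
  d2 <- rowSums((codes - km$centers[km$cluster, , drop = FALSE])^2)
  sizes <- tabulate(km$cluster, nbins = r)
  widths <- vapply(seq_len(r), function(k) {
    if (sizes[k] >= 2L) sqrt(mean(d2[km$cluster == k])) else NA_real_
  }, numeric(1))
  widths[!is.na(widths) & widths < 1e-12] <- NA_real_  # coincident members
  if (all(is.na(widths))) widths[] <- 0.1
  else widths[is.na(widths)] <- mean(widths, na.rm = TRUE)
  structure(list(centers = km$centers, widths = widths, r = r,
                 cluster = km$cluster, inertia = sum(d2)),
            class = "rbf_layer")
}

# Seeded Lloyd k-means with k-means++ init; empty clusters are re-seeded
# from the currently farthest point. Deterministic under with_seed().
kmeans_lloyd <- function(X, k, max_iter = 300L, tol = 1e-6) {
  n <- nrow(X)
  # k-means++: each next center sampled with probability prop. to squared
  # distance from the nearest chosen center
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  if (k > 1L) {
    d2 <- rowSums((X - centers[rep(1L, n), , drop = FALSE])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = prob)
      centers <- rbind(centers, X[idx, , drop = FALSE])
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx, ], `-`)^2))
    }
  }
  cluster <- integer(n)
  for (it in seq_len(max_iter)) {
    D <- dist2_matrix(X, centers)
    cluster <- max.col(-D, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- cluster == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        far <- which.max(D[cbind(seq_len(n), cluster)])
        new_centers[j, ] <- X[far, ]
        cluster[far] <- j
      }
    }
    shift <- max(rowSums((new_centers - centers)^2))
    centers <- new_centers
    if (shift < tol^2) break
  }
  D <- dist2_matrix(X, centers)
  cluster <- max.col(-D, ties.method = "first")
  list(centers = centers, cluster = cluster)
}

# squared Euclidean distances, n x m
dist2_matrix <- function(X, M) {
  d2 <- outer(rowSums(X^2), rowSums(M^2), `+`) - 2 * X %*% t(M)
  d2[d2 < 0] <- 0
  dimnames(d2) <- NULL
  d2
}

#' Gaussian RBF activations
#'
#' `phi_k(x) = exp(-||x - u_k||^2 / (2 sigma_k^2))`: 1 exactly at the
#' center, strictly decreasing in distance.
#'
#' @param codes N x h matrix.
#' @param layer an `rbf_layer` from [fit_centers()].
#' @return N x r matrix with entries in (0, 1].
#' @export
rbf_activations <- function(codes, layer) {
  codes <- as.matrix(codes)
  if (ncol(codes) != ncol(layer$centers))
    stop("code dimension does not match the RBF centers")
  if (any(layer$widths <= 0)) stop("RBF widths must be positive")
  d2 <- dist2_matrix(codes, layer$centers)
  exp(sweep(d2, 2L, -2 * layer$widths^2, `/`))
}

#' Fit the linear one-hot output layer
#'
#' Ridge-regularized least squares on the design `[activations, 1]`
#' against the one-hot targets: minimizes
#' `||A theta - T||^2 + ridge ||theta||^2`. The solution is the
#' deterministic closed form of RBF network training.
#'
#' @param activations N x r RBF activation matrix.
#' @param targets N x p one-hot target matrix (see [one_hot()]).
#' @param ridge non-negative ridge penalty; the tiny default keeps the
#'   normal equations well-posed without noticeably biasing the fit.
#' @return (r + 1) x p weight matrix; the last row is the bias.
#' @export
fit_output_weights <- function(activations, targets, ridge = 1e-8) {
  A <- cbind(as.matrix(activations), 1)
  T <- as.matrix(targets)
  if (nrow(A) != nrow(T)) stop("activations and targets disagree on N")
  G <- crossprod(A)
  if (ridge > 0) diag(G) <- diag(G) + ridge
  th <- tryCatch(solve(G, crossprod(A, T)), error = function(e) {
    if (ridge == 0)
      stop("singular normal equations with ridge = 0; use ridge > 0")
    stop(e)
  })
  th
}

#' Predict classes from RBF network scores
#'
#' Computes the linear output scores and decodes each instance to the
#' class of maximal score, breaking ties toward the lowest class id.
#'
#' @param codes N x h matrix of hidden codes.
#' @param net an `rbf_network` (list with `layer`, `output_weights`, `p`).
#' @return List with `scores` (N x p) and `labels` (0-based class ids).
#' @export
network_predict <- function(codes, net) {
  act <- rbf_activations(codes, net$layer)
  scores <- cbind(act, 1) %*% net$output_weights
  labels <- max.col(scores, ties.method = "first") - 1L
  list(scores = scores, labels = labels)
}

#' Training mean squared error of network scores
#'
#' Mean over instances of the squared Euclidean distance between the
#' score row and its one-hot target — the quantity the greedy unit-count
#' search minimizes.
#'
#' @param scores N x p score matrix.
#' @param targets N x p one-hot matrix.
#' @return Non-negative scalar.
#' @export
training_mse <- function(scores, targets) {
  scores <- as.matrix(scores); targets <- as.matrix(targets)
  if (!all(dim(scores) == dim(targets)))
    stop("scores and targets must have identical shape")
  sum((scores - targets)^2) / nrow(scores)
}

#' Greedy search configuration
#'
#' @param r_min smallest candidate unit count (default: the number of
#'   classes p, resolved at search time when `NULL`).
#' @param r_max largest candidate (default: `floor(N / 2)`, resolved at
#'   search time when `NULL`).
#' @param step candidate increment (default 1).
#' @param ridge ridge penalty for the output-layer fit.
#' @param seed integer seed for the k-means runs.
#' @return A `greedy_config` list.
#' @export
greedy_config <- function(r_min = NULL, r_max = NULL, step = 1L,
                          ridge = 1e-8, seed = 1L) {
  stopifnot(step >= 1L, ridge >= 0)
  structure(list(r_min = r_min, r_max = r_max, step = as.integer(step),
                 ridge = ridge, seed = as.integer(seed)),
            class = "greedy_config")
}

#' Greedy minimum-training-MSE search over RBF unit counts
#'
#' Starting from `r_min` (by default the number of activity types) and
#' stepping up to `r_max` (by default half the training-set size), fits
#' one full RBF network per candidate unit count and keeps the one with
#' minimum training MSE, ties going to the smallest count.
#'
#' @param codes N x h matrix of (frozen) hidden codes for the training set.
#' @param targets N x p one-hot target matrix.
#' @param config a [greedy_config()].
#' @return List with `network` (the selected `rbf_network`), `r` (its unit
#'   count) and `trace` (data frame of candidate `r` and `training_mse`).
#' @export
greedy_search <- function(codes, targets, config = greedy_config()) {
  codes <- as.matrix(codes); targets <- as.matrix(targets)
  n <- nrow(codes); p <- ncol(targets)
  r_min <- if (is.null(config$r_min)) p else as.integer(config$r_min)
  r_max <- if (is.null(config$r_max)) n %/% 2L else as.integer(config$r_max)
  r_max <- min(r_max, n)
  if (r_min < 1L) stop("r_min must be at least 1")
  if (r_min > r_max)
    stop("empty candidate set: r_min (", r_min, ") > r_max (", r_max, ")")
  candidates <- seq.int(r_min, r_max, by = config$step)
  best <- NULL; best_mse <- Inf
  trace <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    r <- candidates[i]
    layer <- fit_centers(codes, r, seed = config$seed)
    act <- rbf_activations(codes, layer)
    th <- fit_output_weights(act, targets, ridge = config$ridge)
    scores <- cbind(act, 1) %*% th
    mse <- training_mse(scores, targets)
    trace[i] <- mse
    if (mse < best_mse) {   # strict: ties keep the smaller r
      best_mse <- mse
      best <- structure(list(layer = layer, output_weights = th, p = p),
                        class = "rbf_network")
    }
  }
  list(network = best, r = best$layer$r,
       trace = data.frame(r = candidates, training_mse = trace))
}
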