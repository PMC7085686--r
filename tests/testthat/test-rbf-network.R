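test_that("k-means centers recover separated blobs and are deterministic", {
  blobs <- two_blobs(n_per = 25L, h = 2L, sep = 5, sd = 0.1, seed = 8L)
  layer <- fit_centers(blobs$X, 2L, seed = 3L)
  # oracle: direct means of the generated blob members
  got <- layer$centers[order(layer$centers[, 1]), ]
  want <- rbind(colMeans(blobs$X[1:25, ]), colMeans(blobs$X[26:50, ]))
  expect_lt(max(abs(got - want)), 0.1)
  expect_true(all(layer$widths > 0))

  layer2 <- fit_centers(blobs$X, 2L, seed = 3L)
  expect_identical(layer$centers, layer2$centers)

  # cross-check against the reference k-means on the same data
  km <- kmeans(blobs$X, centers = 2L, nstart = 5L)
  ref <- km$centers[order(km$centers[, 1]), ]
  expect_lt(max(abs(got - ref)), 1e-6)
})

test_that("r = N on distinct points yields zero-inertia singleton clusters", {
  set.seed(9)
  X <- matrix(rnorm(20), 10, 2)
  layer <- fit_centers(X, 10L, seed = 1L)
  expect_equal(layer$inertia, 0)
  expect_equal(nrow(unique(layer$centers)), 10L)
  expect_true(all(layer$widths > 0))   # singleton fallback width
  expect_error(fit_centers(X, 11L), "exceeds")
})

test_that("Gaussian activations match the scalar formula", {
  layer <- structure(list(centers = rbind(c(0, 0), c(1, 1)),
                          widths = c(0.5, 2), r = 2L),
                     class = "rbf_layer")
  act <- rbf_activations(rbind(c(0, 0)), layer)
  expect_equal(act[1, 1], 1)   # at the center
  # ||x - u||^2 = 2 sigma^2 gives exp(-1)
  x <- c(sqrt(2) * 0.5, 0)
  expect_equal(rbf_activations(rbind(x), layer)[1, 1], exp(-1))

  set.seed(10)
  X <- matrix(runif(8), 4, 2)
  act <- rbf_activations(X, layer)
  for (i in 1:4) for (k in 1:2) {
    d2 <- sum((X[i, ] - layer$centers[k, ])^2)
    expect_equal(act[i, k], exp(-d2 / (2 * layer$widths[k]^2)))
  }
  expect_true(all(act > 0 & act <= 1))

  bad <- layer; bad$widths <- c(0.5, 0)
  expect_error(rbf_activations(X, bad), "positive")
})

test_that("output-layer fit matches the normal equations and shrinks under ridge", {
  set.seed(11)
  A <- matrix(runif(18), 6, 3)
  T <- one_hot(c(0L, 1L, 2L, 0L, 1L, 2L), 3L)
  th <- fit_output_weights(A, T, ridge = 1e-3)
  # oracle: explicit normal equations
  A1 <- cbind(A, 1)
  want <- solve(crossprod(A1) + 1e-3 * diag(4), crossprod(A1, T))
  expect_equal(th, want)

  # weight norm decreases monotonically as ridge grows
  norms <- vapply(10^seq(-4, 4), function(lam)
    sum(fit_output_weights(A, T, ridge = lam)^2), numeric(1))
  expect_true(all(diff(norms) < 0))

  # identity activations (r = N) with no ridge interpolate the targets
  I6 <- diag(6)
  T2 <- one_hot(c(0L, 1L, 0L, 1L, 0L, 1L), 2L)
  th0 <- fit_output_weights(I6[, 1:5], T2, ridge = 1e-10)
  pred <- cbind(I6[, 1:5], 1) %*% th0
  expect_lt(max(abs(pred - T2)), 1e-4)
})

test_that("prediction takes the maximal score with low-id tie breaking", {
  layer <- structure(list(centers = matrix(0, 1, 2), widths = 1, r = 1L),
                     class = "rbf_layer")
  net <- structure(list(layer = layer,
                        output_weights = rbind(c(0, 0, 0),
                                               c(0.1, 0.9, 0.3)),
                        p = 3L), class = "rbf_network")
  out <- network_predict(rbind(c(0, 0)), net)
  expect_equal(out$labels, 1L)
  net$output_weights <- rbind(c(0, 0, 0), c(0.5, 0.5, 0.2))
  expect_equal(network_predict(rbind(c(0, 0)), net)$labels, 0L)
})

test_that("training MSE equals the elementwise loop oracle", {
  T <- one_hot(c(0L, 1L), 2L)
  expect_equal(training_mse(T, T), 0)
  S <- T; S[2, ] <- S[2, ] + c(1, -1)
  expect_equal(training_mse(S, T), 1)
  set.seed(12)
  S <- matrix(runif(12), 4, 3); T3 <- one_hot(c(0L, 1L, 2L, 1L), 3L)
  acc <- 0
  for (i in 1:4) acc <- acc + sum((S[i, ] - T3[i, ])^2)
  expect_equal(training_mse(S, T3), acc / 4)
})

test_that("fitted output weights are a local least-squares optimum", {
  set.seed(13)
  A <- matrix(runif(30), 10, 3)
  T <- one_hot(rep(0:1, 5), 2L)
  ridge <- 1e-4
  th <- fit_output_weights(A, T, ridge = ridge)
  A1 <- cbind(A, 1)
  obj <- function(w) sum((A1 %*% w - T)^2) + ridge * sum(w^2)
  base <- obj(th)
  for (i in 1:100) {
    expect_gte(obj(th + matrix(rnorm(length(th), 0, 1e-3),
                               nrow(th), ncol(th))), base)
  }
})

test_that("greedy search covers the candidate grid and returns its minimum", {
  blobs <- two_blobs(n_per = 20L, h = 3L, sep = 4, sd = 0.3, seed = 14L)
  T <- one_hot(blobs$labels, 2L)
  gs <- greedy_search(blobs$X, T, greedy_config(seed = 2L))
  expect_equal(gs$trace$r, seq.int(2L, 20L))   # p .. floor(N/2)
  expect_equal(min(gs$trace$training_mse),
               gs$trace$training_mse[gs$trace$r == gs$r])
  # selected network is at least as accurate as the smallest candidate
  small <- fit_centers(blobs$X, 2L, seed = 2L)
  act <- rbf_activations(blobs$X, small)
  th <- fit_output_weights(act, T)
  acc_small <- mean(max.col(cbind(act, 1) %*% th) - 1L == blobs$labels)
  acc_best <- mean(network_predict(blobs$X, gs$network)$labels ==
                     blobs$labels)
  expect_gte(acc_best, acc_small)

  single <- greedy_search(blobs$X, T,
                          greedy_config(r_min = 5L, r_max = 5L))
  expect_equal(single$r, 5L)
  expect_equal(nrow(single$trace), 1L)
  expect_error(greedy_search(blobs$X, T,
                             greedy_config(r_min = 6L, r_max = 5L)),
               "empty candidate set")
})
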