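test_that("sigmoid is symmetric, bounded and stable at extreme arguments", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3.2, -0.5, 0.1, 2.7)
  expect_equal(sigmoid(x), 1 - sigmoid(-x))
  expect_true(is.finite(sigmoid(500)) && sigmoid(500) <= 1)
  expect_true(is.finite(sigmoid(-500)) && sigmoid(-500) >= 0)
  m <- matrix(c(-1, 0, 1, 2), 2, 2)
  expect_equal(dim(sigmoid(m)), c(2L, 2L))
})

test_that("forward pass matches a hand-composed scalar chain", {
  # all-zero parameters: every unit outputs sigmoid(0) = 0.5
  zero <- autoencoder_params(matrix(0, 2, 3), rep(0, 3),
                             matrix(0, 3, 2), rep(0, 2))
  fw <- ae_forward(rbind(c(1, 0), c(0, 1)), zero)
  expect_true(all(fw$C == 0.5) && all(fw$Y == 0.5))

  # h = 1, d = 2: compose the chain with scalar arithmetic
  p <- autoencoder_params(matrix(c(0.3, -0.7), 2, 1), 0.2,
                          matrix(c(0.5, -0.4), 1, 2), c(0.1, -0.2))
  x <- c(1, 1)
  c1 <- 1 / (1 + exp(-(0.3 * 1 + (-0.7) * 1 + 0.2)))
  y1 <- 1 / (1 + exp(-(c1 * 0.5 + 0.1)))
  y2 <- 1 / (1 + exp(-(c1 * (-0.4) - 0.2)))
  fw <- ae_forward(rbind(x), p)
  expect_equal(as.numeric(fw$C), c1)
  expect_equal(as.numeric(fw$Y), c(y1, y2))
  expect_equal(encode(rbind(x), p), fw$C)

  expect_error(ae_forward(rbind(c(1, 0, 1)), p), "expects 2")
})

test_that("reconstruction error matches an elementwise loop oracle", {
  expect_equal(reconstruction_mse(rbind(c(0, 0)), rbind(c(0, 0))), 0)
  expect_equal(reconstruction_mse(rbind(c(1, 1)), rbind(c(0, 0))), 2)
  set.seed(4)
  X <- matrix(runif(15), 5, 3); Y <- matrix(runif(15), 5, 3)
  acc <- 0
  for (i in 1:5) for (j in 1:3) acc <- acc + (Y[i, j] - X[i, j])^2
  expect_equal(reconstruction_mse(Y, X), acc / 5)
  expect_error(reconstruction_mse(Y, X[1:4, ]), "shape")
})

test_that("Halton points follow the van der Corput sequences", {
  expect_equal(as.numeric(halton_points(3, 1)), c(0.5, 0.25, 0.75))
  expect_equal(halton_points(1, 2)[1, ], c(0.5, 1 / 3))
  h <- halton_points(50, 3)
  expect_true(all(h >= 0 & h < 1))
  expect_lt(abs(mean(h[, 1]) - 0.5), 0.05)  # low-discrepancy sanity
})

test_that("perturbation sets stay inside the Q-neighborhood", {
  p0 <- perturbation_set(0, 50L, 4L)
  expect_true(all(p0$offsets == 0))
  expect_equal(perturbation_set(1, 5L, 1L)$offsets[1, 1], 0)  # 2*0.5 - 1
  ps <- perturbation_set(0.3, 50L, 10L)
  expect_lte(max(abs(ps$offsets)), 0.3)
  expect_error(perturbation_set(-0.1, 50L, 2L), "non-negative")
  # deterministic construction
  expect_identical(perturbation_set(0.3, 50L, 10L)$offsets, ps$offsets)
})

test_that("sensitivity measure is zero at Q = 0 and invariant to row duplication", {
  ae <- tiny_ae(d = 4L, h = 5L, seed = 2L)
  X <- random_binary(6, 4, seed = 3L)
  expect_equal(stsm(ae, X, perturbation_set(0, 50L, 4L)), 0)
  ps <- perturbation_set(0.2, 50L, 4L)
  one <- stsm(ae, X[1, , drop = FALSE], ps)
  dup <- stsm(ae, X[c(1, 1, 1), ], ps)
  expect_equal(dup, one)
  # raw-sum scaling differs from the expectation by exactly J
  expect_equal(stsm(ae, X, ps, scaling = "sum"), 50 * stsm(ae, X, ps))
})

test_that("quasi-Monte-Carlo sensitivity agrees with a plain Monte-Carlo oracle", {
  cases <- list(list(d = 3L, h = 5L, Q = 0.3, seed = 1L),
                list(d = 5L, h = 8L, Q = 0.5, seed = 2L),
                list(d = 4L, h = 6L, Q = 0.1, seed = 3L))
  for (cs in cases) {
    ae <- tiny_ae(cs$d, cs$h, seed = cs$seed)
    X <- random_binary(5, cs$d, seed = cs$seed + 10L)
    qmc <- stsm(ae, X, perturbation_set(cs$Q, 50L, cs$d))
    mc <- mc_sensitivity(ae, X, cs$Q, n_samples = 10000L,
                         seed = cs$seed + 20L)
    expect_lt(abs(qmc - mc) / mc, 0.10)
  }
})

test_that("sensitivity grows with the neighborhood radius on most small networks", {
  grew <- vapply(1:20, function(s) {
    ae <- tiny_ae(d = 3L, h = 4L, seed = s)
    X <- random_binary(4, 3, seed = s + 100L)
    q <- runif(1, 0.05, 0.25)
    stsm(ae, X, perturbation_set(2 * q, 50L, 3L)) >=
      stsm(ae, X, perturbation_set(q, 50L, 3L))
  }, logical(1))
  expect_gte(mean(grew), 0.9)
})

test_that("combined objective is the sum of its separately computed terms", {
  ae <- tiny_ae(d = 3L, h = 4L, seed = 5L)
  X <- random_binary(6, 3, seed = 6L)
  ps <- perturbation_set(0.2, 50L, 3L)
  R <- reconstruction_mse(ae_forward(X, ae)$Y, X)
  expect_equal(lissa_objective(ae, X, ps, stsm_weight = 0), R)
  expect_equal(lissa_objective(ae, X, perturbation_set(0, 50L, 3L)), R)
  expect_equal(lissa_objective(ae, X, ps, stsm_weight = 0.7),
               R + 0.7 * stsm(ae, X, ps))
})

test_that("analytic gradients match central finite differences", {
  for (s in 1:3) {
    d <- 3L; h <- 4L
    ae <- tiny_ae(d, h, seed = s)
    X <- random_binary(5, d, seed = s + 50L)
    ps <- perturbation_set(0.2, 20L, d)
    g <- lissa_gradient(ae, X, ps, stsm_weight = 1)
    eps <- 1e-5
    for (nm in c("W", "b1", "V", "b2")) {
      analytic <- g[[paste0("g", nm)]]
      numeric_g <- analytic
      for (i in seq_along(ae[[nm]])) {
        up <- ae; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- ae; dn[[nm]][i] <- dn[[nm]][i] - eps
        numeric_g[i] <- (lissa_objective(up, X, ps) -
                         lissa_objective(dn, X, ps)) / (2 * eps)
      }
      rel <- sqrt(sum((analytic - numeric_g)^2)) /
        max(sqrt(sum(numeric_g^2)), 1e-12)
      expect_lt(rel, 1e-5)
    }
  }
})

test_that("training reduces the objective and is reproducible", {
  ds <- generate_dataset(generator_config(d = 8L, p = 5L,
                                          n_per_class = 10L, seed = 21L))
  cfg <- lissa_config(epochs = 120L, seed = 4L)
  ae <- train_autoencoder(ds, cfg)
  hist <- attr(ae, "history")
  expect_lt(hist$objective[nrow(hist)], hist$objective[1])

  # plain-autoencoder mode reduces reconstruction error alone
  cfg0 <- lissa_config(epochs = 120L, seed = 4L, stsm_weight = 0)
  ae0 <- train_autoencoder(ds, cfg0)
  h0 <- attr(ae0, "history")
  expect_lt(h0$R[nrow(h0)], h0$R[1])
  expect_true(all(h0$stsm == 0))

  # same seed and config give bit-identical parameters
  ae2 <- train_autoencoder(ds, cfg)
  expect_identical(ae$W, ae2$W)
  expect_identical(ae$V, ae2$V)
  expect_identical(attr(ae, "history"), attr(ae2, "history"))
})

test_that("generalization-error bound degenerates and orders correctly", {
  expect_equal(lge_bound(0.04, 0.01, A = 0, B = 0, eta = 0.05, N = 100),
               (sqrt(0.04) + sqrt(0.01))^2)
  expect_equal(lge_bound(0, 0, A = 0, B = 2, eta = 0.05, N = 100),
               2 * sqrt(log(0.05) / (-200)))
  vals <- vapply(seq(0, 1, by = 0.1), function(R)
    lge_bound(R, 0.02, A = 0.5, B = 1, eta = 0.05, N = 50), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(lge_bound(0.1, 0.1, 0, 0, eta = 1.2, N = 10), "eta")
})

test_that("trained autoencoders survive a JSON round trip", {
  ds <- generate_dataset(generator_config(d = 6L, p = 3L,
                                          n_per_class = 8L, seed = 31L))
  ae <- train_autoencoder(ds, lissa_config(epochs = 20L))
  path <- withr::local_tempfile(fileext = ".json")
  save_autoencoder(ae, path)
  back <- load_autoencoder(path)
  expect_equal(back$W, ae$W)
  expect_equal(back$b2, ae$b2)
  X <- ds$features
  expect_equal(ae_forward(X, back)$Y, ae_forward(X, ae)$Y)
})
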