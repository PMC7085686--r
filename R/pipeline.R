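# End-to-end model: frozen-encoder feature extraction feeding the greedy
# RBF search, repeated cross-validation, hidden-width sweep, t-test.

#' Train the full activity-recognition model
#'
#' Two-step training: (1) the sensitivity-regularized autoencoder is fit
#' on the training features; (2) its encoder is frozen, the training set
#' is mapped to hidden codes, and the greedy minimum-training-MSE search
#' fits the RBF classifier on those codes against one-hot targets. Only
#' the RBF part is retrained per candidate unit count.
#'
#' @param dataset a [binary_dataset()] (training split).
#' @param lissa_cfg a [lissa_config()].
#' @param search_cfg a [greedy_config()].
#' @return A `lissa_rbf` model: list with `ae`, `net`, `r`, `trace`,
#'   `activity_names`, `sensor_names` and the two configs.
#' @export
train_model <- function(dataset, lissa_cfg = lissa_config(),
                        search_cfg = greedy_config()) {
  stopifnot(inherits(dataset, "binary_dataset"))
  ae <- train_autoencoder(dataset, lissa_cfg)
  codes <- encode(dataset$features, ae)
  targets <- one_hot(dataset$labels, dataset$p)
  gs <- greedy_search(codes, targets, search_cfg)
  structure(list(ae = ae, net = gs$network, r = gs$r, trace = gs$trace,
                 activity_names = dataset$activity_names,
                 sensor_names = dataset$sensor_names,
                 lissa_cfg = lissa_cfg, search_cfg = search_cfg),
            class = "lissa_rbf")
}

#' @export
print.lissa_rbf <- function(x, ...) {
  cat(sprintf(
    "lissa_rbf model: %d sensors -> %d hidden codes -> %d RBF units -> %d activities\n",
    x$ae$d, x$ae$h, x$r, x$net$p))
  invisible(x)
}

#' Predict activity classes
#'
#' Encodes the binary feature rows with the frozen encoder and classifies
#' the codes with the RBF network.
#'
#' @param object a `lissa_rbf` model.
#' @param features M x d binary matrix or a [binary_dataset()].
#' @param type `"label"` (0-based class ids, default), `"name"` (activity
#'   names) or `"score"` (M x p score matrix).
#' @param ... unused.
#' @return Predictions in the requested form.
#' @export
predict.lissa_rbf <- function(object, features, type = c("label", "name",
                                                         "score"), ...) {
  type <- match.arg(type)
  X <- if (inherits(features, "binary_dataset")) features$features
       else as.matrix(features)
  if (ncol(X) != object$ae$d)
    stop("features have ", ncol(X), " columns but the model expects ",
         object$ae$d)
  out <- network_predict(encode(X, object$ae), object$net)
  switch(type,
         label = out$labels,
         name = object$activity_names[out$labels + 1L],
         score = out$scores)
}

#' Repeated k-fold cross-validation of the full pipeline
#'
#' For every fold of every repeat, the autoencoder and the RBF search are
#' retrained from scratch on the k-1 training folds and evaluated on the
#' held-out fold. Accuracy and support-weighted F1 are reported per fold,
#' as mean +/- sd over all folds (in percent), and at the instance level
#' over the aggregate confusion matrix pooled across folds and repeats.
#'
#' @param dataset a [binary_dataset()].
#' @param lissa_cfg a [lissa_config()].
#' @param search_cfg a [greedy_config()].
#' @param k folds (default 10).
#' @param repeats repetitions (default 5).
#' @param seed integer seed driving the fold plan and per-fold training
#'   seeds.
#' @param stratified stratify folds by class?
#' @return A `cv_result`: list with `fold_metrics` (data frame: repeat_id,
#'   fold, n_test, accuracy, weighted_f1), `summary` (means and sds in
#'   percent, plus instance-level aggregate accuracy and weighted F1),
#'   `aggregate` (pooled `confusion_matrix`), and the plan.
#' @export
repeated_cv <- function(dataset, lissa_cfg = lissa_config(),
                        search_cfg = greedy_config(), k = 10L,
                        repeats = 5L, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(dataset, "binary_dataset"))
  plan <- make_folds(dataset, k = k, repeats = repeats, seed = seed,
                     stratified = stratified)
  p <- dataset$p
  agg <- matrix(0L, p, p)
  rows <- vector("list", repeats * k)
  ri <- 0L
  for (rep_id in seq_len(repeats)) {
    fold_of <- plan$assignments[[rep_id]]
    for (f in seq_len(k) - 1L) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      train_ds <- binary_dataset(
        dataset$features[train_idx, , drop = FALSE],
        dataset$labels[train_idx],
        sensor_names = dataset$sensor_names,
        activity_names = dataset$activity_names)
      cfg <- lissa_cfg
      cfg$seed <- (seed + 7919L * rep_id + 101L * f) %% 2147483647L
      scfg <- search_cfg
      scfg$seed <- (cfg$seed + 1L) %% 2147483647L
      model <- train_model(train_ds, cfg, scfg)
      pred <- predict(model, dataset$features[test_idx, , drop = FALSE])
      cm <- confusion(dataset$labels[test_idx], pred, p)
      agg <- agg + cm$counts
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        repeat_id = rep_id, fold = f, n_test = length(test_idx),
        accuracy = overall_accuracy(cm), weighted_f1 = weighted_f1(cm))
    }
  }
  fold_metrics <- do.call(rbind, rows)
  agg_cm <- as_confusion(agg)
  summary <- list(
    accuracy_mean_pct = 100 * mean(fold_metrics$accuracy),
    accuracy_sd_pct = 100 * stats::sd(fold_metrics$accuracy),
    weighted_f1_mean_pct = 100 * mean(fold_metrics$weighted_f1),
    weighted_f1_sd_pct = 100 * stats::sd(fold_metrics$weighted_f1),
    aggregate_accuracy_pct = 100 * overall_accuracy(agg_cm),
    aggregate_weighted_f1_pct = 100 * weighted_f1(agg_cm))
  structure(list(fold_metrics = fold_metrics, summary = summary,
                 aggregate = agg_cm, plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cv_result: %d repeats x %d folds\n",
              x$plan$repeats, x$plan$k))
  cat(sprintf("  accuracy    %.2f +/- %.2f %%  (aggregate %.2f %%)\n",
              s$accuracy_mean_pct, s$accuracy_sd_pct,
              s$aggregate_accuracy_pct))
  cat(sprintf("  weighted F1 %.2f +/- %.2f %%  (aggregate %.2f %%)\n",
              s$weighted_f1_mean_pct, s$weighted_f1_sd_pct,
              s$aggregate_weighted_f1_pct))
  invisible(x)
}

#' Sweep the autoencoder hidden width
#'
#' Re-runs the full cross-validated pipeline for each candidate hidden
#' width and tabulates mean accuracy and weighted F1 — the protocol for
#' studying how many hidden units the feature extractor needs.
#'
#' @param dataset a [binary_dataset()].
#' @param hidden_grid integer vector of hidden widths (default
#'   `seq(20, 140, by = 20)`).
#' @param lissa_cfg base [lissa_config()]; its `hidden_units` is replaced
#'   per grid point.
#' @param search_cfg a [greedy_config()].
#' @param k,repeats,seed cross-validation settings (see [repeated_cv()]).
#' @return Data frame with one row per width: `hidden_units`,
#'   `accuracy_pct`, `accuracy_sd_pct`, `f1_pct`, `f1_sd_pct`.
#' @export
sweep_hidden <- function(dataset, hidden_grid = seq(20L, 140L, by = 20L),
                         lissa_cfg = lissa_config(),
                         search_cfg = greedy_config(), k = 10L,
                         repeats = 1L, seed = 1L) {
  rows <- lapply(hidden_grid, function(h) {
    cfg <- lissa_cfg
    cfg$hidden_units <- as.integer(h)
    cv <- repeated_cv(dataset, cfg, search_cfg, k = k, repeats = repeats,
                      seed = seed)
    data.frame(hidden_units = as.integer(h),
               accuracy_pct = cv$summary$accuracy_mean_pct,
               accuracy_sd_pct = cv$summary$accuracy_sd_pct,
               f1_pct = cv$summary$weighted_f1_mean_pct,
               f1_sd_pct = cv$summary$weighted_f1_sd_pct)
  })
  do.call(rbind, rows)
}

#' Two-sample t-test between per-run metric vectors
#'
#' Compares two classifiers' repeated-CV metric values. Welch's unequal-
#' variance form is the default; `pooled = TRUE` gives the equal-variance
#' test. When both samples are constant and equal the test is degenerate
#' and `t = 0, p = 1` is returned by convention.
#'
#' @param scores_a,scores_b numeric vectors of per-run metric values
#'   (at least 2 each).
#' @param alpha significance level (default 0.05).
#' @param pooled use the pooled-variance test instead of Welch?
#' @param alternative passed to [stats::t.test()] (default two-sided).
#' @return List with `t`, `p_value`, `significant` (p < alpha) and the
#'   two sample means.
#' @export
compare_ttest <- function(scores_a, scores_b, alpha = 0.05,
                          pooled = FALSE, alternative = "two.sided") {
  if (length(scores_a) < 2L || length(scores_b) < 2L)
    stop("need at least 2 observations per side")
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0 &&
      mean(scores_a) == mean(scores_b)) {
    return(list(t = 0, p_value = 1, significant = FALSE,
                mean_a = mean(scores_a), mean_b = mean(scores_b)))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = pooled,
                      alternative = alternative)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha,
       mean_a = mean(scores_a), mean_b = mean(scores_b))
}

#' Save or load a trained model as JSON
#'
#' Stores the autoencoder, RBF centers/widths/output weights and the
#' config echoes so a trained model reloads exactly.
#'
#' @param model a `lissa_rbf`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the `lissa_rbf`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lissa_rbf"))
  obj <- list(
    ae = list(d = model$ae$d, h = model$ae$h,
              W = as.vector(t(model$ae$W)), b1 = model$ae$b1,
              V = as.vector(t(model$ae$V)), b2 = model$ae$b2),
    net = list(r = model$net$layer$r, p = model$net$p,
               centers = as.vector(t(model$net$layer$centers)),
               widths = model$net$layer$widths,
               output_weights = as.vector(t(model$net$output_weights))),
    activity_names = model$activity_names,
    sensor_names = model$sensor_names,
    lissa_cfg = unclass(model$lissa_cfg),
    search_cfg = unclass(model$search_cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ae <- autoencoder_params(
    W = matrix(x$ae$W, x$ae$d, x$ae$h, byrow = TRUE), b1 = x$ae$b1,
    V = matrix(x$ae$V, x$ae$h, x$ae$d, byrow = TRUE), b2 = x$ae$b2)
  layer <- structure(
    list(centers = matrix(x$net$centers, x$net$r, x$ae$h, byrow = TRUE),
         widths = x$net$widths, r = as.integer(x$net$r)),
    class = "rbf_layer")
  net <- structure(
    list(layer = layer,
         output_weights = matrix(x$net$output_weights, x$net$r + 1L,
                                 x$net$p, byrow = TRUE),
         p = as.integer(x$net$p)),
    class = "rbf_network")
  structure(list(ae = ae, net = net, r = layer$r, trace = NULL,
                 activity_names = x$activity_names,
                 sensor_names = x$sensor_names,
                 lissa_cfg = x$lissa_cfg, search_cfg = x$search_cfg),
            class = "lissa_rbf")
}
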