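# Seeded generator of synthetic binary smart-home activity datasets.
#
# Each activity class has a binary sensor-signature prototype; instances
# are prototypes with independent per-bit flip noise. Aliased class pairs
# share one prototype, emulating activities (breakfast / lunch / dinner /
# snack) whose interactions with the environment are indistinguishable
# from the sensors' point of view.

#' Synthetic generator configuration
#'
#' @param d number of binary sensors (default 12, a typical deployment).
#' @param p number of activity types (default 9).
#' @param n_per_class instances per class (default 27, giving ~240
#'   instances at the defaults — the scale of real annotated ADL sets).
#' @param prototype_density probability a prototype bit is 1
#'   (default 0.35: a handful of sensors fire per activity).
#' @param flip_prob per-bit noise probability rho in `[0, 0.5]`
#'   (default 0.05).
#' @param aliased_pairs list of 2-element integer vectors of 0-based class
#'   ids forced to share one prototype.
#' @param imbalance geometric per-class size decay factor in (0, 1];
#'   1 (default) gives balanced classes, smaller values skew supports.
#' @param asymmetric if `TRUE`, noise only clears bits (1 -> 0),
#'   emulating missed sensor activations, instead of symmetric flips.
#' @param seed integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(d = 12L, p = 9L, n_per_class = 27L,
                             prototype_density = 0.35, flip_prob = 0.05,
                             aliased_pairs = list(), imbalance = 1,
                             asymmetric = FALSE, seed = 1L) {
  stopifnot(d >= 1L, p >= 1L, n_per_class >= 1L,
            prototype_density > 0, prototype_density < 1,
            flip_prob >= 0, flip_prob <= 0.5,
            imbalance > 0, imbalance <= 1)
  for (pr in aliased_pairs)
    if (length(pr) != 2L || any(pr < 0L) || any(pr >= p))
      stop("aliased_pairs must be 2-element vectors of class ids in 0..p-1")
  structure(list(d = as.integer(d), p = as.integer(p),
                 n_per_class = as.integer(n_per_class),
                 prototype_density = prototype_density,
                 flip_prob = flip_prob, aliased_pairs = aliased_pairs,
                 imbalance = imbalance, asymmetric = asymmetric,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw class sensor-signature prototypes
#'
#' Samples one binary prototype per class with the configured bit density.
#' Non-aliased prototypes are kept pairwise distinct by rejection (up to
#' 1000 redraws each); classes listed in `aliased_pairs` share a single
#' prototype.
#'
#' @param config a [generator_config()].
#' @return p x d 0/1 matrix of class prototypes.
#' @export
make_prototypes <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    proto <- matrix(NA_real_, config$p, config$d)
    key <- function(v) paste(v, collapse = "")
    seen <- character(0)
    for (cls in seq_len(config$p)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        v <- as.numeric(stats::runif(config$d) < config$prototype_density)
        if (!(key(v) %in% seen)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("cannot draw ", config$p, " distinct prototypes with d = ",
             config$d, "; increase d or the density")
      proto[cls, ] <- v
      seen <- c(seen, key(v))
    }
    for (pr in config$aliased_pairs)
      proto[pr[2] + 1L, ] <- proto[pr[1] + 1L, ]
    proto
  })
}

#' Generate a synthetic binary activity dataset
#'
#' Each instance is its class prototype with every bit flipped
#' independently with probability `flip_prob` (or, in asymmetric mode,
#' every 1-bit cleared with that probability). Class sizes follow the
#' `imbalance` decay; with the default of 1 all classes have
#' `n_per_class` instances.
#'
#' @param config a [generator_config()].
#' @return A [binary_dataset()] with attribute `prototypes`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  proto <- make_prototypes(config)
  sizes <- pmax(1L, as.integer(round(
    config$n_per_class * config$imbalance^(seq_len(config$p) - 1L))))
  labels <- rep(seq_len(config$p) - 1L, times = sizes)
  n <- length(labels)
  features <- with_seed(config$seed + 1L, {
    X <- proto[labels + 1L, , drop = FALSE]
    U <- matrix(stats::runif(n * config$d), n, config$d)
    if (config$asymmetric) {
      X[X == 1 & U < config$flip_prob] <- 0
    } else {
      flip <- U < config$flip_prob
      X[flip] <- 1 - X[flip]
    }
    X
  })
  ds <- binary_dataset(features, labels,
                       activity_names = paste0("activity_",
                                               seq_len(config$p) - 1L))
  attr(ds, "prototypes") <- proto
  attr(ds, "config") <- config
  ds
}

#' Inject sensor faults into an existing dataset
#'
#' Flips every feature bit independently with probability `fault_prob`,
#' modelling transmission errors or hardware faults. Labels are left
#' untouched and the input dataset is not modified.
#'
#' @param dataset a [binary_dataset()].
#' @param fault_prob per-bit flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A new [binary_dataset()] with corrupted features.
#' @export
inject_faults <- function(dataset, fault_prob, seed = 1L) {
  stopifnot(inherits(dataset, "binary_dataset"),
            fault_prob >= 0, fault_prob <= 1)
  X <- dataset$features
  X <- with_seed(as.integer(seed), {
    flip <- matrix(stats::runif(length(X)), nrow(X), ncol(X)) < fault_prob
    X[flip] <- 1 - X[flip]
    X
  })
  binary_dataset(X, dataset$labels, sensor_names = dataset$sensor_names,
                 activity_names = dataset$activity_names)
}

#' Nearest-prototype reference classifier
#'
#' Assigns each instance to the class whose prototype is nearest in
#' Hamming distance (ties to the lowest class id). With zero noise and
#' distinct prototypes this classifier is perfect, giving a ceiling that
#' end-to-end pipeline runs can be checked against.
#'
#' @param features M x d binary matrix.
#' @param prototypes p x d prototype matrix (e.g. from a generated
#'   dataset's `prototypes` attribute).
#' @return Integer vector of 0-based class ids.
#' @export
nearest_prototype <- function(features, prototypes) {
  D <- dist2_matrix(as.matrix(features), as.matrix(prototypes))
  max.col(-D, ties.method = "first") - 1L
}
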