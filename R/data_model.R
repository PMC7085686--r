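# Dataset container, file I/O, label encoding, fold planning.

#' Construct a binary activity dataset
#'
#' Bundles an instance-by-sensor matrix of binary activations with integer
#' class labels. One row is one activity instance; one column is one binary
#' sensor (1 = activated during the instance, 0 = not). Labels are 0-based
#' class ids into `activity_names`.
#'
#' @param features numeric matrix, N x d, entries 0/1.
#' @param labels integer vector of length N with values in `0:(p-1)`.
#' @param sensor_names character vector of d sensor names. Defaults to
#'   `s1..sd`.
#' @param activity_names character vector of p activity names. Defaults to
#'   the distinct label ids as strings.
#' @return An object of class `binary_dataset` with elements `features`,
#'   `labels`, `sensor_names`, `activity_names`, and counts `n`, `d`, `p`.
#' @examples
#' ds <- binary_dataset(rbind(c(1, 0), c(0, 1), c(1, 1)), c(0L, 1L, 0L))
#' ds$p
#' @export
binary_dataset <- function(features, labels, sensor_names = NULL,
                           activity_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L || ncol(features) < 1L)
    stop("dataset needs at least one instance and one sensor")
  bad <- which(!(features %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(features)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(features)) + 1L
    stop(sprintf("non-binary feature value %g at row %d, column %d",
                 features[i, j], i, j))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("labels length must equal the number of instances")
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers")
  if (is.null(activity_names)) {
    activity_names <- as.character(sort(unique(labels)))
  }
  p <- length(activity_names)
  if (any(labels >= p))
    stop("labels reference undeclared activities (id >= p)")
  if (p < 2L)
    stop("at least two activity types are required")
  if (is.null(sensor_names))
    sensor_names <- paste0("s", seq_len(ncol(features)))
  if (length(sensor_names) != ncol(features))
    stop("sensor_names length must equal the number of sensors")
  dimnames(features) <- NULL
  structure(
    list(features = features, labels = labels,
         sensor_names = as.character(sensor_names),
         activity_names = as.character(activity_names),
         n = nrow(features), d = ncol(features), p = p),
    class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf("binary_dataset: %d instances, %d sensors, %d activities\n",
              x$n, x$d, x$p))
  supp <- tabulate(x$labels + 1L, nbins = x$p)
  cat("supports:", paste(sprintf("%s=%d", x$activity_names, supp),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Read a binary activity dataset from delimited text
#'
#' Expects one instance per row: d feature columns of 0/1 values followed
#' by a final label column of activity names. The delimiter is
#' auto-detected among comma and tab. A header row carries sensor names
#' and then the label column name (conventionally `activity`). Label
#' strings are mapped to 0-based ids in order of first appearance, so the
#' encoding is deterministic for a given file.
#'
#' @param path path to a CSV or TSV file.
#' @param header logical; does the first row carry column names?
#' @return A [binary_dataset()].
#' @seealso [write_dataset()]
#' @export
load_dataset <- function(path, header = TRUE) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty dataset file: ", path)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
  if (ncol(df) < 2L) stop("dataset file needs feature columns plus a label column")
  d <- ncol(df) - 1L
  lab_str <- df[[ncol(df)]]
  if (any(!nzchar(lab_str)))
    stop("empty activity label at row ", which(!nzchar(lab_str))[1])
  feat <- suppressWarnings(
    vapply(df[seq_len(d)], as.numeric, numeric(nrow(df))))
  feat <- matrix(feat, nrow = nrow(df), ncol = d)
  if (anyNA(feat)) {
    idx <- which(is.na(feat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric feature value at row %d, column %d",
                 idx[1], idx[2]))
  }
  activity_names <- unique(lab_str)       # first-appearance order
  labels <- match(lab_str, activity_names) - 1L
  sensor_names <- if (header) colnames(df)[seq_len(d)] else NULL
  binary_dataset(feat, labels, sensor_names = sensor_names,
                 activity_names = activity_names)
}

#' Write a binary activity dataset as delimited text
#'
#' Inverse of [load_dataset()]: sensor columns then an `activity` column
#' of label strings, with a header row.
#'
#' @param dataset a [binary_dataset()].
#' @param path output file path.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "binary_dataset"))
  df <- as.data.frame(dataset$features)
  names(df) <- dataset$sensor_names
  df$activity <- dataset$activity_names[dataset$labels + 1L]
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' One-hot encode class labels
#'
#' Each label becomes a unit basis row vector, the regression target used
#' when fitting the linear output layer of the RBF classifier. Column sums
#' therefore equal the class supports.
#'
#' @param labels integer vector of 0-based class ids.
#' @param p number of classes.
#' @return An N x p 0/1 matrix with exactly one 1 per row.
#' @examples
#' one_hot(c(0L, 2L, 1L), 3L)
#' @export
one_hot <- function(labels, p) {
  labels <- as.integer(labels)
  p <- as.integer(p)
  if (any(labels < 0L) || any(labels >= p))
    stop("labels must lie in 0..p-1")
  T <- matrix(0, length(labels), p)
  T[cbind(seq_along(labels), labels + 1L)] <- 1
  T
}

#' Plan repeated k-fold cross-validation splits
#'
#' Produces deterministic fold assignments for `repeats` independent
#' shuffles. With `stratified = TRUE` (default) each class is distributed
#' across folds as evenly as its support permits, so per-fold class counts
#' stay within one of the proportional share; otherwise folds are plain
#' random with sizes differing by at most one.
#'
#' @param dataset a [binary_dataset()].
#' @param k number of folds; must not exceed the number of instances.
#' @param repeats number of independent repetitions.
#' @param seed integer seed; the same seed reproduces the plan exactly.
#' @param stratified balance class proportions per fold?
#' @return A `fold_plan`: list with `k`, `repeats`, `seed`, `stratified`
#'   and `assignments`, a list of length-`repeats` integer vectors with
#'   fold ids in `0:(k-1)`.
#' @export
make_folds <- function(dataset, k = 10L, repeats = 5L, seed = 1L,
                       stratified = TRUE) {
  stopifnot(inherits(dataset, "binary_dataset"))
  k <- as.integer(k); repeats <- as.integer(repeats)
  n <- dataset$n
  if (k > n) stop("k (", k, ") exceeds the number of instances (", n, ")")
  if (k < 2L) stop("k must be at least 2")
  assignments <- with_seed(as.integer(seed), {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(n)
      if (stratified) {
        # deal each shuffled class round-robin, rotating the starting fold
        # so small classes do not pile into fold 0
        start <- 0L
        for (cls in seq_len(dataset$p) - 1L) {
          idx <- which(dataset$labels == cls)
          if (!length(idx)) next
          idx <- idx[sample.int(length(idx))]
          fold[idx] <- (start + seq_along(idx) - 1L) %% k
          start <- (start + length(idx)) %% k
        }
      } else {
        fold <- rep_len(seq_len(k) - 1L, n)[sample.int(n)]
      }
      fold
    })
  })
  structure(list(k = k, repeats = repeats, seed = as.integer(seed),
                 stratified = stratified, assignments = assignments),
            class = "fold_plan")
}

#' Save or load a fold plan as JSON
#'
#' Serializing the plan allows an exact rerun of a cross-validation split.
#'
#' @param plan a `fold_plan` from [make_folds()].
#' @param path JSON file path.
#' @return `save_fold_plan` returns `path` invisibly; `load_fold_plan`
#'   returns the `fold_plan`.
#' @export
save_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_fold_plan
#' @export
load_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$assignments <- if (is.matrix(x$assignments)) {
    lapply(seq_len(nrow(x$assignments)),
           function(i) as.integer(x$assignments[i, ]))
  } else if (is.list(x$assignments)) {
    lapply(x$assignments, as.integer)
  } else {
    list(as.integer(x$assignments))
  }
  structure(list(k = as.integer(x$k), repeats = as.integer(x$repeats),
                 seed = as.integer(x$seed), stratified = x$stratified,
                 assignments = x$assignments),
            class = "fold_plan")
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
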