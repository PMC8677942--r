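#' Interval summary features for time-series forests
#'
#' Mean, standard deviation, and ordinary-least-squares slope of each series
#' over an interval of sample positions (1-based, inclusive). Slope is in
#' units of µV per sample.
#'
#' @param X Matrix with series in rows.
#' @param start,end Interval bounds, `1 <= start < end <= ncol(X)`.
#' @return Matrix with columns `mean`, `sd`, `slope`.
#' @export
intervalFeatures <- function(X, start, end) {
  stopifnot(is.matrix(X), start >= 1, end <= ncol(X), start < end)
  seg <- X[, start:end, drop = FALSE]
  m <- rowMeans(seg)
  s <- apply(seg, 1, sd)
  i <- seq_len(ncol(seg))
  ic <- i - mean(i)
  slope <- as.numeric(seg %*% ic) / sum(ic * ic)
  cbind(mean = m, sd = s, slope = slope)
}

# binary cross-entropy of a split, in nats; y is logical
.nodeEntropy <- function(npos, n) {
  p <- npos / n
  ifelse(n == 0 | p <= 0 | p >= 1, 0, -(p * log(p) + (1 - p) * log(1 - p)))
}

# Grow one binary decision tree on a feature matrix, minimising the weighted
# binary cross-entropy of the children. Returns a data.frame of nodes.
.growTree <- function(F, y, max_depth = 10L, min_split = 2L) {
  nodes <- list()
  addNode <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         prob = mean(y[idx]))
    n <- length(idx)
    if (depth >= max_depth || n < min_split || all(y[idx]) || !any(y[idx]))
      return(id)
    parent_ent <- .nodeEntropy(sum(y[idx]), n) * n
    best <- list(gain = 1e-12)
    for (f in seq_len(ncol(F))) {
      v <- F[idx, f]
      o <- order(v)
      vs <- v[o]; ys <- y[idx][o]
      distinct <- which(diff(vs) > 0)
      if (!length(distinct)) next
      cpos <- cumsum(ys)
      nl <- distinct
      npos_l <- cpos[distinct]
      ent <- .nodeEntropy(npos_l, nl) * nl +
        .nodeEntropy(sum(ys) - npos_l, n - nl) * (n - nl)
      j <- which.min(ent)
      gain <- parent_ent - ent[j]
      if (gain > best$gain) {
        best <- list(gain = gain, feature = f,
                     threshold = (vs[distinct[j]] + vs[distinct[j] + 1]) / 2)
      }
    }
    if (is.null(best$feature)) return(id)
    go_left <- F[idx, best$feature] <= best$threshold
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$left <<- addNode(idx[go_left], depth + 1L)
    nodes[[id]]$right <<- addNode(idx[!go_left], depth + 1L)
    id
  }
  addNode(seq_along(y), 0L)
  nodes
}

.treePredict <- function(nodes, Fq) {
  vapply(seq_len(nrow(Fq)), function(i) {
    id <- 1L
    repeat {
      nd <- nodes[[id]]
      if (is.na(nd$feature)) return(nd$prob)
      id <- if (Fq[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
  }, numeric(1))
}

#' Fit a time-series forest
#'
#' An ensemble of interval-feature decision trees: each tree samples
#' `n_intervals` random intervals (default `round(sqrt(T))`, minimum length
#' 3; start and length uniform), summarises every interval by its mean,
#' standard deviation and OLS slope, and grows a binary tree on those
#' features by minimising binary cross-entropy. Fully seeded and
#' deterministic; training-set row order does not affect the forest given
#' the seed (intervals depend only on the seed, splits only on the data
#' values).
#'
#' @param X Matrix of equal-length series in rows (length `T >= 3`).
#' @param y Labels, coerced to binary (`ON_POS`/1/TRUE is the positive
#'   class).
#' @param n_estimators Number of trees.
#' @param n_intervals Intervals sampled per tree (default `round(sqrt(T))`).
#' @param min_interval Minimum interval length in samples.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed.
#' @return Object of class `"TSFModel"`.
#' @export
tsfFit <- function(X, y, n_estimators = 100L, n_intervals = NULL,
                   min_interval = 3L, max_depth = 10L, seed = 1L) {
  X <- as.matrix(X)
  Tn <- ncol(X)
  if (Tn < 3) stop("series length must be at least 3")
  y <- .asBinaryLabels(y)
  if (all(y) || !any(y)) stop("both classes are required to fit")
  n_estimators <- .assertCount(n_estimators, "n_estimators", lower = 1L)
  n_intervals <- .assertCount(n_intervals %||% max(1L, round(sqrt(Tn))),
                              "n_intervals", lower = 1L)
  trees <- .withSeed(seed, lapply(seq_len(n_estimators), function(b) {
    start <- sample.int(Tn - min_interval + 1L, n_intervals, replace = TRUE)
    maxlen <- Tn - start + 1L
    len <- min_interval +
      floor(runif(n_intervals) * (maxlen - min_interval + 1L))
    ints <- cbind(start = start, end = start + len - 1L)
    F <- do.call(cbind, lapply(seq_len(n_intervals), function(i)
      intervalFeatures(X, ints[i, 1], ints[i, 2])))
    list(intervals = ints, nodes = .growTree(F, y, max_depth = max_depth))
  }))
  structure(list(trees = trees, n_estimators = n_estimators,
                 n_intervals = n_intervals, series_length = Tn,
                 seed = as.integer(seed)),
            class = "TSFModel")
}

#' Predict with a time-series forest
#'
#' Majority vote across trees (each tree votes positive when its leaf
#' probability exceeds 0.5); the returned probability is the positive vote
#' fraction and an exactly even vote resolves to the negative class.
#'
#' @param model A `"TSFModel"` from [tsfFit()].
#' @param X Matrix of series in rows (same length as at training).
#' @return `data.frame` with `label` (`"ON_POS"`/`"ON_NEG"`) and
#'   `probability` (positive vote fraction).
#' @export
tsfPredict <- function(model, X) {
  stopifnot(inherits(model, "TSFModel"))
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (ncol(X) != model$series_length)
    stop(sprintf("series length %d does not match training length %d",
                 ncol(X), model$series_length))
  votes <- vapply(model$trees, function(tr) {
    F <- do.call(cbind, lapply(seq_len(nrow(tr$intervals)), function(i)
      intervalFeatures(X, tr$intervals[i, 1], tr$intervals[i, 2])))
    as.numeric(.treePredict(tr$nodes, F) > 0.5)
  }, numeric(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  prob <- rowMeans(votes)
  data.frame(label = ifelse(prob > 0.5, "ON_POS", "ON_NEG"),
             probability = prob, stringsAsFactors = FALSE)
}
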