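#' Dynamic time warping distance
#'
#' Minimum cumulative cost over monotone warping paths with step set
#' \{(1,0), (0,1), (1,1)\}, local cost `|x_i - y_j|` for univariate series
#' (squared cost optional), computed by dynamic programming in C. An optional
#' Sakoe–Chiba band of half-width `band` constrains `|i - j| <= band`.
#'
#' `dtwDistance(x, x) == 0`; with `band = 0` and equal lengths the path is
#' forced onto the diagonal and the distance equals `sum(|x - y|)`.
#'
#' @param x,y Numeric series (non-empty).
#' @param band Non-negative integer band half-width, or `NULL` for
#'   unbounded. Must be at least `|length(x) - length(y)|`.
#' @param squared Use squared local cost.
#' @return Non-negative cumulative cost.
#' @examples
#' dtwDistance(c(0, 0), c(1, 1))  # 2: diagonal path
#' @export
dtwDistance <- function(x, y, band = NULL, squared = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("series must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("series must not contain NA")
  if (is.null(band)) {
    band <- -1L
  } else {
    band <- .assertCount(band, "band", lower = 0L)
    if (band < abs(length(x) - length(y)))
      stop("band smaller than the length difference: no feasible path")
  }
  .dtw_cost_cpp(x, y, as.integer(band), .assertFlag(squared, "squared"))
}

#' k-nearest-neighbour DTW classification
#'
#' Predicts the label of each query series from its `k` nearest training
#' series under [dtwDistance()]. Distance ties are broken by the smallest
#' training index; a tied vote is resolved by the label of the closest
#' (then smallest-index) neighbour.
#'
#' @param train_series List of numeric series (or matrix with series in
#'   rows).
#' @param train_labels Labels, one per training series.
#' @param query_series Single series, list of series, or matrix with series
#'   in rows.
#' @param k Number of neighbours (default 1).
#' @param band,squared Passed to [dtwDistance()].
#' @return Vector of predicted labels (same type as `train_labels`).
#' @export
knnDtwPredict <- function(train_series, train_labels, query_series, k = 1L,
                          band = NULL, squared = FALSE) {
  train_series <- .asSeriesList(train_series)
  if (!length(train_series)) stop("empty training set")
  k <- .assertCount(k, "k", lower = 1L)
  if (k > length(train_series)) stop("k exceeds the training-set size")
  if (length(train_labels) != length(train_series))
    stop("one label per training series is required")
  queries <- .asSeriesList(query_series)
  preds <- vapply(queries, function(q) {
    d <- vapply(train_series, dtwDistance, numeric(1), y = q,
                band = band, squared = squared)
    nn <- order(d)[seq_len(k)]  # order() is stable: smallest index wins ties
    labs <- as.character(train_labels[nn])
    votes <- table(labs)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) top <- labs[labs %in% top][1]  # closest tied label
    top
  }, character(1))
  if (is.factor(train_labels)) factor(preds, levels = levels(train_labels))
  else if (is.numeric(train_labels)) as.numeric(preds)
  else preds
}

.asSeriesList <- function(x) {
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  if (is.numeric(x)) return(list(x))
  stopifnot(is.list(x))
  x
}
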