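.classifierKinds <- c("nn_dtw", "svm_linear", "svm_rbf", "rf", "gb", "tsf",
                      "lstm")

#' Classifier configuration for the waveform benchmark
#'
#' Builds a configuration whose defaults are the benchmark's reference
#' hyperparameters: RBF-kernel SVM with regularization constant `C = 1.5`
#' and `gamma = 1 / (n_features * var(X))` ("scale"); random forest with 200
#' estimators; gradient boosting with 100 estimators; time-series forest
#' with 100 estimators; LSTM with 3 layers, batch size 6, dropout 0.6,
#' hidden size 16, Adam optimizer, learning rate 0.001, 100 epochs. Any
#' field can be overridden through `...`.
#'
#' @param kind One of `"nn_dtw"`, `"svm_linear"`, `"svm_rbf"`, `"rf"`,
#'   `"gb"`, `"tsf"`, `"lstm"`.
#' @param seed Integer seed for the classifier's own randomness.
#' @param ... Overrides (e.g. `C`, `n_estimators`, `band`, `k`,
#'   `lstm = list(n_epochs = 5)`).
#' @return A list of class `"ClassifierConfig"`.
#' @examples
#' classifierConfig("svm_rbf")$C            # 1.5
#' classifierConfig("rf")$n_estimators      # 200
#' @export
classifierConfig <- function(kind, seed = 1L, ...) {
  kind <- match.arg(kind, .classifierKinds)
  cfg <- switch(kind,
    nn_dtw = list(k = 1L, band = NULL, squared = FALSE),
    svm_linear = list(C = 1),
    svm_rbf = list(C = 1.5, gamma_mode = "scale"),
    rf = list(n_estimators = 200L),
    gb = list(n_estimators = 100L, max_depth = 3L, learning_rate = 0.1),
    tsf = list(n_estimators = 100L),
    lstm = list(lstm = list(n_layers = 3L, batch_size = 6L, dropout = 0.6,
                            hidden_dims = 16L, optimizer = "adam",
                            learning_rate = 0.001, n_epochs = 100L)))
  over <- list(...)
  if (kind == "lstm" && !is.null(over$lstm)) {
    cfg$lstm[names(over$lstm)] <- over$lstm
    over$lstm <- NULL
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s) for kind '", kind, "': ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$kind <- kind
  cfg$seed <- as.integer(seed)
  class(cfg) <- "ClassifierConfig"
  cfg
}

#' Train a benchmark classifier on raw waveforms
#'
#' Trains one of the benchmark classifier kinds on raw series (each waveform
#' is the feature vector). Labels are encoded as ON_POS = +1 and ON_NEG = -1.
#' The standard kinds are backed by established learners — `e1071::svm`
#' (linear and RBF kernels), `randomForest`, and `xgboost` with binomial
#' deviance (logistic loss) for gradient boosting — while `nn_dtw`, `tsf`
#' and `lstm` are the package's own implementations. `svm_rbf` uses the
#' "scale" gamma, `1 / (n_features * var(X))`.
#'
#' @param kind Classifier kind (see [classifierConfig()]).
#' @param X Matrix of waveforms in rows.
#' @param y Labels.
#' @param config A `"ClassifierConfig"` (defaults to
#'   `classifierConfig(kind)`).
#' @return Object of class `"ERGClassifier"`; predict with
#'   [predictClassifier()].
#' @export
fitStandardClassifier <- function(kind, X, y, config = classifierConfig(kind)) {
  kind <- match.arg(kind, .classifierKinds)
  stopifnot(inherits(config, "ClassifierConfig"), config$kind == kind)
  X <- as.matrix(X)
  ybin <- .asBinaryLabels(y)
  yf <- factor(ifelse(ybin, "ON_POS", "ON_NEG"), levels = c("ON_NEG", "ON_POS"))
  fit <- switch(kind,
    nn_dtw = list(train = X, labels = yf, k = config$k, band = config$band,
                  squared = config$squared %||% FALSE),
    svm_linear = .withSeed(config$seed,
      e1071::svm(X, yf, kernel = "linear", cost = config$C, scale = FALSE)),
    svm_rbf = {
      gamma <- 1 / (ncol(X) * var(as.vector(X)))
      .withSeed(config$seed,
        e1071::svm(X, yf, kernel = "radial", cost = config$C, gamma = gamma,
                   scale = FALSE))
    },
    rf = .withSeed(config$seed,
      randomForest::randomForest(X, yf, ntree = config$n_estimators)),
    gb = .withSeed(config$seed,
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = config$max_depth,
                                       eta = config$learning_rate,
                                       nthread = 1),
                         data = xgboost::xgb.DMatrix(X, label = as.numeric(ybin)),
                         nrounds = config$n_estimators, verbose = 0)),
    tsf = tsfFit(X, ybin, n_estimators = config$n_estimators,
                 seed = config$seed),
    lstm = {
      p <- config$lstm
      lstmFit(X, ybin, n_layers = p$n_layers, hidden_dims = p$hidden_dims,
              batch_size = p$batch_size, dropout = p$dropout,
              learning_rate = p$learning_rate, n_epochs = p$n_epochs,
              seed = config$seed)
    })
  structure(list(kind = kind, fit = fit, config = config),
            class = "ERGClassifier")
}

#' Predict labels with a trained benchmark classifier
#'
#' @param model An `"ERGClassifier"` from [fitStandardClassifier()].
#' @param X Matrix of waveforms in rows.
#' @return Character vector of `"ON_POS"`/`"ON_NEG"` labels.
#' @export
predictClassifier <- function(model, X) {
  stopifnot(inherits(model, "ERGClassifier"))
  X <- as.matrix(X)
  switch(model$kind,
    nn_dtw = as.character(knnDtwPredict(model$fit$train, model$fit$labels, X,
                                        k = model$fit$k, band = model$fit$band,
                                        squared = model$fit$squared)),
    svm_linear = ,
    svm_rbf = as.character(predict(model$fit, X)),
    rf = as.character(predict(model$fit, X)),
    gb = ifelse(predict(model$fit, xgboost::xgb.DMatrix(X)) > 0.5,
                "ON_POS", "ON_NEG"),
    tsf = tsfPredict(model$fit, X)$label,
    lstm = lstmPredict(model$fit, X)$label)
}
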