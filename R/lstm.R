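# Compact multi-layer LSTM binary classifier, trained by Adam on the
# cross-entropy loss with full backpropagation through time. Pure R, fully
# seeded and deterministic. Designed for short experiments on modest
# cohorts; at the full default configuration (3 layers x 16 units x 430
# timesteps x 100 epochs) training is slow, so tests and pipelines typically
# reduce n_epochs.

.lstmInitLayer <- function(input_dim, hidden) {
  # one weight matrix per layer mapping [x_t, h_{t-1}, 1] -> 4 gates (i,f,g,o)
  sc <- 1 / sqrt(input_dim + hidden)
  W <- matrix(runif((input_dim + hidden + 1) * 4 * hidden, -sc, sc),
              input_dim + hidden + 1, 4 * hidden)
  W[input_dim + hidden + 1, hidden + seq_len(hidden)] <- 1  # forget-gate bias
  W
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass for a batch; returns caches when training
.lstmForward <- function(params, Xb, dropout = 0, train = FALSE) {
  n <- nrow(Xb); Tn <- ncol(Xb); H <- params$hidden; L <- params$n_layers
  caches <- if (train) vector("list", L)
  masks <- vector("list", L)
  inp <- lapply(seq_len(Tn), function(t) matrix(Xb[, t], n, 1))
  for (l in seq_len(L)) {
    W <- params$layers[[l]]
    h <- cs <- matrix(0, n, H)
    hs <- vector("list", Tn)
    if (train) cache_t <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      zin <- cbind(inp[[t]], h, 1)
      g <- zin %*% W
      i_g <- .sigmoid(g[, 1:H, drop = FALSE])
      f_g <- .sigmoid(g[, H + 1:H, drop = FALSE])
      c_g <- tanh(g[, 2 * H + 1:H, drop = FALSE])
      o_g <- .sigmoid(g[, 3 * H + 1:H, drop = FALSE])
      cs_new <- f_g * cs + i_g * c_g
      tc <- tanh(cs_new)
      h_new <- o_g * tc
      if (train)
        cache_t[[t]] <- list(zin = zin, i = i_g, f = f_g, g = c_g, o = o_g,
                             c_prev = cs, c = cs_new, tc = tc)
      cs <- cs_new; h <- h_new
      hs[[t]] <- h
    }
    if (train && dropout > 0 && l < L) {
      mask <- matrix(rbinom(n * H, 1, 1 - dropout), n, H) / (1 - dropout)
      masks[[l]] <- mask
      hs <- lapply(hs, function(hh) hh * mask)
    }
    if (train) caches[[l]] <- cache_t
    inp <- hs
  }
  h_last <- inp[[Tn]]
  logits <- as.numeric(h_last %*% params$W_out + params$b_out)
  list(prob = .sigmoid(logits), h_last = h_last, caches = caches,
       masks = masks, logits = logits)
}

# full BPTT gradient for one batch
.lstmBackward <- function(params, Xb, yb, fwd, dropout = 0) {
  n <- nrow(Xb); Tn <- ncol(Xb); H <- params$hidden; L <- params$n_layers
  grads <- list(layers = lapply(params$layers, function(W) W * 0),
                W_out = params$W_out * 0, b_out = 0)
  dlogit <- matrix((fwd$prob - yb) / n, n, 1)
  grads$W_out <- crossprod(fwd$h_last, dlogit)
  grads$b_out <- sum(dlogit)
  # gradient flowing into the last hidden state of the top layer
  dh_extern <- vector("list", Tn)
  for (t in seq_len(Tn)) dh_extern[[t]] <- matrix(0, n, H)
  dh_extern[[Tn]] <- dlogit %*% t(params$W_out)
  for (l in rev(seq_len(L))) {
    cache_t <- fwd$caches[[l]]
    in_dim <- nrow(params$layers[[l]]) - H - 1
    dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
    dinp <- vector("list", Tn)
    mask <- if (l < L && dropout > 0) fwd$masks[[l]]
    for (t in rev(seq_len(Tn))) {
      ext <- dh_extern[[t]]
      if (!is.null(mask)) ext <- ext * mask
      dh <- dh_next + ext
      ch <- cache_t[[t]]
      dc <- dc_next + dh * ch$o * (1 - ch$tc^2)
      d_o <- dh * ch$tc * ch$o * (1 - ch$o)
      d_i <- dc * ch$g * ch$i * (1 - ch$i)
      d_f <- dc * ch$c_prev * ch$f * (1 - ch$f)
      d_g <- dc * ch$i * (1 - ch$g^2)
      dgates <- cbind(d_i, d_f, d_g, d_o)
      grads$layers[[l]] <- grads$layers[[l]] + crossprod(ch$zin, dgates)
      dz <- dgates %*% t(params$layers[[l]])
      dinp[[t]] <- dz[, seq_len(in_dim), drop = FALSE]
      dh_next <- dz[, in_dim + seq_len(H), drop = FALSE]
      dc_next <- dc * ch$f
    }
    dh_extern <- dinp  # becomes the external gradient for the layer below
  }
  grads
}

#' Train a compact LSTM classifier on raw waveforms
#'
#' A small multi-layer LSTM fed the waveform one sample per timestep, with
#' the last hidden state mapped through a dense sigmoid unit; trained with
#' Adam on binary cross-entropy, with inverted dropout between layers.
#' Implemented in R with full backpropagation through time; fully seeded and
#' deterministic. The defaults are the benchmark configuration (3 layers,
#' hidden size 16, batch 6, dropout 0.6, Adam with learning rate 0.001, 100
#' epochs); reduce `n_epochs` for quick experiments.
#'
#' @param X Matrix of series in rows.
#' @param y Labels (`ON_POS`/1/TRUE positive).
#' @param n_layers,hidden_dims,batch_size,dropout,learning_rate,n_epochs
#'   Hyperparameters.
#' @param seed Integer seed.
#' @return Object of class `"LSTMModel"`.
#' @export
lstmFit <- function(X, y, n_layers = 3L, hidden_dims = 16L, batch_size = 6L,
                    dropout = 0.6, learning_rate = 0.001, n_epochs = 100L,
                    seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(.asBinaryLabels(y))
  mu <- mean(X); sdev <- sd(X)
  if (sdev == 0) sdev <- 1
  Xs <- (X - mu) / sdev
  n <- nrow(Xs); H <- .assertCount(hidden_dims, "hidden_dims", 1L)
  L <- .assertCount(n_layers, "n_layers", 1L)
  .withSeed(seed, {
    params <- list(hidden = H, n_layers = L,
                   layers = lapply(seq_len(L), function(l)
                     .lstmInitLayer(if (l == 1) 1L else H, H)),
                   W_out = matrix(runif(H, -0.1, 0.1), H, 1), b_out = 0)
    adam <- list(m = list(layers = lapply(params$layers, function(w) w * 0),
                          W_out = params$W_out * 0, b_out = 0),
                 v = list(layers = lapply(params$layers, function(w) w * 0),
                          W_out = params$W_out * 0, b_out = 0))
    step <- 0
    for (epoch in seq_len(.assertCount(n_epochs, "n_epochs", 1L))) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (b in batches) {
        fwd <- .lstmForward(params, Xs[b, , drop = FALSE], dropout, train = TRUE)
        gr <- .lstmBackward(params, Xs[b, , drop = FALSE], y[b], fwd, dropout)
        step <- step + 1
        upd <- function(p, g, mm, vv) {
          mm <- 0.9 * mm + 0.1 * g
          vv <- 0.999 * vv + 0.001 * g^2
          mh <- mm / (1 - 0.9^step); vh <- vv / (1 - 0.999^step)
          list(p = p - learning_rate * mh / (sqrt(vh) + 1e-8), m = mm, v = vv)
        }
        for (l in seq_len(L)) {
          u <- upd(params$layers[[l]], gr$layers[[l]],
                   adam$m$layers[[l]], adam$v$layers[[l]])
          params$layers[[l]] <- u$p
          adam$m$layers[[l]] <- u$m; adam$v$layers[[l]] <- u$v
        }
        u <- upd(params$W_out, gr$W_out, adam$m$W_out, adam$v$W_out)
        params$W_out <- u$p; adam$m$W_out <- u$m; adam$v$W_out <- u$v
        u <- upd(params$b_out, gr$b_out, adam$m$b_out, adam$v$b_out)
        params$b_out <- u$p; adam$m$b_out <- u$m; adam$v$b_out <- u$v
      }
    }
    structure(list(params = params, center = mu, scale = sdev,
                   series_length = ncol(X), seed = as.integer(seed)),
              class = "LSTMModel")
  })
}

#' Predict with a fitted LSTM classifier
#'
#' @param model An `"LSTMModel"` from [lstmFit()].
#' @param X Matrix of series in rows.
#' @return `data.frame` with `label` and `probability` (positive-class).
#' @export
lstmPredict <- function(model, X) {
  stopifnot(inherits(model, "LSTMModel"))
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (ncol(X) != model$series_length) stop("series length mismatch")
  Xs <- (X - model$center) / model$scale
  prob <- .lstmForward(model$params, Xs, train = FALSE)$prob
  data.frame(label = ifelse(prob > 0.5, "ON_POS", "ON_NEG"),
             probability = prob, stringsAsFactors = FALSE)
}
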