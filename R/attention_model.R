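#' Model configuration for the attention encoder-decoder
#'
#' @param units GRU units per direction (default 64).
#' @param max_len Maximum (padded) sequence length (default 40).
#' @param batch_size Mini-batch size for training (default 256).
#' @param epochs Maximum training epochs (default 30; the reference protocol
#'   trains for 5--30 epochs).
#' @param patience Early-stopping patience on validation MAE; 0 disables
#'   early stopping and always trains for `epochs` epochs.
#' @param min_delta Minimum validation-MAE improvement (scaled target units)
#'   that resets the patience counter.
#' @param learning_rate Adam learning rate; all other Adam settings are the
#'   optimizer defaults (beta1 0.9, beta2 0.999, eps 1e-8).
#' @param mask_pad Whether padding positions are masked out of the attention
#'   softmax (default `FALSE`; per-amino-acid averaging downstream excludes
#'   pad positions regardless).
#' @param seed Integer seed driving weight initialisation and shuffling.
#' @return A list of class `"attn_config"`.
#' @export
attn_config <- function(units = 64L, max_len = 40L, batch_size = 256L,
                        epochs = 30L, patience = 0L, min_delta = 0,
                        learning_rate = 1e-3, mask_pad = FALSE, seed = 1L) {
  stopifnot(units >= 1, max_len >= 1, batch_size >= 1, epochs >= 1,
            min_delta >= 0)
  structure(list(units = as.integer(units), max_len = as.integer(max_len),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 min_delta = min_delta, learning_rate = learning_rate,
                 mask_pad = isTRUE(mask_pad), seed = as.integer(seed)),
            class = "attn_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model weights
#'
#' Glorot-uniform initialisation for all weight matrices, zero biases. The
#' decoder input vocabulary is the alphabet plus the dedicated start symbol.
#'
#' @param alphabet An [make_alphabet()] alphabet.
#' @param config An [attn_config()].
#' @return A model object of class `"attn_model"` (untrained).
#' @export
attn_init <- function(alphabet, config = attn_config()) {
  stopifnot(inherits(alphabet, "attn_alphabet"),
            inherits(config, "attn_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  A <- alphabet$size; u <- config$units
  Ad <- A + 1L                       # + start symbol
  din <- 2L * u + Ad                 # decoder input: [context ; one-hot start]
  params <- list(
    Wf = glorot(A, 3 * u), Uf = glorot(u, 3 * u), bf = matrix(0, 1, 3 * u),
    Wb = glorot(A, 3 * u), Ub = glorot(u, 3 * u), bb = matrix(0, 1, 3 * u),
    Was = glorot(2 * u, u), Uah = glorot(2 * u, u), ba = matrix(0, 1, u),
    va = matrix(glorot(u, 1), u, 1),
    Vf = glorot(din, 3 * u), Qf = glorot(u, 3 * u), cf = matrix(0, 1, 3 * u),
    Vb = glorot(din, 3 * u), Qb = glorot(u, 3 * u), cb = matrix(0, 1, 3 * u),
    wd = glorot(2 * u, 1), bd = 0)
  structure(list(params = params, alphabet = alphabet, config = config,
                 history = NULL, trained = FALSE),
            class = "attn_model")
}

#' @export
print.attn_model <- function(x, ...) {
  cat("<attn_model> BiGRU encoder-decoder with additive attention\n",
      "  units/direction: ", x$config$units,
      "  channels: ", x$alphabet$size,
      "  max_len: ", x$config$max_len, "\n",
      "  trained: ", x$trained,
      if (x$trained) paste0(" (", length(x$history$train_mse), " epochs)"),
      "\n", sep = "")
  invisible(x)
}

pad_index <- function(alphabet) {
  if (is.null(alphabet$pad)) -1L else unname(alphabet$index[alphabet$pad])
}

model_indices <- function(model, sequences) {
  sequences_to_indices(sequences, model$alphabet, model$config$max_len)
}

## ---- reference forward path (plain R) --------------------------------------
## These exported operations expose the model's internal stages one at a time
## (encoder states, attention step, single decoding step). They are written
## directly from the layer equations and are intended for inspection and for
## small inputs; `predict()` runs the same computation through the compiled
## batched path.

sigmoid_r <- function(x) 1 / (1 + exp(-x))

gru_step_r <- function(x, h_prev, W, U, b) {
  u <- length(h_prev)
  p <- drop(crossprod(W, x)) + drop(b)
  zr <- drop(h_prev %*% U[, seq_len(2 * u), drop = FALSE])
  z <- sigmoid_r(p[seq_len(u)] + zr[seq_len(u)])
  r <- sigmoid_r(p[u + seq_len(u)] + zr[u + seq_len(u)])
  hh <- tanh(p[2 * u + seq_len(u)] +
               drop((r * h_prev) %*% U[, 2 * u + seq_len(u), drop = FALSE]))
  (1 - z) * h_prev + z * hh
}

#' Run the bidirectional encoder over sequences
#'
#' Returns, per sequence, the `max_len` encoder hidden states (forward and
#' backward GRU states concatenated, dimension `2 * units`) and the encoder
#' final state used to initialise the decoder.
#'
#' @param model An [attn_init()] model (trained or not).
#' @param sequences Character vector of sequences over the model alphabet.
#' @return List with `states` (list of `max_len` x `2*units` matrices, one
#'   per sequence) and `final_state` (matrix `n` x `2*units`).
#' @export
attn_encode <- function(model, sequences) {
  stopifnot(inherits(model, "attn_model"))
  idx <- model_indices(model, sequences)
  p <- model$params; u <- model$config$units; Tn <- ncol(idx)
  onehot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
  A <- model$alphabet$size
  states <- vector("list", nrow(idx))
  fin <- matrix(0, nrow(idx), 2 * u)
  for (s in seq_len(nrow(idx))) {
    hf <- matrix(0, Tn, u); hb <- matrix(0, Tn, u)
    h <- numeric(u)
    for (t in seq_len(Tn)) {
      h <- gru_step_r(onehot(idx[s, t], A), h, p$Wf, p$Uf, p$bf)
      hf[t, ] <- h
    }
    h <- numeric(u)
    for (t in rev(seq_len(Tn))) {
      h <- gru_step_r(onehot(idx[s, t], A), h, p$Wb, p$Ub, p$bb)
      hb[t, ] <- h
    }
    states[[s]] <- cbind(hf, hb)
    fin[s, ] <- c(hf[Tn, ], hb[1, ])
  }
  list(states = states, final_state = fin)
}

#' Additive attention over encoder states
#'
#' Computes alignment scores `e_j = va' tanh(Was' s_prev + Uah' h_j + ba)`,
#' softmax-normalises them into attention weights, and returns the context
#' vector as the weighted sum of the encoder states. The weights are
#' non-negative and sum to 1, so the context lies in the convex hull of the
#' states.
#'
#' @param model An `"attn_model"`.
#' @param s_prev Decoder state before the (single) decoding step: numeric
#'   vector of length `2 * units`.
#' @param states Matrix of encoder states, `T` x `2*units` (rows are
#'   positions), as returned by [attn_encode()].
#' @param mask Optional logical vector of length `T`; positions with `FALSE`
#'   are excluded from the softmax.
#' @return List with `context` (length `2*units`), `weights` (length `T`,
#'   summing to 1) and `scores` (length `T`).
#' @export
attn_attention <- function(model, s_prev, states, mask = NULL) {
  p <- model$params
  sw <- drop(s_prev %*% p$Was) + drop(p$ba)
  a <- tanh(sweep(states %*% p$Uah, 2, sw, "+"))
  e <- drop(a %*% p$va)
  if (!is.null(mask)) e[!mask] <- -Inf
  w <- exp(e - max(e)); w <- w / sum(w)
  list(context = drop(w %*% states), weights = w, scores = e)
}

#' Single decoding step producing the scalar prediction
#'
#' Runs one step of the decoder BiGRU on the concatenation of the context
#' vector and the one-hot start symbol, initialised from the encoder final
#' state, and applies the single-unit dense head.
#'
#' @param model An `"attn_model"`.
#' @param context Context vector (length `2*units`).
#' @param final_state Encoder final state (length `2*units`).
#' @return A single numeric: the predicted (scaled) log intensity.
#' @export
attn_decode_scalar <- function(model, context, final_state) {
  p <- model$params; u <- model$config$units
  Ad <- model$alphabet$size + 1L
  xd <- c(context, numeric(Ad - 1L), 1)   # one-hot start symbol last
  df <- gru_step_r(xd, final_state[seq_len(u)], p$Vf, p$Qf, p$cf)
  db <- gru_step_r(xd, final_state[u + seq_len(u)], p$Vb, p$Qb, p$cb)
  drop(c(df, db) %*% p$wd) + p$bd
}

## ---- training and prediction ----------------------------------------------

#' Train the attention encoder-decoder
#'
#' Minimises mean squared error with Adam (optimizer defaults) over
#' mini-batches, recording training MSE/MAE and validation MAE per epoch.
#' Targets are expected already transformed and scaled (see [fit_minmax()]).
#' With `patience > 0` training stops once validation MAE has not improved
#' for that many epochs and the best-validation weights are kept.
#'
#' @param model An [attn_init()] model.
#' @param sequences,targets Training sequences and scaled targets.
#' @param val_sequences,val_targets Optional validation split (required for
#'   early stopping).
#' @param verbose Print per-epoch progress.
#' @return The trained model, with `history` (`train_mse`, `train_mae`,
#'   `val_mae`, `best_epoch`) attached.
#' @export
attn_train <- function(model, sequences, targets,
                       val_sequences = character(), val_targets = numeric(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "attn_model"))
  if (length(sequences) == 0) stop("empty training set")
  if (length(sequences) != length(targets))
    stop("sequences and targets must have equal length")
  cfg <- model$config
  idx <- model_indices(model, sequences)
  idx_val <- if (length(val_sequences))
    model_indices(model, val_sequences) else
      matrix(integer(), 0, cfg$max_len)
  fit <- cpp_train(model$params, idx, as.numeric(targets), idx_val,
                   as.numeric(val_targets),
                   epochs = cfg$epochs, batch_size = cfg$batch_size,
                   lr = cfg$learning_rate, patience = cfg$patience,
                   min_delta = cfg$min_delta %||% 0,
                   seed = cfg$seed, pad_idx = pad_index(model$alphabet),
                   mask_pad = cfg$mask_pad, verbose = verbose)
  model$params <- fit$params
  model$history <- list(train_mse = fit$train_mse, train_mae = fit$train_mae,
                        val_mae = fit$val_mae, best_epoch = fit$best_epoch)
  model$trained <- TRUE
  model
}

#' Predict scaled intensities and attention weights
#'
#' @param object A trained `"attn_model"`.
#' @param sequences Character vector of sequences over the model alphabet.
#' @param ... Unused.
#' @return List with `y_hat` (numeric vector, scaled log intensity scale) and
#'   `alpha` (matrix `n` x `max_len` of attention weights; each row sums
#'   to 1).
#' @export
predict.attn_model <- function(object, sequences, ...) {
  idx <- model_indices(object, sequences)
  out <- cpp_predict(object$params, idx,
                     pad_idx = pad_index(object$alphabet),
                     mask_pad = object$config$mask_pad, single = FALSE)
  list(y_hat = drop(out$yhat), alpha = out$alpha)
}
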