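#' Mean absolute percentage error
#'
#' `100 * mean(|y - y_hat| / |y|)`, the headline performance metric. All
#' true values must be nonzero; evaluation is always on log or real
#' intensities, both strictly positive.
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return MAPE in percent.
#' @export
mape <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (any(y == 0)) stop("MAPE undefined: zero true value")
  100 * mean(abs(y - y_hat) / abs(y))
}

#' Mean absolute and mean squared error
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return List with `mae` and `mse`.
#' @export
mae_mse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  list(mae = mean(abs(y - y_hat)), mse = mean((y - y_hat)^2))
}

## ---- learners --------------------------------------------------------------

#' Learner factories for the cross-validation harness
#'
#' A learner bundles a `fit(sequences, targets, val_sequences, val_targets,
#' seed)` function and a `predict(fit, sequences)` function returning either
#' a numeric vector or a list with `y_hat` (and optionally `alpha`).
#'
#' * `attention_learner()`: the BiGRU encoder-decoder with attention.
#' * `baseline_learner("ridge")`: ridge regression on the positional
#'   tabular (840-variable) encoding, penalty `lambda` in the classic
#'   `RSS + penalty * ||b||^2` parameterisation (fitted via glmnet).
#' * `baseline_learner("random_forest")`: random forest on the same
#'   encoding (ranger, 100 trees, unlimited depth).
#' * `dummy_learner()`: predicts the training mean (sanity floor).
#'
#' @param alphabet Alphabet used to encode sequences.
#' @param config An [attn_config()]; its seed is combined with the fold
#'   seed.
#' @return A learner list.
#' @export
attention_learner <- function(alphabet, config = attn_config()) {
  list(
    name = "attention",
    fit = function(sequences, targets, val_sequences, val_targets, seed) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      model <- attn_init(alphabet, cfg)
      attn_train(model, sequences, targets, val_sequences, val_targets)
    },
    predict = function(fit, sequences) predict(fit, sequences))
}

#' @rdname attention_learner
#' @param kind `"ridge"` or `"random_forest"`.
#' @param max_len Padded length for the tabular encoding.
#' @param penalty Ridge penalty (default 1).
#' @param num_trees Random-forest size (default 100).
#' @export
baseline_learner <- function(kind = c("ridge", "random_forest"), alphabet,
                             max_len = 40L, penalty = 1, num_trees = 100L) {
  kind <- match.arg(kind)
  enc <- function(sequences)
    positional_tabular_matrix(sequences, alphabet, max_len)
  if (kind == "ridge") {
    list(
      name = "ridge",
      fit = function(sequences, targets, val_sequences, val_targets, seed) {
        x <- enc(c(sequences, val_sequences))
        y <- c(targets, val_targets)
        # glmnet's objective is 1/(2n) RSS + lambda/2 ||b||^2 for alpha = 0;
        # lambda = penalty/n matches RSS + penalty ||b||^2.
        glmnet::glmnet(x, y, alpha = 0, lambda = penalty / length(y),
                       standardize = FALSE)
      },
      predict = function(fit, sequences)
        drop(stats::predict(fit, enc(sequences))))
  } else {
    list(
      name = "random_forest",
      fit = function(sequences, targets, val_sequences, val_targets, seed) {
        x <- enc(c(sequences, val_sequences))
        df <- data.frame(x)
        df$.y <- c(targets, val_targets)
        ranger::ranger(dependent.variable.name = ".y", data = df,
                       num.trees = num_trees, seed = seed)
      },
      predict = function(fit, sequences)
        stats::predict(fit, data.frame(enc(sequences)))$predictions)
  }
}

#' @rdname attention_learner
#' @export
dummy_learner <- function() {
  list(
    name = "dummy",
    fit = function(sequences, targets, val_sequences, val_targets, seed)
      mean(c(targets, val_targets)),
    predict = function(fit, sequences) rep(fit, length(sequences)))
}

## ---- cross-validation harness ----------------------------------------------

#' k-fold cross-validated evaluation of a learner
#'
#' Implements the full evaluation protocol: optional natural-log transform
#' of the targets, per-fold min-max scaling fitted on that fold's training
#' data only, training with an inner validation subset, prediction on the
#' held-out fold, inverse scaling, and metrics on both the unscaled log
#' scale and the real (exponentiated) scale. MAPE is never computed on the
#' min-max-scaled values, where a zero minimum would make it undefined.
#'
#' @param dataset A `"synthetic_dataset"`, or a list/tibble with `sequence`
#'   and `target` elements.
#' @param learner A learner from [attention_learner()],
#'   [baseline_learner()] or [dummy_learner()].
#' @param k Number of folds (default 5).
#' @param seed Seed driving fold assignment and per-fold training seeds.
#' @param log_target Natural-log transform the targets before scaling
#'   (default `TRUE`). With `FALSE` (already-linear targets) the "log"
#'   metrics are computed on the raw target scale and the real-scale
#'   metrics coincide with them.
#' @param scale_range Min-max target range `c(lo, hi)`.
#' @param val_fraction Inner validation fraction (default 0.2).
#' @return A `"metric_report"`: `per_fold` tibble, `summary` (mean and
#'   sample sd across folds for every metric), `predictions` (pooled
#'   held-out predictions with fold labels, log- and real-scale), and
#'   `alpha` (pooled held-out attention weights when the learner returns
#'   them, ordered as the input sequences).
#' @export
crossval <- function(dataset, learner, k = 5L, seed = 1L,
                     log_target = TRUE, scale_range = c(0, 1),
                     val_fraction = 0.2) {
  if (inherits(dataset, "synthetic_dataset")) dataset <- dataset$data
  sequences <- dataset$sequence
  targets <- dataset$target
  n <- length(sequences)
  y_work <- if (log_target) log_transform(targets) else targets
  folds <- kfold_split(n, k = k, val_fraction = val_fraction, seed = seed)

  per_fold <- NULL
  pred_log <- numeric(n)
  alpha <- NULL
  for (j in seq_len(k)) {
    test <- folds$fold == j
    val <- folds$val[, j]
    train <- !test & !val
    scaler <- fit_minmax(y_work[!test], scale_range[1], scale_range[2])
    fit <- learner$fit(sequences[train], minmax_apply(scaler, y_work[train]),
                       sequences[val], minmax_apply(scaler, y_work[val]),
                       seed = seed * 1000L + j)
    out <- learner$predict(fit, sequences[test])
    if (is.list(out)) {
      if (!is.null(out$alpha)) {
        if (is.null(alpha)) alpha <- matrix(NA_real_, n, ncol(out$alpha))
        alpha[test, ] <- out$alpha
      }
      out <- out$y_hat
    }
    yhat_log <- minmax_invert(scaler, out)
    pred_log[test] <- yhat_log
    m_log <- mae_mse(y_work[test], yhat_log)
    # degenerate learners (constant predictions) have no defined correlation
    cor_or_na <- function(a, b)
      if (stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
    row <- tibble::tibble(
      fold = j,
      mape_log = mape(y_work[test], yhat_log),
      pcc_log = cor_or_na(y_work[test], yhat_log),
      mae_log = m_log$mae, mse_log = m_log$mse,
      mape_real = if (log_target)
        mape(targets[test], exp(yhat_log)) else mape(y_work[test], yhat_log),
      pcc_real = if (log_target)
        cor_or_na(targets[test], exp(yhat_log)) else
          cor_or_na(y_work[test], yhat_log))
    per_fold <- rbind(per_fold, row)
  }
  metrics <- setdiff(names(per_fold), "fold")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]]), 0),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]]), 0))
  structure(list(
    learner = learner$name, per_fold = per_fold, summary = summary,
    predictions = tibble::tibble(
      sequence = sequences, fold = folds$fold, target = targets,
      y_hat_log = pred_log,
      y_hat_real = if (log_target) exp(pred_log) else pred_log),
    alpha = alpha, log_target = log_target, scale_range = scale_range,
    seed = seed),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> learner:", x$learner, " (", nrow(x$per_fold),
      "folds )\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %8.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Format a metric report as a benchmark table row
#'
#' @param reports List of `"metric_report"`s.
#' @return Tibble with one row per learner: MAPE (%) and PCC on
#'   log-transformed and real-scale data, as `mean +/- sd` strings.
#' @export
benchmark_table <- function(reports) {
  fmt <- function(r, m) {
    s <- r$summary
    sprintf("%.2f ± %.2f", s$mean[s$metric == m], s$sd[s$metric == m])
  }
  dplyr::bind_rows(lapply(reports, function(r) tibble::tibble(
    model = r$learner,
    mape_log = fmt(r, "mape_log"), pcc_log = fmt(r, "pcc_log"),
    mape_real = fmt(r, "mape_real"), pcc_real = fmt(r, "pcc_real"))))
}
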