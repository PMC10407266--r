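#' Sequence alphabets
#'
#' An alphabet fixes the channel order of all encodings: the symbols come
#' first (alphabetically for amino acids), followed by the padding channel
#' when variable-length sequences are allowed. A distinguished start symbol
#' (never part of encoder input) is carried for the decoder vocabulary.
#'
#' @param residues Character vector of single-character symbols.
#' @param pad Padding symbol, or `NULL` for fixed-length alphabets without a
#'   pad channel.
#' @param start Start-of-decoding symbol (must differ from all others).
#' @return An object of class `"attn_alphabet"` with elements `residues`,
#'   `pad`, `start`, `size` (number of encoder input channels) and `index`,
#'   the symbol-to-channel map.
#' @examples
#' aa_alphabet()          # 20 amino acids + pad: 21 channels
#' make_alphabet(LETTERS[1:10], pad = NULL)  # fixed-length, 10 channels
#' @export
make_alphabet <- function(residues, pad = "-", start = "^") {
  residues <- as.character(residues)
  stopifnot(length(residues) >= 1, all(nchar(residues) == 1))
  syms <- c(residues, pad)
  if (anyDuplicated(syms) || start %in% syms)
    stop("alphabet symbols (including pad and start) must be distinct")
  index <- seq_along(syms)
  names(index) <- syms
  structure(
    list(residues = residues, pad = pad, start = start,
         size = length(syms), index = index),
    class = "attn_alphabet")
}

#' @rdname make_alphabet
#' @export
aa_alphabet <- function() {
  make_alphabet(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], pad = "-")
}

#' @export
print.attn_alphabet <- function(x, ...) {
  cat("<attn_alphabet> ", x$size, " channels: ",
      paste(x$residues, collapse = ""),
      if (!is.null(x$pad)) paste0(" + pad '", x$pad, "'"),
      "; start '", x$start, "'\n", sep = "")
  invisible(x)
}

split1 <- function(s) strsplit(s, "")[[1]]

#' Map sequences to padded channel-index matrices
#'
#' Internal workhorse shared by the one-hot encoders and the model: each
#' sequence becomes one row of 1-based channel indices, padded to `max_len`
#' with the pad channel.
#'
#' @param sequences Character vector.
#' @inheritParams one_hot_encode
#' @return Integer matrix, `length(sequences)` x `max_len`.
#' @keywords internal
sequences_to_indices <- function(sequences, alphabet, max_len = 40L) {
  stopifnot(inherits(alphabet, "attn_alphabet"))
  n <- length(sequences)
  out <- matrix(NA_integer_, n, max_len)
  pad_idx <- if (is.null(alphabet$pad)) NA_integer_ else
    unname(alphabet$index[alphabet$pad])
  for (i in seq_len(n)) {
    ch <- split1(sequences[[i]])
    if (length(ch) > max_len)
      stop("sequence ", i, " has length ", length(ch),
           ", exceeding max_len = ", max_len)
    idx <- alphabet$index[ch]
    if (anyNA(idx)) {
      bad <- unique(ch[is.na(idx)])
      stop("unknown symbol(s) in sequence ", i, ": ",
           paste(bad, collapse = ", "))
    }
    if (length(ch) < max_len) {
      if (is.na(pad_idx))
        stop("sequence ", i, " is shorter than max_len and the alphabet ",
             "has no pad symbol")
      idx <- c(idx, rep(pad_idx, max_len - length(ch)))
    }
    out[i, ] <- unname(idx)
  }
  out
}

#' One-hot encode a sequence
#'
#' Encodes a single sequence as a `max_len` x `alphabet$size` binary matrix:
#' row `t` carries a single 1 in the channel of the symbol at position `t`;
#' rows beyond the sequence length carry the pad channel. Every row sums to
#' exactly 1.
#'
#' @param sequence A single character string.
#' @param alphabet An [make_alphabet()] object.
#' @param max_len Padded length (default 40, the model's maximum peptide
#'   length).
#' @return Binary matrix of dimension `max_len` x `alphabet$size` with
#'   dimnames `position` x symbol.
#' @examples
#' m <- one_hot_encode("ACK", aa_alphabet())
#' all(rowSums(m) == 1)
#' @export
one_hot_encode <- function(sequence, alphabet, max_len = 40L) {
  stopifnot(length(sequence) == 1)
  idx <- sequences_to_indices(sequence, alphabet, max_len)[1, ]
  m <- matrix(0L, max_len, alphabet$size,
              dimnames = list(NULL, names(alphabet$index)))
  m[cbind(seq_len(max_len), idx)] <- 1L
  m
}

#' Positional tabular encoding for baseline models
#'
#' Flattens the one-hot matrix in position-major, symbol-minor order into a
#' single binary vector with one variable per (symbol, position) pair:
#' `max_len * alphabet$size` variables in total (840 for 21 channels over 40
#' positions). Exactly `max_len` entries are 1.
#'
#' @inheritParams one_hot_encode
#' @return Named binary integer vector of length `max_len * alphabet$size`.
#' @export
positional_tabular_encode <- function(sequence, alphabet, max_len = 40L) {
  m <- one_hot_encode(sequence, alphabet, max_len)
  v <- as.integer(t(m))
  names(v) <- paste0(rep(colnames(m), times = max_len), "_",
                     rep(seq_len(max_len), each = alphabet$size))
  v
}

#' Positional tabular design matrix for a set of sequences
#'
#' @param sequences Character vector.
#' @inheritParams one_hot_encode
#' @return Binary matrix, `length(sequences)` x `max_len * alphabet$size`.
#' @export
positional_tabular_matrix <- function(sequences, alphabet, max_len = 40L) {
  idx <- sequences_to_indices(sequences, alphabet, max_len)
  n <- nrow(idx)
  p <- max_len * alphabet$size
  out <- matrix(0L, n, p)
  # variable for (symbol s, position t) sits at column (t-1)*size + s
  for (t in seq_len(max_len)) {
    out[cbind(seq_len(n), (t - 1L) * alphabet$size + idx[, t])] <- 1L
  }
  colnames(out) <- paste0(rep(names(alphabet$index), times = max_len), "_",
                          rep(seq_len(max_len), each = alphabet$size))
  out
}

#' Natural-log transform of intensities
#'
#' MS1 intensities span several orders of magnitude and are modelled on the
#' natural-log scale. Zero intensities must be filtered before this step.
#'
#' @param intensity Positive numeric vector.
#' @return `log(intensity)`; `log_inverse()` is `exp()` restricted to the
#'   same contract.
#' @export
log_transform <- function(intensity) {
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("log_transform requires strictly positive finite intensities")
  log(intensity)
}

#' @rdname log_transform
#' @param x Numeric vector on the log scale.
#' @export
log_inverse <- function(x) exp(x)

#' Min-max scaling of targets
#'
#' Fits an affine map sending the observed minimum to `target_lo` and the
#' observed maximum to `target_hi`. Values outside the fitted range (e.g.
#' test-set targets beyond the training range) extrapolate linearly. The
#' scaler is always fitted on training data only.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param target_lo,target_hi Target range endpoints (default `[0, 1]`).
#' @return An object of class `"minmax_scaler"`.
#' @examples
#' sc <- fit_minmax(c(10, 20))
#' minmax_apply(sc, 15)    # 0.5
#' minmax_invert(sc, 1.5)  # 25
#' @export
fit_minmax <- function(values, target_lo = 0, target_hi = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stop("cannot fit a min-max scaler on constant input")
  if (target_hi <= target_lo) stop("target_hi must exceed target_lo")
  structure(list(observed_min = lo, observed_max = hi,
                 target_lo = target_lo, target_hi = target_hi),
            class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler A fitted `"minmax_scaler"`.
#' @param x Numeric vector.
#' @export
minmax_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  scaler$target_lo + (x - scaler$observed_min) /
    (scaler$observed_max - scaler$observed_min) *
    (scaler$target_hi - scaler$target_lo)
}

#' @rdname fit_minmax
#' @export
minmax_invert <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  scaler$observed_min + (x - scaler$target_lo) /
    (scaler$target_hi - scaler$target_lo) *
    (scaler$observed_max - scaler$observed_min)
}

#' k-fold cross-validation assignment with inner validation subsets
#'
#' Partitions `n_items` into `k` folds of near-equal size (sizes differ by at
#' most 1). For each test fold, a fraction `val_fraction` of the remaining
#' training items is marked as the validation subset used to monitor
#' overfitting during training. Fully deterministic given `seed`.
#'
#' @param n_items Number of items (must be at least `k`).
#' @param k Number of folds (default 5).
#' @param val_fraction Fraction of each training split held out for
#'   validation (default 0.2).
#' @param seed Integer seed.
#' @return An object of class `"fold_assignment"`: `fold` (integer vector in
#'   `1..k`) and `val`, an `n_items` x `k` logical matrix whose column `j`
#'   flags validation items when fold `j` is the test fold (`FALSE` for the
#'   test items themselves).
#' @export
kfold_split <- function(n_items, k = 5L, val_fraction = 0.2, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  if (n_items < k) stop("n_items must be at least k")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n_items))
  val <- matrix(FALSE, n_items, k)
  for (j in seq_len(k)) {
    train_idx <- which(fold != j)
    n_val <- floor(val_fraction * length(train_idx))
    if (n_val > 0) val[sample(train_idx, n_val), j] <- TRUE
  }
  structure(list(fold = fold, val = val, k = k,
                 val_fraction = val_fraction, seed = seed),
            class = "fold_assignment")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
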