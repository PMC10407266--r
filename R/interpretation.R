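#' Parse an AAindex1 flat file
#'
#' AAindex1 records are delimited by `//`; the `H` line carries the
#' accession, `D` lines the description, and the `I` line is followed by two
#' rows of ten values in the standard residue layout
#' (`A R N D C Q E G H I` / `L K M F P S T W Y V`). `NA` entries are kept as
#' missing values.
#'
#' @param path Path to an AAindex1-format file.
#' @return List of `"property_index"` objects, each with `accession`,
#'   `description` and `values` (named numeric of length 20, possibly with
#'   `NA`s).
#' @export
parse_aaindex1 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  row1 <- strsplit("A R N D C Q E G H I", " ")[[1]]
  row2 <- strsplit("L K M F P S T W Y V", " ")[[1]]
  out <- list()
  rec <- NULL
  fresh <- function() list(accession = NA_character_, description = "",
                           values = NULL, ivals = character(0),
                           in_d = FALSE, in_i = FALSE)
  rec <- fresh()
  flush_rec <- function(rec) {
    if (is.na(rec$accession)) return(NULL)
    v <- suppressWarnings(as.numeric(rec$ivals))
    bad <- is.na(v) & !(toupper(rec$ivals) %in% c("NA", "NA."))
    if (length(rec$ivals) != 20 || any(bad))
      stop("malformed value block in AAindex1 record ",
           rec$accession)
    names(v) <- c(row1, row2)
    structure(list(accession = rec$accession,
                   description = trimws(rec$description),
                   values = v),
              class = "property_index")
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 1)
    body <- trimws(substr(ln, 2, nchar(ln)))
    if (tag == "H") {
      rec$accession <- body
      rec$in_d <- rec$in_i <- FALSE
    } else if (tag == "D") {
      rec$description <- paste0(rec$description, body)
      rec$in_d <- TRUE; rec$in_i <- FALSE
    } else if (tag == "I") {
      rec$in_i <- TRUE; rec$in_d <- FALSE
    } else if (tag == "/" && startsWith(ln, "//")) {
      p <- flush_rec(rec)
      if (!is.null(p)) out[[p$accession]] <- p
      rec <- fresh()
    } else if (tag == " " || tag == "\t") {
      if (rec$in_i)
        rec$ivals <- c(rec$ivals, strsplit(body, "\\s+")[[1]])
      else if (rec$in_d)
        rec$description <- paste(rec$description, body)
    } else {
      rec$in_d <- rec$in_i <- FALSE
    }
  }
  p <- flush_rec(rec)
  if (!is.null(p)) out[[p$accession]] <- p
  unname(out)
}

#' @export
print.property_index <- function(x, ...) {
  cat("<property_index> ", x$accession, ": ", x$description, "\n", sep = "")
  invisible(x)
}

#' Average attention weights per amino acid
#'
#' Turns per-prediction attention weights into a per-residue relevance
#' profile: weights are first averaged within each sequence over the
#' positions holding the same residue (pad positions are excluded), and the
#' per-sequence means are then averaged across sequences. With
#' `presence_conditioned = TRUE` (default) the across-sequence denominator
#' is the number of sequences containing the residue; otherwise it is the
#' total number of sequences (which deflates rare residues toward zero).
#' Residues never observed are absent from the profile.
#'
#' @param sequences Character vector of sequences.
#' @param alphas Matrix of attention weights, `length(sequences)` x
#'   `max_len` (rows may extend past each sequence's length into padding).
#' @param presence_conditioned Across-sequence averaging semantics (see
#'   above).
#' @return Tibble with `residue`, `mean_weight`, `n_sequences_containing`,
#'   sorted by decreasing weight.
#' @export
mean_attention_per_aa <- function(sequences, alphas,
                                  presence_conditioned = TRUE) {
  if (is.list(alphas)) alphas <- do.call(rbind, alphas)
  if (nrow(alphas) != length(sequences))
    stop("alphas must have one row per sequence")
  n <- length(sequences)
  sums <- list()
  counts <- list()
  present <- list()
  for (i in seq_len(n)) {
    ch <- split1(sequences[[i]])
    if (length(ch) > ncol(alphas))
      stop("sequence ", i, " is longer than its attention weight vector")
    w <- alphas[i, seq_along(ch)]
    m <- tapply(w, ch, mean)
    for (r in names(m)) {
      sums[[r]] <- (sums[[r]] %||% 0) + m[[r]]
      present[[r]] <- (present[[r]] %||% 0L) + 1L
    }
  }
  res <- sort(names(sums))
  denom <- if (presence_conditioned) unlist(present[res]) else rep(n, length(res))
  out <- tibble::tibble(residue = res,
                        mean_weight = unname(unlist(sums[res]) / denom),
                        n_sequences_containing =
                          unname(unlist(present[res])))
  out[order(-out$mean_weight), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation with its two-sided p-value
#'
#' Pairwise-deletes missing entries, then computes Pearson's r and the
#' two-sided p-value from the t transform `t = r sqrt((n-2)/(1-r^2))` with
#' `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors (at least 3 complete pairs).
#' @return List with `pcc`, `p_value` and `n` (complete pairs used).
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(pcc = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Screen AAindex1 indices against an attention profile
#'
#' Correlates the per-residue mean attention weights with each property
#' index and reports those with `|PCC|` at or above the threshold
#' (inclusive), sorted by `|PCC|` descending with ties broken by accession.
#' A Benjamini-Hochberg adjusted p-value is included as supplementary
#' output; the significance call itself uses the fixed `|PCC|` cutoff.
#'
#' @param profile Tibble from [mean_attention_per_aa()].
#' @param indices List of `"property_index"` objects
#'   ([parse_aaindex1()]).
#' @param threshold Absolute-PCC cutoff (default 0.7).
#' @return Tibble with `accession`, `description`, `pcc`, `p_value`, `n`,
#'   `p_adj_bh` for the indices passing the cutoff.
#' @export
rank_significant <- function(profile, indices, threshold = 0.7) {
  w <- profile$mean_weight
  names(w) <- profile$residue
  rows <- lapply(indices, function(ix) {
    shared <- intersect(names(w), names(ix$values)[is.finite(ix$values)])
    if (length(shared) < 3) return(NULL)
    r <- pearson_with_p(w[shared], ix$values[shared])
    tibble::tibble(accession = ix$accession, description = ix$description,
                   pcc = r$pcc, p_value = r$p_value, n = r$n)
  })
  all <- dplyr::bind_rows(rows)
  if (nrow(all) == 0) return(all)
  all$p_adj_bh <- stats::p.adjust(all$p_value, method = "BH")
  hit <- all[abs(all$pcc) >= threshold, , drop = FALSE]
  hit[order(-abs(hit$pcc), hit$accession), ]
}

#' Side-chain and terminal pKa values used for net-charge computation
#'
#' @return Named numeric vector of pKa values (Asp, Glu, His, Cys, Tyr, Lys,
#'   Arg side chains plus N- and C-terminus).
#' @export
pka_table <- function() {
  c(D = 3.65, E = 4.25, H = 6.0, C = 8.3, Y = 10.07, K = 10.53, R = 12.48,
    Nterm = 9.0, Cterm = 2.0)
}

#' Sequence descriptors used in the charge/hydrophobicity sanity checks
#'
#' Computes, for one peptide: the sum and mean of a property index over its
#' residues (when an index is supplied), the count of positively charged
#' residues (Arg, Lys, His), the net charge at the given pH by
#' Henderson-Hasselbalch summation over ionizable side chains and the two
#' termini (see [pka_table()]), and length-normalized variants.
#'
#' @param sequence Peptide over the 20 standard letters.
#' @param index Optional `"property_index"`; if it lacks a residue present
#'   in the sequence the index descriptors are `NA`.
#' @param pH Optional numeric vector of pH values at which to compute net
#'   charge (e.g. `c(7, 3)`).
#' @return One-row tibble: `length`, `n_positive`,
#'   `n_positive_per_length`, then `net_charge_pH<p>` and
#'   `net_charge_per_length_pH<p>` per requested pH, then `index_sum` and
#'   `index_mean` when an index was given.
#' @export
peptide_descriptors <- function(sequence, index = NULL, pH = NULL) {
  ch <- split1(sequence)
  if (!all(ch %in% split1("ACDEFGHIKLMNPQRSTVWY")))
    stop("sequence contains non-standard residues")
  L <- length(ch)
  out <- tibble::tibble(length = L,
                        n_positive = sum(ch %in% c("R", "K", "H")),
                        n_positive_per_length =
                          sum(ch %in% c("R", "K", "H")) / L)
  if (!is.null(pH)) {
    pk <- pka_table()
    for (p in pH) {
      pos <- 1 / (1 + 10^(p - pk["Nterm"])) +
        sum(vapply(c("K", "R", "H"),
                   function(r) sum(ch == r) / (1 + 10^(p - pk[r])), 0))
      neg <- 1 / (1 + 10^(pk["Cterm"] - p)) +
        sum(vapply(c("D", "E", "C", "Y"),
                   function(r) sum(ch == r) / (1 + 10^(pk[r] - p)), 0))
      q <- unname(pos - neg)
      out[[paste0("net_charge_pH", p)]] <- q
      out[[paste0("net_charge_per_length_pH", p)]] <- q / L
    }
  }
  if (!is.null(index)) {
    v <- index$values[ch]
    if (anyNA(v)) {
      out$index_sum <- NA_real_
      out$index_mean <- NA_real_
    } else {
      out$index_sum <- sum(v)
      out$index_mean <- mean(v)
    }
  }
  out
}
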