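test_that("AAindex1 records parse with values, continuation lines and NAs", {
  set.seed(4)
  vals1 <- round(runif(20, -2, 2), 3); names(vals1) <- aa20
  vals2 <- vals1; vals2[c("W", "Y")] <- NA
  path <- write_aaindex_fixture(list(
    list(accession = "TEST000101", description = "A synthetic hydropathy scale",
         values = vals1),
    list(accession = "TEST000102", description = "A scale with missing values",
         values = vals2)))
  idx <- parse_aaindex1(path)
  expect_length(idx, 2)
  expect_equal(idx[[1]]$accession, "TEST000101")
  expect_equal(sort(names(idx[[1]]$values)), sort(aa20))
  expect_equal(unname(idx[[1]]$values[aa20]), unname(vals1[aa20]))
  expect_equal(sum(is.na(idx[[2]]$values)), 2)

  # malformed value block names the record
  bad <- readLines(path)
  bad <- bad[-9]                        # drop one value row of record 1
  badpath <- tempfile(); writeLines(bad, badpath)
  expect_error(parse_aaindex1(badpath), "TEST000101")
})

test_that("per-amino-acid attention averaging is a two-level mean", {
  # "AAC" with weights .5/.3/.2: within-sequence means A = .4, C = .2
  p1 <- mean_attention_per_aa("AAC", matrix(c(0.5, 0.3, 0.2), 1))
  expect_equal(p1$mean_weight[p1$residue == "A"], 0.4)
  expect_equal(p1$mean_weight[p1$residue == "C"], 0.2)

  # adding "C" with weight 1: C = (0.2 + 1)/2 = 0.6 over sequences containing C
  al <- matrix(0, 2, 3); al[1, ] <- c(0.5, 0.3, 0.2); al[2, 1] <- 1
  p2 <- mean_attention_per_aa(c("AAC", "C"), al)
  expect_equal(p2$mean_weight[p2$residue == "C"], 0.6)
  expect_equal(p2$mean_weight[p2$residue == "A"], 0.4)
  expect_equal(p2$n_sequences_containing[p2$residue == "A"], 1)
  expect_false("D" %in% p2$residue)     # unobserved residues are absent

  # total-count semantics deflate residues missing from some sequences
  p3 <- mean_attention_per_aa(c("AAC", "C"), al, presence_conditioned = FALSE)
  expect_equal(p3$mean_weight[p3$residue == "A"], 0.2)

  # brute-force two-level group-by oracle on random batches (pads excluded)
  set.seed(12)
  for (rep in 1:3) {
    seqs <- replicate(20, paste(sample(aa20[1:8], sample(3:6, 1), TRUE),
                                collapse = ""))
    al <- matrix(runif(20 * 6), 20, 6)
    got <- mean_attention_per_aa(seqs, al)
    for (r in unique(unlist(strsplit(seqs, "")))) {
      per_seq <- vapply(seq_along(seqs), function(i) {
        ch <- strsplit(seqs[i], "")[[1]]
        if (!r %in% ch) return(NA_real_)
        mean(al[i, which(ch == r)])
      }, 0)
      expect_equal(got$mean_weight[got$residue == r],
                   mean(per_seq, na.rm = TRUE))
    }
  }

  expect_error(mean_attention_per_aa("ACDEFG", matrix(1, 1, 3)), "longer")
})

test_that("pearson_with_p matches the t-transform and is symmetric and affine-invariant", {
  set.seed(2)
  x <- rnorm(20); y <- x + rnorm(20)
  r <- pearson_with_p(x, y)
  expect_equal(r$pcc, cor(x, y))
  tstat <- r$pcc * sqrt((20 - 2) / (1 - r$pcc^2))
  expect_equal(r$p_value, 2 * pt(abs(tstat), df = 18, lower.tail = FALSE))
  expect_equal(pearson_with_p(y, x)$pcc, r$pcc)
  expect_equal(pearson_with_p(2 * x + 3, y)$pcc, r$pcc)

  expect_equal(pearson_with_p(x, x)$pcc, 1)
  expect_error(pearson_with_p(x, rep(1, 20)), "zero variance")
  # pairwise deletion of missing entries
  xm <- x; xm[1:2] <- NA
  expect_equal(pearson_with_p(xm, y)$n, 18)

  # r = 0.7 at n = 20: frozen two-sided p from the t oracle,
  # t = 0.7 * sqrt(18 / (1 - 0.49)) = 4.1588, p ~ 5.8e-4
  z <- residuals(lm(rnorm(20) ~ x))
  y70 <- 0.7 * scale(x) + sqrt(1 - 0.49) * scale(z)
  r70 <- pearson_with_p(x, as.numeric(y70))
  expect_equal(r70$pcc, 0.7, tolerance = 1e-10)
  expect_equal(r70$p_value, 5.8e-4, tolerance = 0.01)
})

test_that("index screening is |PCC|-inclusive, ranked, and recovers a planted index", {
  set.seed(31)
  base <- runif(20); names(base) <- aa20
  profile <- tibble::tibble(residue = aa20, mean_weight = unname(base),
                            n_sequences_containing = 100L)
  mk_ix <- function(acc, v) structure(
    list(accession = acc, description = acc, values = v),
    class = "property_index")

  prop <- mk_ix("PROP000101", base * 3 + 1)       # exactly proportional
  flip <- mk_ix("FLIP000101", -base)              # sign-flipped
  decoys <- lapply(1:20, function(i)
    mk_ix(sprintf("DECY%06d", i), setNames(runif(20), aa20)))
  hits <- rank_significant(profile, c(list(prop, flip), decoys))
  expect_equal(hits$accession[1:2], c("FLIP000101", "PROP000101"))  # tie on |1|
  expect_equal(hits$pcc[hits$accession == "PROP000101"], 1)
  expect_equal(hits$pcc[hits$accession == "FLIP000101"], -1)
  expect_true(all(abs(hits$pcc) >= 0.7))

  # boundary |pcc| exactly at the threshold is reported
  x <- profile$mean_weight
  # construct y with cor(x, y) == 0.7 exactly
  z <- residuals(lm(runif(20) ~ x))
  y <- 0.7 * scale(x) + sqrt(1 - 0.49) * scale(z)
  expect_equal(cor(x, y)[1], 0.7, tolerance = 1e-12)
  bnd <- mk_ix("BNDY000101", setNames(as.numeric(y), aa20))
  expect_true("BNDY000101" %in% rank_significant(profile, list(bnd))$accession)

  # planted index + 10% noise ranks first in >= 95% of 100 seeded repetitions
  set.seed(77)
  wins <- 0
  for (i in 1:100) {
    noisy <- base + rnorm(20, 0, 0.1 * sd(base))
    prof_i <- tibble::tibble(residue = aa20, mean_weight = unname(noisy),
                             n_sequences_containing = 100L)
    top <- rank_significant(prof_i, c(list(prop), decoys), threshold = 0)
    wins <- wins + (top$accession[1] == "PROP000101")
  }
  expect_gte(wins, 95)
})

test_that("peptide descriptors compute charge counts, net charge and index sums", {
  expect_equal(peptide_descriptors("KRHA")$n_positive, 3)

  # two-term Henderson-Hasselbalch check: GG at pH 7 is ~ +0.99 - 1.00
  gg <- peptide_descriptors("GG", pH = 7)
  expect_equal(gg$net_charge_pH7,
               1 / (1 + 10^(7 - 9)) - 1 / (1 + 10^(2 - 7)), tolerance = 1e-12)
  expect_lt(abs(gg$net_charge_pH7 - (-0.01)), 0.001)

  # acidic pH protonates the termini: net charge approaches +1 for GG at pH 3
  gg3 <- peptide_descriptors("GG", pH = c(7, 3))
  expect_gt(gg3$net_charge_pH3, gg3$net_charge_pH7)

  ix <- structure(list(accession = "X", description = "x",
                       values = setNames(rep(0.5, 20), aa20)),
                  class = "property_index")
  d <- peptide_descriptors("AA", index = ix)
  expect_equal(d$index_sum, 1)
  expect_equal(d$index_mean, 0.5)

  ix$values["A"] <- NA
  expect_true(is.na(peptide_descriptors("AA", index = ix)$index_sum))
  expect_error(peptide_descriptors("AXZ"), "non-standard")
})
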