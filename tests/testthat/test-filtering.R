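test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)  # sd 1, mean 2
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-2, 1)), "positive mean")
})

test_that("quality filters remove PEP/reverse/contaminant/zero-intensity in order", {
  mk <- function(pep = 0.001, rev = FALSE, con = FALSE, int = 1e6)
    tibble::tibble(sequence = "ACDK", intensity = int, pep = pep,
                   reverse = rev, contaminant = con, pool_id = "p")
  five <- dplyr::bind_rows(mk(pep = 0.05), mk(rev = TRUE), mk(con = TRUE),
                           mk(int = 0), mk())
  res <- apply_quality_filters(five)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$report$removed, rep(1, 4))
  expect_equal(res$report$stage,
               c("pep", "reverse", "contaminant", "zero_intensity"))
  # stages compose
  expect_equal(res$report$surviving[-4], res$report$input[-1])

  # the PEP boundary is inclusive on removal
  boundary <- apply_quality_filters(mk(pep = 0.01))
  expect_equal(nrow(boundary$records), 0)
  kept <- apply_quality_filters(mk(pep = 0.005))
  expect_equal(nrow(kept$records), 1)

  empty <- apply_quality_filters(five[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$report$removed, rep(0, 4))
})

test_that("quality filtering matches a one-pass predicate oracle and is order-insensitive", {
  for (seed in 1:5) {
    d <- random_measurements(300, seed)
    res <- apply_quality_filters(d)
    # independent one-pass enumeration of the four predicates
    keep <- d$pep < 0.01 & !d$reverse & !d$contaminant & d$intensity > 0
    expect_equal(nrow(res$records), sum(keep))
    expect_equal(res$records$sequence, d$sequence[keep])
    # per-stage counts from sequential enumeration
    k1 <- d$pep < 0.01
    k2 <- k1 & !d$reverse
    k3 <- k2 & !d$contaminant
    k4 <- k3 & d$intensity > 0
    expect_equal(res$report$removed,
                 c(sum(!k1), sum(k1) - sum(k2), sum(k2) - sum(k3),
                   sum(k3) - sum(k4)))
    # surviving set invariant under criterion order (zero-intensity first)
    alt <- d[d$intensity > 0, ]
    alt <- apply_quality_filters(alt)$records
    expect_setequal(
      paste(alt$sequence, alt$pool_id, alt$intensity),
      paste(res$records$sequence, res$records$pool_id,
            res$records$intensity))
  }
})

test_that("replicate merging takes the median, drops singletons and applies the CV cutoff", {
  d <- tibble::tibble(
    sequence = c(rep("AAAK", 3), rep("CCCK", 3), rep("DDDK", 2), "EEEK"),
    intensity = c(10, 10, 10, 1, 2, 3, 100, 110, 5e5),
    pep = 0.001, reverse = FALSE, contaminant = FALSE,
    pool_id = paste0("p", c(1:3, 1:3, 1:2, 1)),
    enzyme = "Trypsin", enzyme_mode = "specific")
  res <- merge_replicates(d)
  # AAAK: cv 0 kept; CCCK: cv 0.5 removed; DDDK: median 105, cv ~0.0673 kept;
  # EEEK: single measurement dropped
  expect_setequal(res$peptides$sequence, c("AAAK", "DDDK"))
  expect_equal(res$peptides$median_intensity[res$peptides$sequence == "DDDK"],
               105)
  expect_equal(res$peptides$cv[res$peptides$sequence == "DDDK"],
               sd(c(100, 110)) / 105)
  expect_equal(res$report$stage, c("merge", "single_measurement", "cv"))
  expect_equal(res$report$removed, c(9 - 4, 1, 1))
  expect_true(all(res$peptides$cv <= 0.3))

  # singletons kept when replicates are not required (cv undefined)
  res2 <- merge_replicates(d, require_replicates = FALSE)
  expect_true("EEEK" %in% res2$peptides$sequence)
})

test_that("lowering the CV cutoff never increases the survivor count", {
  d <- random_measurements(500, 99)
  d <- apply_quality_filters(d)$records
  counts <- vapply(c(0.5, 0.3, 0.2, 0.1, 0.05),
                   function(cv) nrow(merge_replicates(d, cv_max = cv)$peptides),
                   0)
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation selects on search metadata only", {
  d <- tibble::tibble(
    sequence = c("AK", "CK", "DK", "EK"),
    enzyme = c("Trypsin", "LysN", "Trypsin", "AspN"),
    enzyme_mode = c("specific", "specific", "unspecific", "semi-specific"))
  expect_equal(segment_dataset(d, "Trypsin", "specific")$sequence, "AK")
  expect_equal(segment_dataset(d, "any", "any"), d)
  expect_equal(nrow(segment_dataset(d[0, ], "Trypsin", "specific")), 0)

  # metadata-based trypticity can disagree with the K/R-terminus test
  aud <- audit_tryptic(tibble::tibble(sequence = c("AAAK", "AAAP"),
                                      enzyme = c("LysN", "Trypsin")))
  expect_equal(attr(aud, "n_disagree"), 2)
})

test_that("the full cascade composes and its report is internally consistent", {
  d <- random_measurements(600, 7)
  res <- filter_cascade(d, enzyme = "Trypsin", mode = "specific")
  expect_true(all(res$report$input - res$report$removed ==
                    res$report$surviving))
  expect_true(all(res$peptides$enzyme == "Trypsin"))
  expect_true(all(res$peptides$cv <= 0.3))
  expect_true(all(res$peptides$n_measurements >= 2))
  expect_true(all(res$peptides$median_intensity > 0))

  # report serialises to JSON
  path <- tempfile(fileext = ".json")
  write_filter_report(res$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$surviving, res$report$surviving)
})
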