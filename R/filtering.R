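#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, the
#' replicate-consistency statistic used to filter peptides whose MS1
#' intensities vary too much across pools.
#'
#' @param values Numeric vector of at least two positive intensities.
#' @return `sd(values) / mean(values)`.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 0.5
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2)
    stop("coefficient of variation requires at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("coefficient of variation requires a positive mean")
  stats::sd(values) / m
}

new_filter_report <- function(stage, input, removed) {
  tibble::tibble(stage = stage, input = input, removed = removed,
                 surviving = input - removed)
}

#' Quality-based filtering of peptide measurements
#'
#' Applies, in order: removal of identifications with PEP at or above
#' `pep_max` (the boundary is inclusive on removal), removal of reverse-hit
#' (decoy) sequences, removal of potential contaminants, and removal of
#' zero-intensity measurements. The report counts removals per criterion in
#' application order, so later stages count only records that survived the
#' earlier ones.
#'
#' @param records Tibble of assembled measurements (columns `pep`,
#'   `reverse`, `contaminant`, `intensity`).
#' @param pep_max PEP threshold (default 0.01; a record with `pep ==
#'   pep_max` is removed).
#' @return List with `records` (survivors) and `report` (a per-stage
#'   tibble: `stage`, `input`, `removed`, `surviving`).
#' @export
apply_quality_filters <- function(records, pep_max = 0.01) {
  stages <- list(
    pep = function(d) d$pep < pep_max,
    reverse = function(d) !d$reverse,
    contaminant = function(d) !d$contaminant,
    zero_intensity = function(d) d$intensity > 0)
  report <- NULL
  for (nm in names(stages)) {
    keep <- if (nrow(records)) stages[[nm]](records) else logical(0)
    report <- rbind(report,
                    new_filter_report(nm, nrow(records), sum(!keep)))
    records <- records[keep, , drop = FALSE]
  }
  list(records = records, report = report)
}

#' Merge peptide replicates across pools
#'
#' Collapses all measurements of the same sequence (across pools) into one
#' record carrying the median intensity, the coefficient of variation of the
#' per-pool intensities, and the measurement count, then applies the
#' replication and variation filters: peptides observed only once are
#' dropped when `require_replicates` (their CV is undefined), and peptides
#' with CV above `cv_max` are dropped. Enzyme metadata is carried as the
#' sorted set of observed tags (a single tag when unambiguous).
#'
#' @param records Quality-filtered measurements.
#' @param cv_max CV threshold (default 0.3; strictly greater is removed).
#' @param require_replicates Drop single-measurement peptides (default
#'   `TRUE`).
#' @return List with `peptides` (tibble: `sequence`, `median_intensity`,
#'   `cv`, `n_measurements`, `enzyme`, `enzyme_mode`) and `report`
#'   (stages `merge`, `single_measurement`, `cv`). The `merge` stage counts
#'   rows collapsed away by merging; the later stages count merged peptides
#'   removed.
#' @export
merge_replicates <- function(records, cv_max = 0.3,
                             require_replicates = TRUE) {
  has_meta <- all(c("enzyme", "enzyme_mode") %in% names(records))
  grp <- dplyr::group_by(records, .data$sequence)
  merged <- dplyr::summarise(
    grp,
    median_intensity = stats::median(.data$intensity),
    cv = if (dplyr::n() >= 2)
      coefficient_of_variation(.data$intensity) else NA_real_,
    n_measurements = dplyr::n(),
    enzyme = if (has_meta)
      paste(sort(unique(.data$enzyme)), collapse = ";") else NA_character_,
    enzyme_mode = if (has_meta)
      paste(sort(unique(.data$enzyme_mode)), collapse = ";") else
        NA_character_,
    .groups = "drop")

  report <- new_filter_report("merge", nrow(records),
                              nrow(records) - nrow(merged))
  if (require_replicates) {
    keep <- merged$n_measurements >= 2
    report <- rbind(report, new_filter_report("single_measurement",
                                              nrow(merged), sum(!keep)))
    merged <- merged[keep, , drop = FALSE]
  }
  keep <- is.na(merged$cv) | merged$cv <= cv_max
  # NA cv only possible when require_replicates = FALSE (singletons kept)
  report <- rbind(report, new_filter_report("cv", nrow(merged), sum(!keep)))
  merged <- merged[keep, , drop = FALSE]
  list(peptides = merged, report = report)
}

#' Subset peptides by search enzyme and enzyme mode
#'
#' Metadata-based segmentation: selects records whose MaxQuant search
#' settings match the requested enzyme and digestion mode. Selection is by
#' the recorded search metadata, never by a sequence-pattern test (a
#' "tryptic" peptide here is one searched with Trypsin, not one ending in
#' K/R); [audit_tryptic()] reports the disagreement between the two
#' definitions.
#'
#' @param peptides Tibble with `enzyme` and `enzyme_mode` columns (either
#'   measurements or merged peptides).
#' @param enzyme Enzyme to keep, or `"any"`.
#' @param mode Enzyme mode to keep, or `"any"`.
#' @return The matching subset.
#' @export
segment_dataset <- function(peptides, enzyme = "any", mode = "any") {
  keep <- rep(TRUE, nrow(peptides))
  if (!identical(enzyme, "any")) keep <- keep & peptides$enzyme == enzyme
  if (!identical(mode, "any")) keep <- keep & peptides$enzyme_mode == mode
  peptides[keep & !is.na(keep), , drop = FALSE]
}

#' Audit metadata-based vs sequence-based trypticity
#'
#' @param peptides Tibble with `sequence` and `enzyme` columns.
#' @return Tibble with per-peptide flags `tryptic_metadata` (searched with
#'   Trypsin) and `tryptic_terminus` (C-terminal K or R) and the overall
#'   disagreement count as attribute `n_disagree`.
#' @export
audit_tryptic <- function(peptides) {
  meta <- peptides$enzyme == "Trypsin"
  term <- grepl("[KR]$", peptides$sequence)
  out <- tibble::tibble(sequence = peptides$sequence,
                        tryptic_metadata = meta, tryptic_terminus = term)
  attr(out, "n_disagree") <- sum(meta != term, na.rm = TRUE)
  out
}

#' Run the full filter cascade
#'
#' Convenience pipeline mirroring the reference workflow: quality filters,
#' optional enzyme/mode segmentation (applied before merging, as in the
#' segmented branch of the reference protocol), replicate merging and CV
#' filtering. Returns the final peptides and the concatenated per-stage
#' report.
#'
#' @inheritParams apply_quality_filters
#' @inheritParams merge_replicates
#' @inheritParams segment_dataset
#' @return List with `peptides` and `report`.
#' @export
filter_cascade <- function(records, pep_max = 0.01, cv_max = 0.3,
                           enzyme = "any", mode = "any",
                           require_replicates = TRUE) {
  q <- apply_quality_filters(records, pep_max = pep_max)
  recs <- q$records
  report <- q$report
  if (!identical(enzyme, "any") || !identical(mode, "any")) {
    n0 <- nrow(recs)
    if (!identical(mode, "any")) {
      recs <- segment_dataset(recs, enzyme = "any", mode = mode)
      report <- rbind(report, new_filter_report("enzyme_mode", n0,
                                                n0 - nrow(recs)))
      n0 <- nrow(recs)
    }
    if (!identical(enzyme, "any")) {
      recs <- segment_dataset(recs, enzyme = enzyme, mode = "any")
      report <- rbind(report, new_filter_report("enzyme", n0,
                                                n0 - nrow(recs)))
    }
  }
  m <- merge_replicates(recs, cv_max = cv_max,
                        require_replicates = require_replicates)
  list(peptides = m$peptides, report = rbind(report, m$report))
}

#' Write a filter report as JSON
#'
#' @param report Per-stage report tibble.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
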