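#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

#' Default MaxQuant column map
#'
#' Column-name dialects vary across MaxQuant versions; readers accept a
#' configurable map with these defaults.
#'
#' @return Named character vector mapping internal field names to MaxQuant
#'   header names.
#' @export
mq_default_columns <- function() {
  c(sequence = "Sequence", intensity = "Intensity", pep = "PEP",
    reverse = "Reverse", contaminant = "Potential contaminant")
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

#' Read a MaxQuant peptides.txt table
#'
#' Parses the peptide-level output of a MaxQuant search into one row per
#' identified peptide: sequence, summed MS1 intensity, posterior error
#' probability (PEP), and the reverse / potential-contaminant flags. Any
#' non-empty value in a flag column counts as flagged (MaxQuant writes
#' `"+"`). A missing or empty intensity is parsed as 0 (MaxQuant leaves
#' unquantified peptides blank); such rows are removed later by the
#' zero-intensity filter. Sequences containing letters outside the 20
#' standard one-letter codes (B, J, O, U, X, Z) are rejected at ingest and
#' counted.
#'
#' @param path Path to a tab-separated peptides.txt.
#' @param pool_id Pool identifier attached to every row (defaults to the file
#'   name without extension).
#' @param columns Column map, see [mq_default_columns()].
#' @return A tibble with columns `sequence`, `intensity`, `pep`, `reverse`,
#'   `contaminant`, `pool_id`; attribute `n_rejected_nonstandard` carries the
#'   number of rows dropped for non-standard residues.
#' @export
read_peptides_table <- function(path, pool_id = NULL,
                                columns = mq_default_columns()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(pool_id)) pool_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- read_tsv_quiet(path)
  required <- columns[c("sequence", "intensity", "pep")]
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("peptides table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))

  parse_num <- function(x, what, zero_if_empty = FALSE) {
    x <- trimws(x)
    if (zero_if_empty) x[x == "" | is.na(x)] <- "0"
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & x != "")
    if (length(bad))
      stop("unparseable ", what, " value in ", path, " at data row ",
           bad[1], ": '", x[bad[1]], "'")
    out
  }
  flag_col <- function(name) {
    cn <- columns[[name]]
    if (!is.null(cn) && cn %in% names(raw)) {
      v <- raw[[cn]]
      !is.na(v) & trimws(v) != ""
    } else rep(FALSE, nrow(raw))
  }

  out <- tibble(
    sequence = toupper(trimws(raw[[columns[["sequence"]]]])),
    intensity = parse_num(raw[[columns[["intensity"]]]], "intensity",
                          zero_if_empty = TRUE),
    pep = parse_num(raw[[columns[["pep"]]]], "PEP"),
    reverse = flag_col("reverse"),
    contaminant = flag_col("contaminant"),
    pool_id = pool_id)

  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", out$sequence)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message("read_peptides_table: rejected ", n_rejected,
            " sequence(s) with non-standard residues in ", basename(path))
    out <- out[ok, , drop = FALSE]
  }
  if (any(out$pep < 0 | out$pep > 1))
    stop("PEP values outside [0, 1] in ", path)
  attr(out, "n_rejected_nonstandard") <- n_rejected
  out
}

norm_enzyme <- function(x) {
  x <- trimws(x)
  known <- c(trypsin = "Trypsin", "trypsin/p" = "Trypsin", lysn = "LysN",
             aspn = "AspN")
  out <- unname(known[tolower(x)])
  ifelse(is.na(out), "other", out)
}

norm_mode <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("other", length(x))
  out[grepl("^specific", x)] <- "specific"
  out[grepl("semi", x)] <- "semi-specific"
  out[grepl("unspecific|^none$", x)] <- "unspecific"
  out
}

#' Read enzyme settings from a MaxQuant summary.txt
#'
#' Extracts the declared protease and digestion mode for one pool. The
#' summary table has one row per raw file plus a "Total" row; enzyme values
#' must agree across the file rows.
#'
#' @param path Path to a tab-separated summary.txt with `Enzyme` and
#'   `Enzyme mode` columns.
#' @param pool_id Pool identifier (defaults to the file name).
#' @return A list of class `"pool_metadata"` with `pool_id`, `enzyme`
#'   (Trypsin / LysN / AspN / other) and `enzyme_mode` (specific /
#'   semi-specific / unspecific / other).
#' @export
read_summary <- function(path, pool_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(pool_id)) pool_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- read_tsv_quiet(path)
  need <- c("Enzyme", "Enzyme mode")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("summary ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  enz <- unique(trimws(raw$Enzyme[trimws(raw$Enzyme) != ""]))
  mode <- unique(trimws(raw$`Enzyme mode`[trimws(raw$`Enzyme mode`) != ""]))
  if (length(enz) == 0 || length(mode) == 0)
    stop("summary ", path, " declares no enzyme/enzyme mode")
  if (length(enz) > 1)
    stop("summary ", path, " declares multiple enzymes: ",
         paste(enz, collapse = ", "))
  if (length(mode) > 1)
    stop("summary ", path, " declares multiple enzyme modes: ",
         paste(mode, collapse = ", "))
  structure(list(pool_id = pool_id, enzyme = norm_enzyme(enz),
                 enzyme_mode = norm_mode(mode)),
            class = "pool_metadata")
}

#' Read an SDRF-Proteomics metadata table
#'
#' Returns one annotation record per data-file row, keyed by the data-file
#' name (column `comment[data file]`, falling back to the first column).
#' All columns are preserved as opaque annotations.
#'
#' @param path Path to a tab-separated SDRF file.
#' @return Named list of single-row annotation lists.
#' @export
read_sdrf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_tsv_quiet(path)
  if (nrow(raw) == 0) return(structure(list(), names = character()))
  keycol <- grep("^comment\\[data file\\]$", names(raw), ignore.case = TRUE,
                 value = TRUE)
  keycol <- if (length(keycol)) keycol[1] else names(raw)[1]
  keys <- raw[[keycol]]
  out <- list()
  for (i in seq_len(nrow(raw))) {
    k <- keys[i]
    rec <- as.list(raw[i, , drop = FALSE])
    if (k %in% names(out)) {
      if (!identical(out[[k]], rec))
        stop("SDRF ", path, " has conflicting duplicate entries for '",
             k, "'")
    } else out[[k]] <- rec
  }
  out
}

#' Attach pool metadata to peptide rows
#'
#' Joins the enzyme and enzyme-mode settings of a pool onto its peptide
#' rows, producing per-pool unified records.
#'
#' @param rows Tibble from [read_peptides_table()]; all rows must carry the
#'   pool in `meta$pool_id`.
#' @param meta A `"pool_metadata"` from [read_summary()].
#' @return The input tibble with `enzyme` and `enzyme_mode` columns added;
#'   row count unchanged.
#' @export
assemble_records <- function(rows, meta) {
  stopifnot(inherits(meta, "pool_metadata"))
  if (nrow(rows) == 0)
    return(tibble(rows, enzyme = character(0), enzyme_mode = character(0)))
  foreign <- unique(rows$pool_id[rows$pool_id != meta$pool_id])
  if (length(foreign))
    stop("rows carry pool_id(s) not matching metadata pool '",
         meta$pool_id, "': ", paste(foreign, collapse = ", "))
  rows$enzyme <- meta$enzyme
  rows$enzyme_mode <- meta$enzyme_mode
  rows
}

unified_cols <- c("sequence", "intensity", "pep", "reverse", "contaminant",
                  "pool_id", "enzyme", "enzyme_mode")

#' Write / read the unified per-pool CSV
#'
#' The unified CSV is the exchange format between ingestion and filtering:
#' columns `sequence`, `intensity`, `pep`, `reverse`, `contaminant`,
#' `pool_id`, `enzyme`, `enzyme_mode`. Writing then re-reading yields
#' identical field values.
#'
#' @param records Assembled records ([assemble_records()]).
#' @param path Output CSV path.
#' @export
write_unified_csv <- function(records, path) {
  stopifnot(all(unified_cols %in% names(records)))
  readr::write_csv(records[, unified_cols], path)
  invisible(path)
}

#' @rdname write_unified_csv
#' @export
read_unified_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readr::read_csv(path, col_types = readr::cols(
    sequence = readr::col_character(), intensity = readr::col_double(),
    pep = readr::col_double(), reverse = readr::col_logical(),
    contaminant = readr::col_logical(), pool_id = readr::col_character(),
    enzyme = readr::col_character(), enzyme_mode = readr::col_character()),
    progress = FALSE)
}
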