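# Fixture builders: all test inputs are constructed in code at test time.

write_peptides_fixture <- function(rows, path = tempfile(fileext = ".txt"),
                                   columns = c("Sequence", "Intensity", "PEP",
                                               "Reverse",
                                               "Potential contaminant")) {
  header <- paste(columns, collapse = "\t")
  lines <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
  writeLines(c(header, lines), path)
  path
}

write_summary_fixture <- function(enzyme = "Trypsin", mode = "Specific",
                                  path = tempfile(fileext = ".txt")) {
  writeLines(c("Raw file\tEnzyme\tEnzyme mode",
               paste("pool01.raw", enzyme, mode, sep = "\t"),
               paste("Total", enzyme, mode, sep = "\t")),
             path)
  path
}

write_sdrf_fixture <- function(files, path = tempfile(fileext = ".tsv"),
                               organisms = rep("synthetic", length(files))) {
  body <- if (length(files)) paste0("sample ", seq_along(files), "\t",
                                    organisms, "\t", files) else character(0)
  writeLines(c("source name\tcharacteristics[organism]\tcomment[data file]",
               body), path)
  path
}

# A random measurement table for property-style filter tests.
random_measurements <- function(n, seed) {
  set.seed(seed)
  seqs <- replicate(max(2, n %/% 3), paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], sample(6:12, 1),
           replace = TRUE), collapse = ""))
  tibble::tibble(
    sequence = sample(seqs, n, replace = TRUE),
    intensity = ifelse(stats::runif(n) < 0.1, 0,
                       stats::rlnorm(n, meanlog = 20, sdlog = 1)),
    pep = stats::runif(n, 0, 0.05),
    reverse = stats::runif(n) < 0.05,
    contaminant = stats::runif(n) < 0.05,
    pool_id = sample(paste0("pool", 1:6), n, replace = TRUE),
    enzyme = sample(c("Trypsin", "LysN", "AspN"), n, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2)),
    enzyme_mode = sample(c("specific", "semi-specific", "unspecific"), n,
                         replace = TRUE, prob = c(0.6, 0.2, 0.2)))
}

# Minimal trained-size model for contract tests (tiny but real).
tiny_model <- function(alphabet = make_alphabet(c("A", "C", "D"), pad = "-"),
                       units = 3L, max_len = 5L, seed = 42L) {
  attn_init(alphabet, attn_config(units = units, max_len = max_len,
                                  batch_size = 4L, epochs = 2L, seed = seed))
}

# AAindex1-format fixture with a handful of records built from given values.
write_aaindex_fixture <- function(indices, path = tempfile(fileext = ".txt")) {
  row1 <- strsplit("A R N D C Q E G H I", " ")[[1]]
  row2 <- strsplit("L K M F P S T W Y V", " ")[[1]]
  fmt <- function(v) paste(ifelse(is.na(v), "NA", format(v)), collapse = "  ")
  lines <- unlist(lapply(indices, function(ix) c(
    paste0("H ", ix$accession),
    paste0("D ", ix$description),
    "R PMID:0000000",
    "A Author, A.",
    "T A synthetic test record",
    "J Nowhere (2026)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    paste0("     ", fmt(ix$values[row1])),
    paste0("     ", fmt(ix$values[row2])),
    "//")))
  writeLines(lines, path)
  path
}

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
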