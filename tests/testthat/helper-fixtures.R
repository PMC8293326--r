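# Fixtures are built in code at test time; nothing binary is stored.

AA20 <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Independent cleavage oracle: scan every position, cut C-terminal of K/R
# unless followed by P, count fragments with length in range.
oracle_digest <- function(sequence, min_len = 7L, max_len = 30L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  count <- 0L
  start <- 1L
  for (i in seq_len(n)) {
    cut <- chars[i] %in% c("K", "R") && (i == n || chars[i + 1L] != "P")
    if (cut || i == n) {
      len <- i - start + 1L
      if (len >= min_len && len <= max_len) count <- count + 1L
      start <- i + 1L
    }
  }
  count
}

write_maxquant_fixture <- function(path, ids,
                                   reverse = rep("", length(ids)),
                                   contaminant = rep("", length(ids)),
                                   site_only = rep("", length(ids))) {
  tab <- data.frame(
    `Majority protein IDs` = ids,
    `Peptides` = seq_along(ids),
    `Reverse` = reverse,
    `Potential contaminant` = contaminant,
    `Only identified by site` = site_only,
    check.names = FALSE
  )
  readr::write_tsv(tab, path, progress = FALSE)
  path
}

write_pd_fixture <- function(path, accessions, master = NULL) {
  tab <- data.frame(
    Accession = accessions,
    `Description` = paste("protein", seq_along(accessions)),
    check.names = FALSE
  )
  if (!is.null(master)) tab$Master <- master
  readr::write_tsv(tab, path, progress = FALSE)
  path
}

write_fasta_fixture <- function(path, accessions, sequences) {
  lines <- as.vector(rbind(
    sprintf(">sp|%s|%s_HUMAN test protein", accessions, accessions),
    sequences
  ))
  writeLines(lines, path)
  path
}

tiny_reference <- function(n = 20L, seed = 42L) {
  withr::with_seed(seed, {
    reference_table(
      data.frame(
        accession = sprintf("REF%03d", seq_len(n)),
        copies_per_cell = 10^runif(n, 2, 8)
      ),
      name = "tiny"
    )
  })
}
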