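#' Write reads to a FASTQ file
#'
#' Sanger FASTQ (Phred+33).  The pipeline's consensus rules never consult
#' base qualities, so all bases are written with a constant quality symbol
#' (Q30 by default).  A `.gz` extension triggers gzip compression.
#'
#' @param reads Tibble with columns `read_id` and `sequence`.
#' @param path Output path.
#' @param quality Phred quality assigned to every base (default 30).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = 30L) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qchar <- rawToChar(as.raw(33L + as.integer(quality)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep(qchar, nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Tibble with columns `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' Write a TSV report with a metadata header
#'
#' Tab-separated, UTF-8, with `#`-prefixed `key=value` header lines carrying
#' at least the tool version; [run_cohort()] adds the seed and a config
#' hash so every output file records how it was produced.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Named list of metadata written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path, meta = list()) {
  meta <- c(list(tool = paste0("umimrd ", utils::packageVersion("umimrd"))), meta)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), vapply(meta, format, "")), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by [write_tsv_report()]
#'
#' @param path Input path.
#' @return A tibble (metadata lines are skipped).
#' @export
read_tsv_report <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#", sep = "\t",
                                      stringsAsFactors = FALSE))
}
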