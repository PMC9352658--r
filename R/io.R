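# FASTQ and table I/O. Sequence files go through Biostrings and are
# gzip-transparent.

#' Read sequences from a FASTQ file
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return Named character vector of read sequences (qualities discarded).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: %s", path), call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTQ file
#'
#' Qualities are not modeled; a constant quality character is written.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  ids <- names(seqs) %||% sprintf("read%d", seq_along(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_csv_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
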