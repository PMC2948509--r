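#' Read a FASTA file
#'
#' Reads nucleotide FASTA via Biostrings, uppercases the residues and
#' normalizes U to T. The first whitespace-separated token of each header is
#' the record id; the remainder (if any) is kept as the description.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a data.frame with columns `id`, `seq` and `desc`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- chartr("U", "T", toupper(as.character(x)))
  data.frame(id = ids, seq = unname(seqs), desc = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids character vector of record ids.
#' @param seqs character vector of sequences (same length as `ids`).
#' @param path output path.
#' @param desc optional character vector of descriptions appended to headers.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, desc = NULL) {
  headers <- ids
  if (!is.null(desc)) {
    headers <- ifelse(nzchar(desc), paste(ids, desc), ids)
  }
  x <- Biostrings::BStringSet(setNames(as.character(seqs), headers))
  tryCatch(
    Biostrings::writeXStringSet(x, filepath = path, width = 70L),
    error = function(e) stop("failed to write FASTA '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA, check.names = FALSE)
}

write_tsv <- function(df, path) {
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("failed to write TSV '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}
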