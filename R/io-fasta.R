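#' Read a genome FASTA
#'
#' Sequences are uppercased and record names truncated at the first
#' whitespace. Duplicate names and empty sequences are rejected.
#'
#' @param path FASTA path.
#' @return a `DNAStringSet`, one element per chromosome.
#' @export
read_fasta <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop_validation("duplicate FASTA record names: %s",
                    paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(lengths(seqs) == 0L))
    stop_validation("empty FASTA record: %s",
                    paste(names(seqs)[lengths(seqs) == 0L], collapse = ", "))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write a genome FASTA
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
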