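# Sequence containers and FASTA / TSV I/O.
#
# Sequences are plain named character vectors over {A,C,G,T,N}; heavier
# containers (DNAStringSet) are used internally where counting speed matters.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

check_dna <- function(seqs, allow_n = TRUE) {
  if (!is.character(seqs) || length(seqs) == 0)
    stop("sequences must be a non-empty character vector", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ",
         paste(utils::head(which(bad), 3L), collapse = ", "), call. = FALSE)
  invisible(seqs)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  check_dna(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# plain TSV helpers used across modules
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
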