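# genome representation: named character vector of uppercase sequences,
# integer base codes A=0, C=1, G=2, T=3 (anything else NA) for fast kernels

.base_code_table <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("a")] <- 0L
  v[utf8ToInt("C")] <- 1L; v[utf8ToInt("c")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("g")] <- 2L
  v[utf8ToInt("T")] <- 3L; v[utf8ToInt("t")] <- 3L
  v
})

.code_base <- c("A", "C", "G", "T")

encode_bases <- function(seq) {
  .base_code_table[utf8ToInt(seq)]
}

decode_bases <- function(codes) {
  out <- .code_base[codes + 1L]
  out[is.na(codes)] <- "N"
  intToUtf8(utf8ToInt(paste(out, collapse = ""))) # no-op; keep as string
}

codes_to_string <- function(codes) {
  chars <- ifelse(is.na(codes), "N", .code_base[codes + 1L])
  paste(chars, collapse = "")
}

#' Coerce to a genome object
#'
#' A genome is represented as a named character vector of uppercase DNA
#' sequences, one element per chromosome. Accepts a named character vector or
#' a [Biostrings::DNAStringSet].
#'
#' @param x Named character vector or `DNAStringSet`.
#' @return Named character vector of uppercase sequences.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("genome must be a named character vector or DNAStringSet")
  }
  if (any(nchar(x) == 0)) abort("zero-length chromosome in genome")
  toupper(x)
}

#' Chromosome lengths of a genome
#' @param genome Genome (see [as_genome()]).
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  genome <- as_genome(genome)
  setNames(nchar(genome), names(genome))
}

#' Reverse complement of DNA strings
#'
#' Vectorized; `N` maps to `N`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a genome from FASTA
#' @param path FASTA file path.
#' @return Named character vector (names truncated at first whitespace).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  as_genome(ss)
}

#' Write a genome to FASTA (60-column wrapped)
#' @param genome Genome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
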