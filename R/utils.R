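#' @keywords internal
"_PACKAGE"

# Base alphabet used throughout; N is tolerated but excluded from statistics.
MITO_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Handles the `{A,C,G,T,N}` alphabet (case-insensitive input, uppercase
#' output). Used to present light-strand features 5'->3' on their coding
#' sense.
#'
#' @param x nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(toupper(x), "")[[1]]

# Count A/C/G/T/N (and anything else as "other") in a sequence string.
base_counts <- function(seq) {
  ch <- seq_chars(seq)
  c(
    A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"),
    N = sum(ch == "N"),
    other = sum(!ch %in% c("A", "C", "G", "T", "N"))
  )
}

# FNV-1a 32-bit hash of a string; used to stamp report headers with a
# config fingerprint without pulling in a digest dependency. Arithmetic is
# done in doubles with a split multiply so every intermediate stays exact.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h_lo <- h %% 65536
    h_hi <- h %/% 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic per-replicate seed stream: a pure function of (seed, r),
# always below 2^31 so it is a valid R integer seed.
replicate_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + as.numeric(r) * 1000003) %% 2147483647)
}

#' Read a single-record genome FASTA
#'
#' Reads one sequence, uppercases it and normalizes U to T. More than one
#' record is an error: a mitogenome assembly is a single circle.
#'
#' @param path FASTA file path.
#' @return named character scalar (name = FASTA header word).
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set))
  }
  s <- chartr("Uu", "Tt", as.character(set[[1]]))
  stats::setNames(toupper(s), names(set))
}

#' Write a genome FASTA
#'
#' @param seq nucleotide string.
#' @param name record name.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seq, name, path, width = 70L) {
  set <- Biostrings::BStringSet(stats::setNames(seq, name))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
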