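#' Count tandem copies of a motif in a region
#'
#' Finds the maximal run of consecutive, non-overlapping motif-length
#' windows, each within `max_mismatch_per_copy` Hamming distance of the
#' motif, and reports the longest such run (ties broken by the leftmost
#' start). Runs are measured in whole motif-length units: a trailing
#' partial copy does not count. The default is exact matching; the
#' mismatch knob accommodates degenerate repeat consensi.
#'
#' @param region nucleotide string (e.g. an extracted control region;
#'   coordinates in the result are 1-based local positions).
#' @param motif nucleotide string, `1 <= nchar(motif) <= nchar(region)`.
#' @param max_mismatch_per_copy allowed mismatches per copy (default 0).
#' @return list of class `repeat_report`: `motif`, `copy_number`,
#'   `run_start` (NA when `copy_number` is 0), `mismatch_per_copy`
#'   (integer vector along the reported run).
#' @export
count_tandem_copies <- function(region, motif, max_mismatch_per_copy = 0L) {
  stopifnot(is.character(region), length(region) == 1L,
            is.character(motif), length(motif) == 1L)
  region <- toupper(region); motif <- toupper(motif)
  m <- nchar(motif); n <- nchar(region)
  if (m < 1L) stop("empty motif")
  if (m > n) stop("motif longer than region")
  rch <- seq_chars(region)
  mch <- seq_chars(motif)
  n_win <- n - m + 1L
  # mismatch count of the window starting at each position
  mm <- integer(n_win)
  for (k in seq_len(m)) {
    mm <- mm + (rch[seq_len(n_win) + (k - 1L)] != mch[k])
  }
  ok <- mm <= max_mismatch_per_copy
  # runlen[i]: copies in the chain starting at i stepping by m
  runlen <- integer(n_win)
  for (i in n_win:1) {
    if (ok[i]) {
      nxt <- i + m
      runlen[i] <- 1L + if (nxt <= n_win) runlen[nxt] else 0L
    }
  }
  if (!any(ok)) {
    return(structure(list(motif = motif, copy_number = 0L,
                          run_start = NA_integer_,
                          mismatch_per_copy = integer(0)),
                     class = "repeat_report"))
  }
  best <- which.max(runlen) # leftmost maximal run
  starts <- best + m * (seq_len(runlen[best]) - 1L)
  structure(list(
    motif = motif,
    copy_number = runlen[best],
    run_start = as.integer(best),
    mismatch_per_copy = mm[starts]
  ), class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat("<repeat_report> motif ", x$motif, ": ", x$copy_number,
      " tandem copies",
      if (x$copy_number > 0) paste0(" from position ", x$run_start),
      "\n", sep = "")
  invisible(x)
}

#' All (possibly overlapping) exact occurrences of a motif
#'
#' @param region nucleotide string.
#' @param motif nucleotide string.
#' @return list: `positions` (1-based start positions, overlapping
#'   occurrences included) and `duplication` (TRUE when the motif occurs
#'   at least twice, the usual definition of a sequence duplication).
#' @export
find_motif_occurrences <- function(region, motif) {
  stopifnot(is.character(region), length(region) == 1L,
            is.character(motif), length(motif) == 1L)
  region <- toupper(region); motif <- toupper(motif)
  m <- nchar(motif); n <- nchar(region)
  if (m < 1L) stop("empty motif")
  if (m > n) return(list(positions = integer(0), duplication = FALSE))
  rch <- seq_chars(region)
  mch <- seq_chars(motif)
  hit <- rep(TRUE, n - m + 1L)
  for (k in seq_len(m)) {
    hit <- hit & (rch[seq_len(n - m + 1L) + (k - 1L)] == mch[k])
  }
  pos <- which(hit)
  list(positions = as.integer(pos), duplication = length(pos) >= 2L)
}

#' Map a local region position to a genome coordinate
#'
#' Local 1-based positions inside a (possibly wrapping) feature are mapped
#' through the feature onto the circle, so repeat coordinates reported in
#' control-region space can be expressed genome-wide.
#'
#' @param local 1-based position(s) within the feature.
#' @param f feature row (`start`, `stop`, `wraps` fields).
#' @param genome_length circle length L.
#' @return genome position(s), 1-based.
#' @export
local_to_genome <- function(local, f, genome_length) {
  pos <- feature_positions(as.integer(f$start), as.integer(f$stop),
                           isTRUE(f$wraps), as.integer(genome_length))
  local <- as.integer(local)
  if (any(local < 1L | local > length(pos))) stop("local position out of feature")
  pos[local]
}
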