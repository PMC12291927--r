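#' Alignment matrix constructor
#'
#' Holds a multiple sequence alignment as a character matrix (rows =
#' samples, columns = alignment sites) over `{A,C,G,T,N,-}`. Gap (`-`) and
#' `N` are treated as missing data, not as alleles, by every downstream
#' census.
#'
#' @param seqs named character vector of aligned sequences, all the same
#'   length, or a character matrix of single characters with rownames.
#' @return a character matrix of class `alignment_matrix`.
#' @export
alignment_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    w <- unique(nchar(seqs))
    if (length(w) != 1L) stop("aligned sequences must all have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named")
  if (anyDuplicated(rownames(m))) stop("duplicate sample names")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop("unexpected alignment characters: ",
                        paste(bad, collapse = " "))
  class(m) <- c("alignment_matrix", class(m))
  m
}

#' Read an aligned FASTA file
#'
#' Strict equal-length check; `U` is normalized to `T` and everything is
#' uppercased.
#'
#' @param path FASTA path.
#' @return an [alignment_matrix()].
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(seq_along(set), function(i)
    chartr("Uu", "Tt", as.character(set[[i]])), character(1))
  names(seqs) <- sub("\\s.*$", "", names(set))
  alignment_matrix(seqs)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an [alignment_matrix()].
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path, width = 70L) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Polymorphic-site census
#'
#' Columns holding at least two distinct states among `{A,C,G,T}` across
#' the samples. Gaps and `N` are missing data: a column of `{A, -}` is not
#' polymorphic.
#'
#' @param aln an [alignment_matrix()] with >= 2 rows.
#' @return 1-based column indices of polymorphic sites.
#' @export
polymorphic_sites <- function(aln) {
  m <- unclass(aln)
  stopifnot(nrow(m) >= 2L)
  miss <- !(m %in% c("A", "C", "G", "T"))
  dim(miss) <- dim(m)
  n_states <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[!miss[, j], j]))
  }, integer(1))
  which(n_states >= 2L)
}

#' Fraction of variable alignment columns
#'
#' @param aln an [alignment_matrix()].
#' @return percentage `100 * |polymorphic sites| / alignment length`.
#' @export
variable_fraction <- function(aln) {
  100 * length(polymorphic_sites(aln)) / ncol(aln)
}

#' Hamming distance between two alignment rows
#'
#' Counts columns where the two samples carry different bases, over the
#' columns where both states are in `{A,C,G,T}`.
#'
#' @param rowA,rowB aligned sequences (strings) or character vectors of
#'   equal length.
#' @return integer count of differing columns.
#' @export
site_diff <- function(rowA, rowB) {
  a <- if (length(rowA) == 1L) seq_chars(rowA) else toupper(rowA)
  b <- if (length(rowB) == 1L) seq_chars(rowB) else toupper(rowB)
  stopifnot(length(a) == length(b))
  ok <- a %in% MITO_BASES & b %in% MITO_BASES
  sum(a[ok] != b[ok])
}

#' Amino-acid substitutions relative to a reference row
#'
#' Translates every row of an in-frame concatenated coding-sequence
#' alignment under the vertebrate mitochondrial code and reports the
#' protein positions where any sample's residue differs from the
#' reference. Codons containing gaps or `N` translate to `X` and never
#' count as substitutions. A trailing partial codon is ignored with a
#' warning.
#'
#' @param aln an [alignment_matrix()], in frame.
#' @param reference_row name of the reference sample.
#' @return data.frame with `position` (codon index), `ref` residue and
#'   `alt` (comma-joined differing residues).
#' @export
aa_substitutions <- function(aln, reference_row) {
  m <- unclass(aln)
  if (!reference_row %in% rownames(m)) stop("unknown reference row: ", reference_row)
  L <- ncol(m)
  if (L %% 3L != 0L) {
    warning("alignment length not divisible by 3; trailing ",
            L %% 3L, " column(s) ignored")
    L <- L - L %% 3L
  }
  code <- mito_code()
  translate_row <- function(ch) {
    s <- paste(ch[seq_len(L)], collapse = "")
    cod <- substring(s, 3L * seq_len(L %/% 3L) - 2L, 3L * seq_len(L %/% 3L))
    aa <- unname(code[cod])
    aa[is.na(aa)] <- "X"
    aa
  }
  prot <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    translate_row(m[i, ])))
  rownames(prot) <- rownames(m)
  ref <- prot[reference_row, ]
  others <- setdiff(rownames(m), reference_row)
  out <- list()
  for (p in seq_along(ref)) {
    alt <- unique(prot[others, p])
    alt <- alt[alt != ref[p] & alt != "X" & ref[p] != "X"]
    if (length(alt)) {
      out[[length(out) + 1L]] <- data.frame(
        position = p, ref = ref[p], alt = paste(sort(alt), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Cytochrome b haplotype scheme
#'
#' Four diagnostic alignment positions and the lineage label attached to
#' each 4-mer of bases read across them. The defaults are the classic pig
#' cytb scheme on its reference coordinate system: positions 15036, 15038,
#' 15041, 15045 with European haplotypes E1 (TGCG) and E2 (TGTG) and Asian
#' haplotypes A1 (CATA), A2 (CATG), A3 (TATG). The positions are
#' reference-relative, so the scheme is fully parameterizable for other
#' coordinate systems.
#'
#' @param positions strictly increasing alignment positions.
#' @param labels named character vector mapping 4-mers to labels.
#' @return list of class `haplotype_scheme`.
#' @export
haplotype_scheme <- function(
    positions = c(15036L, 15038L, 15041L, 15045L),
    labels = c(TGCG = "E1", TGTG = "E2", CATA = "A1", CATG = "A2",
               TATG = "A3")) {
  positions <- as.integer(positions)
  stopifnot(all(diff(positions) > 0L), !is.null(names(labels)),
            !anyDuplicated(labels), !anyDuplicated(names(labels)),
            all(nchar(names(labels)) == length(positions)))
  structure(list(positions = positions, labels = labels),
            class = "haplotype_scheme")
}

#' Classify one sequence under a haplotype scheme
#'
#' Reads the bases at the scheme positions, joins them into a key and
#' looks the key up in the label map. A key not present in the map
#' returns `"unclassified(<key>)"`; any missing base (gap, N, or a
#' position beyond the sequence) returns `"incomplete"`.
#'
#' @param row aligned sequence string or character vector.
#' @param scheme a [haplotype_scheme()].
#' @return label string.
#' @export
classify_haplotype <- function(row, scheme = haplotype_scheme()) {
  stopifnot(inherits(scheme, "haplotype_scheme"))
  ch <- if (length(row) == 1L) seq_chars(row) else toupper(row)
  if (max(scheme$positions) > length(ch)) return("incomplete")
  bases <- ch[scheme$positions]
  if (any(!bases %in% MITO_BASES)) return("incomplete")
  key <- paste(bases, collapse = "")
  if (key %in% names(scheme$labels)) unname(scheme$labels[[key]])
  else paste0("unclassified(", key, ")")
}

#' Classify every row of an alignment
#'
#' @param aln an [alignment_matrix()].
#' @param scheme a [haplotype_scheme()].
#' @return data.frame with `sample` and `haplotype`.
#' @export
classify_haplotypes <- function(aln, scheme = haplotype_scheme()) {
  m <- unclass(aln)
  data.frame(
    sample = rownames(m),
    haplotype = vapply(seq_len(nrow(m)), function(i)
      classify_haplotype(m[i, ], scheme), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Base at a single diagnostic position for every sample
#'
#' A one-position lookup with the same missing-data conventions as
#' [classify_haplotype()]; useful for single-site lineage markers.
#'
#' @param aln an [alignment_matrix()].
#' @param position 1-based alignment position.
#' @return named character vector (missing data as NA).
#' @export
site_lookup <- function(aln, position) {
  m <- unclass(aln)
  stopifnot(position >= 1L, position <= ncol(m))
  b <- m[, position]
  b[!b %in% MITO_BASES] <- NA_character_
  stats::setNames(b, rownames(m))
}
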