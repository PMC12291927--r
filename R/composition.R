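# Vertebrate mitochondrial genetic code (NCBI translation table 2):
# AGA/AGG are stops, ATA codes Met, TGA codes Trp. The table comes from
# Biostrings; the synonymous-family partition for RSCU is derived from it
# with stop codons excluded.
mito_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("2")
    code
  }
})

# Synonymous families: list mapping amino acid -> codons, stops dropped.
mito_families <- function() {
  code <- mito_code()
  fam <- split(names(code), code)
  fam[names(fam) != "*"]
}

#' Extract a feature's sequence from a circular genome
#'
#' Wrap-aware slice of the genome; light-strand features are
#' reverse-complemented so the result always reads 5'->3' on the coding
#' sense. `N` bases pass through unchanged.
#'
#' @param g a [circular_genome()] carrying a sequence.
#' @param f a single feature: one row of a `mito_features` table, or a
#'   list with `start`, `stop`, `strand`, `wraps` fields, or a feature
#'   name present in `g$features`.
#' @return nucleotide string.
#' @export
extract_region <- function(g, f) {
  stopifnot(inherits(g, "circular_genome"))
  if (is.null(g$seq)) stop("genome carries no sequence")
  if (is.character(f) && length(f) == 1L) {
    idx <- match(f, g$features$name)
    if (is.na(idx)) stop("unknown feature: ", f)
    f <- g$features[idx, ]
  }
  pos <- feature_positions(as.integer(f$start), as.integer(f$stop),
                           isTRUE(f$wraps), g$length)
  s <- paste(seq_chars(g$seq)[pos], collapse = "")
  if (identical(f$strand, "-")) s <- revcomp(s)
  s
}

#' Base composition and strand-asymmetry skews of a sequence
#'
#' Computes base counts and percentages, A+T content, and the two skew
#' statistics `AT skew = (A - T)/(A + T)` and `GC skew = (G - C)/(G + C)`.
#' `N` bases are excluded from all denominators. A skew whose denominator
#' is zero is undefined and reported as `NA` (never coerced to 0).
#'
#' @param seq nucleotide string.
#' @param region_label optional label carried into the result.
#' @return a list of class `composition_summary` with `counts`,
#'   `percent`, `at_percent`, `at_skew`, `gc_skew`, `length`,
#'   `n_fraction`, `region_label`.
#' @export
composition_summary <- function(seq, region_label = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  cnt <- base_counts(seq)
  acgt <- cnt[c("A", "C", "G", "T")]
  tot <- sum(acgt)
  if (tot == 0L) stop("sequence has no A/C/G/T bases")
  pct <- 100 * acgt / tot
  n_frac <- cnt[["N"]] / nchar(seq)
  if (n_frac > 0.10) {
    message("region ", region_label, ": ", round(100 * n_frac, 1),
            "% N bases excluded from composition")
  }
  skew <- function(x, y) if ((x + y) == 0) NA_real_ else (x - y) / (x + y)
  structure(list(
    counts = acgt,
    percent = pct,
    at_percent = unname(pct[["A"]] + pct[["T"]]),
    at_skew = skew(acgt[["A"]], acgt[["T"]]),
    gc_skew = skew(acgt[["G"]], acgt[["C"]]),
    length = nchar(seq),
    n_fraction = n_frac,
    region_label = region_label
  ), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("<composition_summary>",
      if (!is.na(x$region_label)) paste0(" ", x$region_label), " ",
      x$length, " bp  A+T ", sprintf("%.1f%%", x$at_percent),
      "  AT skew ", if (is.na(x$at_skew)) "undefined" else sprintf("%.6f", x$at_skew),
      "  GC skew ", if (is.na(x$gc_skew)) "undefined" else sprintf("%.6f", x$gc_skew),
      "\n", sep = "")
  invisible(x)
}

#' Translate a mitochondrial coding sequence
#'
#' Translation under the vertebrate mitochondrial genetic code, with
#' classification of the start codon and of the termination state.
#' Mitochondrial PCGs are frequently annotated with incomplete stop codons
#' completed by mRNA polyadenylation: a CDS whose length mod 3 is 1 and
#' ends in `T` is classified `incomplete_T`, one whose length mod 3 is 2
#' and ends in `TA` is `incomplete_TA`; a final full codon in
#' `{TAA, TAG, AGA, AGG}` is `complete`; anything else is `none`.
#' The terminal stop codon (when complete) is not included in the protein.
#' Codons containing a non-ACGT base translate to `X`.
#'
#' @param cds nucleotide string, length >= 6, 5'->3' coding sense.
#' @return list of class `mito_translation`: `protein`, `start_codon`,
#'   `stop_status`, `internal_stop` (TRUE when a stop codon occurs before
#'   the terminal position; flagged, not fatal).
#' @export
translate_mito <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6L) stop("CDS shorter than 6 bases")
  code <- mito_code()
  n_cod <- n %/% 3L
  rem <- n %% 3L
  codons <- substring(cds, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  start_codon <- codons[1]
  last_codon <- codons[n_cod]
  tail1 <- substring(cds, n, n)
  tail2 <- substring(cds, n - 1L, n)
  stop_status <-
    if (rem == 1L && tail1 == "T") "incomplete_T"
    else if (rem == 2L && tail2 == "TA") "incomplete_TA"
    else if (rem == 0L && identical(unname(code[last_codon]), "*")) "complete"
    else "none"
  if (stop_status == "complete") aa <- aa[-n_cod]
  structure(list(
    protein = paste(aa, collapse = ""),
    start_codon = start_codon,
    stop_status = stop_status,
    internal_stop = any(aa == "*")
  ), class = "mito_translation")
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) * k / sum(counts over c's synonymous family)` where
#' `k` is the family size under the vertebrate mitochondrial code's
#' amino-acid partition (stop codons excluded). A family with zero total
#' count gets RSCU 0 for all members, so the family-sum identity
#' `sum(RSCU) = k` holds exactly whenever the family was observed at all.
#'
#' @param codon_counts named numeric vector of codon counts (names are
#'   DNA codons such as "ATG"); codons absent from the vector count 0.
#' @return named numeric vector of RSCU values over the 60 non-stop
#'   codons, with an `aa` attribute giving each codon's amino acid.
#' @export
rscu <- function(codon_counts) {
  stopifnot(!is.null(names(codon_counts)))
  fam <- mito_families()
  codons <- unlist(fam, use.names = FALSE)
  counts <- stats::setNames(numeric(length(codons)), codons)
  known <- intersect(names(codon_counts), codons)
  counts[known] <- codon_counts[known]
  out <- stats::setNames(numeric(length(codons)), codons)
  aa_of <- stats::setNames(rep(names(fam), lengths(fam)), codons)
  for (a in names(fam)) {
    cs <- fam[[a]]
    tot <- sum(counts[cs])
    out[cs] <- if (tot > 0) counts[cs] * length(cs) / tot else 0
  }
  attr(out, "aa") <- aa_of
  out
}

#' Pooled amino-acid distribution of a set of proteins
#'
#' Percentage of each residue over all supplied protein strings; stop
#' (`*`) and unknown (`X`) symbols are excluded from the denominator.
#'
#' @param proteins character vector of protein strings (one per PCG).
#' @return named numeric vector of percentages over the residues observed,
#'   summing to 100.
#' @export
amino_acid_distribution <- function(proteins) {
  stopifnot(is.character(proteins), length(proteins) >= 1L)
  ch <- unlist(strsplit(paste(proteins, collapse = ""), ""))
  ch <- ch[!ch %in% c("*", "X")]
  if (!length(ch)) stop("no residues after excluding stop/unknown symbols")
  tab <- 100 * table(ch) / length(ch)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Codon-usage profile of a genome's protein-coding genes
#'
#' Extracts every PCG 5'->3', classifies its start codon and stop status,
#' pools complete-codon counts (the terminal stop codon and any trailing
#' partial codon are excluded), and computes RSCU and the pooled
#' amino-acid distribution.
#'
#' @param g a [circular_genome()] with sequence and features.
#' @return list of class `codon_profile`: `genes` (data.frame with name,
#'   start_codon, stop_status, internal_stop, length), `codon_counts`,
#'   `rscu`, `aa_percent`, `proteins` (named list).
#' @export
codon_profile <- function(g) {
  stopifnot(inherits(g, "circular_genome"), !is.null(g$seq),
            !is.null(g$features))
  pcg <- g$features[g$features$gene_class == "PCG", , drop = FALSE]
  if (!nrow(pcg)) stop("no PCG features")
  counts <- stats::setNames(numeric(64),
                            names(mito_code()))
  genes <- vector("list", nrow(pcg))
  proteins <- stats::setNames(vector("list", nrow(pcg)), pcg$name)
  for (i in seq_len(nrow(pcg))) {
    cds <- extract_region(g, pcg[i, ])
    tr <- translate_mito(cds)
    n_cod <- nchar(cds) %/% 3L
    cod <- substring(cds, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    if (tr$stop_status == "complete") cod <- cod[-length(cod)]
    cod <- cod[!grepl("[^ACGT]", cod)]
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    genes[[i]] <- data.frame(
      name = pcg$name[i], start_codon = tr$start_codon,
      stop_status = tr$stop_status, internal_stop = tr$internal_stop,
      length = pcg$length[i], stringsAsFactors = FALSE
    )
    proteins[[i]] <- tr$protein
  }
  structure(list(
    genes = do.call(rbind, genes),
    codon_counts = counts,
    rscu = rscu(counts),
    aa_percent = amino_acid_distribution(gsub("\\*", "", unlist(proteins))),
    proteins = proteins
  ), class = "codon_profile")
}

#' Per-region composition table for a genome
#'
#' Builds the composition/skew table usually printed for mitogenome
#' reports: the whole circle, the concatenated protein-coding genes
#' (coding sense, in start order), each rRNA, and the control region when
#' present, plus one row per PCG. Percentages are reported to full
#' precision; round at presentation time.
#'
#' @param g a [circular_genome()] with sequence and features.
#' @param per_gene also include one row per PCG feature.
#' @return data.frame with region, length, percentages, at_percent and
#'   both skews.
#' @export
composition_table <- function(g, per_gene = TRUE) {
  stopifnot(inherits(g, "circular_genome"), !is.null(g$seq),
            !is.null(g$features))
  f <- g$features
  rows <- list()
  add <- function(label, seq) {
    cs <- composition_summary(seq, label)
    rows[[length(rows) + 1L]] <<- data.frame(
      region = label, length = cs$length,
      A = cs$percent[["A"]], C = cs$percent[["C"]],
      G = cs$percent[["G"]], T = cs$percent[["T"]],
      at_percent = cs$at_percent,
      at_skew = cs$at_skew, gc_skew = cs$gc_skew,
      stringsAsFactors = FALSE
    )
  }
  add("whole", g$seq)
  pcg <- f[f$gene_class == "PCG", , drop = FALSE]
  if (nrow(pcg)) {
    add("PCG_concat", paste(vapply(seq_len(nrow(pcg)), function(i)
      extract_region(g, pcg[i, ]), character(1)), collapse = ""))
  }
  for (nm in f$name[f$gene_class == "rRNA"]) add(nm, extract_region(g, nm))
  if (any(f$gene_class == "control")) {
    add("control", extract_region(g, f[f$gene_class == "control", ][1, ]))
  }
  if (per_gene) for (nm in pcg$name) add(nm, extract_region(g, nm))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
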