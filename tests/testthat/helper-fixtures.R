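# Shared fixtures and independent brute-force oracles. Everything is
# built in code at test time; nothing is downloaded.

.synth_cache <- new.env(parent = emptyenv())

# Memoized synthetic genome (generation costs a few seconds).
get_synth <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.synth_cache[[key]])) {
    .synth_cache[[key]] <- generate_genome(synth_spec(seed = seed))
  }
  .synth_cache[[key]]
}

skeleton_genome <- function() {
  circular_genome(length = 16581L, features = mito_gene_skeleton())
}

# Brute-force PCG union oracle: materialize every covered position.
pcg_union_bruteforce <- function(g) {
  f <- g$features[g$features$gene_class == "PCG", , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(f)), function(i) {
    if (f$wraps[i]) c(f$start[i]:g$length, 1:f$stop[i])
    else f$start[i]:f$stop[i]
  }))
  length(unique(pos))
}

# Brute-force tandem-run oracle: try every start, walk forward in whole
# motif-length steps while each window is within the mismatch budget.
tandem_bruteforce <- function(region, motif, max_mm = 0L) {
  m <- nchar(motif)
  n <- nchar(region)
  mch <- strsplit(motif, "")[[1]]
  rch <- strsplit(region, "")[[1]]
  best <- 0L; best_start <- NA_integer_
  for (s in seq_len(n - m + 1L)) {
    k <- 0L; p <- s
    while (p + m - 1L <= n &&
           sum(rch[p:(p + m - 1L)] != mch) <= max_mm) {
      k <- k + 1L; p <- p + m
    }
    if (k > best) { best <- k; best_start <- s }
  }
  list(copy_number = best, run_start = best_start)
}

# Random nucleotide string.
rand_seq <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# An 8-taxon two-clade tree mimicking a deep Asian/European split.
two_clade_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A1:0.03,A2:0.03):0.03,(A3:0.03,A4:0.03):0.03):0.1,",
    "((E1:0.03,E2:0.03):0.03,(E3:0.03,E4:0.03):0.03):0.1);"))
}
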