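# Pig-like pooled amino-acid usage (percent) used to fill PCG interiors:
# Leu most frequent, Cys rarest, matching the usage profile reported for
# suid mitogenomes. Chosen once; see the methods vignette.
PIG_AA_FREQ <- c(
  L = 15.3, I = 8.9, T = 8.3, S = 7.5, M = 7.0, A = 6.8, N = 5.5,
  P = 5.3, F = 5.2, G = 4.8, V = 4.6, Y = 3.8, H = 3.0, Q = 2.8,
  K = 2.7, E = 2.4, D = 2.1, R = 1.8, W = 1.5, C = 0.7
)

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Synthetic-mitogenome specification
#'
#' Describes the world the generator emulates: the packaged 37-gene
#' coordinate skeleton on a 16,581 bp circle, a pig-like H-strand base
#' composition (A 34.0 / T 26.3 / C 27.8 / G 11.9 %), a control-region
#' tandem repeat (10 bp motif, 9 copies, local start 705), per-gene start
#' codons (ATG, with GTG on nad4l and ATT on nad2) and the six PCGs
#' annotated with incomplete stop codons (nad1, nad2, cox2, cox3, nad3,
#' nad4). All defaults are fixed to that stated world; override fields for
#' experiments.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param genome_length circle length in bp.
#' @param skeleton `mito_features` table (default: packaged skeleton).
#' @param base_freq named frequencies for A, C, G, T (H-strand sense).
#' @param repeat_motif,repeat_copies,repeat_local_start control-region
#'   tandem repeat: motif, copy number, and 1-based local start within the
#'   control region.
#' @param start_codons named overrides of per-PCG start codons.
#' @param incomplete_stop_genes PCG names annotated with incomplete stops.
#' @param aa_freq named amino-acid usage weights for PCG interiors.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       genome_length = 16581L,
                       skeleton = NULL,
                       base_freq = c(A = 0.340, C = 0.278, G = 0.119, T = 0.263),
                       repeat_motif = "CGTACACGTG",
                       repeat_copies = 9L,
                       repeat_local_start = 705L,
                       start_codons = c(nad4l = "GTG", nad2 = "ATT"),
                       incomplete_stop_genes = c("nad1", "nad2", "cox2",
                                                 "cox3", "nad3", "nad4"),
                       aa_freq = PIG_AA_FREQ) {
  if (is.null(skeleton)) skeleton <- mito_gene_skeleton(genome_length)
  stopifnot(attr(skeleton, "genome_length") == genome_length,
            abs(sum(base_freq) - 1) < 1e-8,
            all(c("A", "C", "G", "T") %in% names(base_freq)))
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    skeleton = skeleton, base_freq = base_freq[c("A", "C", "G", "T")],
    repeat_motif = toupper(repeat_motif),
    repeat_copies = as.integer(repeat_copies),
    repeat_local_start = as.integer(repeat_local_start),
    start_codons = start_codons,
    incomplete_stop_genes = incomplete_stop_genes,
    aa_freq = aa_freq
  ), class = "synth_spec")
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# Coding-order genome positions of a feature (reversed for the L strand).
coding_positions <- function(f, L) {
  pos <- feature_positions(as.integer(f$start), as.integer(f$stop),
                           isTRUE(f$wraps), L)
  if (identical(f$strand, "-")) rev(pos) else pos
}

# Write coding-sense bases into the H-strand character vector.
write_coding <- function(chars, genome_pos, strand, bases) {
  if (identical(strand, "-")) bases <- comp_base(bases)
  chars[genome_pos] <- bases
  chars
}

# Codon weights within each synonymous family, proportional to the
# product of target base frequencies over the three codon positions;
# yields the A/T third-position bias typical of mitogenomes.
family_codon_weights <- function(base_freq) {
  fam <- mito_families()
  lapply(fam, function(cs) {
    w <- vapply(cs, function(c3) {
      prod(base_freq[seq_chars(c3)])
    }, numeric(1))
    w / sum(w)
  })
}

#' Generate a pig-like synthetic mitogenome
#'
#' Builds a circular genome on the packaged coordinate skeleton whose
#' protein-coding genes are valid vertebrate-mitochondrial ORFs: the
#' configured start codon, no internal stop codons (enforced jointly
#' across overlapping genes in both frames and strands), and a complete
#' stop codon or the configured incomplete `T`/`TA` ending. The control
#' region carries the configured tandem-repeat run; all remaining
#' positions are drawn so that the genome-wide base composition matches
#' the spec target in expectation. Fully deterministic per seed.
#'
#' @param spec a [synth_spec()].
#' @return list with `genome` (a [circular_genome()]) and `truth`: the
#'   spec plus per-PCG proteins, start codons and stop statuses as built
#'   (recomputed from the final sequence at generation time).
#' @export
generate_genome <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  f <- spec$skeleton
  pcg <- f[f$gene_class == "PCG", , drop = FALSE]
  if (!nrow(pcg)) stop("skeleton has no PCG features")
  bf <- spec$base_freq
  chars <- sample(names(bf), L, replace = TRUE, prob = bf)
  locked <- logical(L)
  fam_w <- family_codon_weights(bf)
  fam <- mito_families()
  aa_names <- names(spec$aa_freq)
  aa_prob <- spec$aa_freq / sum(spec$aa_freq)

  gene_info <- vector("list", nrow(pcg))
  for (i in seq_len(nrow(pcg))) {
    gf <- pcg[i, ]
    cpos <- coding_positions(gf, L)
    len <- length(cpos)
    rem <- len %% 3L
    incomplete <- gf$name %in% spec$incomplete_stop_genes
    if (incomplete && rem == 0L) {
      stop("gene ", gf$name, " flagged incomplete but length is a codon multiple")
    }
    if (!incomplete && rem != 0L) {
      stop("gene ", gf$name, " length is not a codon multiple")
    }
    n_cod <- len %/% 3L
    interior <- if (incomplete) 2L:n_cod else 2L:(n_cod - 1L)
    gene_info[[i]] <- list(name = gf$name, strand = gf$strand, cpos = cpos,
                           n_cod = n_cod, rem = rem, incomplete = incomplete,
                           interior = interior)
  }
  names(gene_info) <- pcg$name

  # interior fill: amino acids from the usage table, codons by family bias
  for (gi in gene_info) {
    n_int <- length(gi$interior)
    aas <- sample(aa_names, n_int, replace = TRUE, prob = aa_prob)
    codons <- vapply(aas, function(a) {
      cs <- fam[[a]]
      if (length(cs) == 1L) cs else sample(cs, 1L, prob = fam_w[[a]])
    }, character(1))
    bases <- unlist(strsplit(codons, ""), use.names = FALSE)
    idx <- unlist(lapply(gi$interior, function(k) (3L * k - 2L):(3L * k)))
    chars <- write_coding(chars, gi$cpos[idx], gi$strand, bases)
  }

  # start codons, then stop codons / incomplete tails, with locking
  for (gi in gene_info) {
    sc <- if (gi$name %in% names(spec$start_codons))
      spec$start_codons[[gi$name]] else "ATG"
    if (!sc %in% c("ATG", "ATT", "ATA", "GTG")) {
      stop("unsupported start codon ", sc, " for ", gi$name)
    }
    p <- gi$cpos[1:3]
    chars <- write_coding(chars, p, gi$strand, seq_chars(sc))
    locked[p] <- TRUE
  }
  for (gi in gene_info) {
    if (gi$incomplete) {
      tail_bases <- if (gi$rem == 1L) "T" else c("T", "A")
      idx <- (3L * gi$n_cod + 1L):(3L * gi$n_cod + gi$rem)
      p <- gi$cpos[idx]
      chars <- write_coding(chars, p, gi$strand, tail_bases)
      locked[p] <- TRUE
    } else {
      idx <- (3L * gi$n_cod - 2L):(3L * gi$n_cod)
      p <- gi$cpos[idx]
      placed <- FALSE
      for (stop_codon in MITO_STOPS) {
        want <- seq_chars(stop_codon)
        h_want <- if (gi$strand == "-") comp_base(want) else want
        if (all(!locked[p] | chars[p] == h_want)) {
          chars <- write_coding(chars, p, gi$strand, want)
          locked[p] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("no stop codon compatible with locked overlap for ",
                        gi$name)
    }
  }

  # joint repair: remove internal stop codons without breaking any
  # overlapping gene's reading frame on either strand
  gene_at <- vector("list", L) # genome position -> list of (gene, offset)
  for (gi in gene_info) {
    for (k in seq_along(gi$cpos)) {
      p <- gi$cpos[k]
      gene_at[[p]] <- c(gene_at[[p]], list(list(name = gi$name, offset = k)))
    }
  }
  codon_at <- function(gi, cod_idx, chars) {
    idx <- (3L * cod_idx - 2L):(3L * cod_idx)
    b <- chars[gi$cpos[idx]]
    if (gi$strand == "-") b <- comp_base(b)
    paste(b, collapse = "")
  }
  violations <- function(chars) {
    out <- list()
    for (gi in gene_info) {
      for (k in gi$interior) {
        if (codon_at(gi, k, chars) %in% MITO_STOPS) {
          out[[length(out) + 1L]] <- list(gene = gi$name, codon = k)
        }
      }
    }
    out
  }
  edit_ok <- function(chars, p) {
    # does any gene covering p now read a stop codon anywhere a stop is
    # not allowed? (the terminal codon of a complete-stop gene is the only
    # place a stop belongs, and those positions are locked anyway)
    for (hit in gene_at[[p]]) {
      gi <- gene_info[[hit$name]]
      cod_idx <- (hit$offset + 2L) %/% 3L
      if (cod_idx > gi$n_cod) next            # trailing partial codon
      terminal_stop_ok <- (cod_idx == gi$n_cod && !gi$incomplete)
      if (!terminal_stop_ok &&
          codon_at(gi, cod_idx, chars) %in% MITO_STOPS) {
        return(FALSE)
      }
    }
    TRUE
  }
  for (iter in seq_len(200L)) {
    v <- violations(chars)
    if (!length(v)) break
    fixed_one <- FALSE
    for (vi in v) {
      gi <- gene_info[[vi$gene]]
      idx <- (3L * vi$codon - 2L):(3L * vi$codon)
      pos3 <- gi$cpos[idx]
      done <- FALSE
      for (k in 3:1) { # prefer third-position edits
        p <- pos3[k]
        if (locked[p]) next
        old <- chars[p]
        for (b in setdiff(names(bf), old)) {
          chars[p] <- b
          if (!(codon_at(gi, vi$codon, chars) %in% MITO_STOPS) &&
              edit_ok(chars, p)) {
            done <- TRUE
            break
          }
          chars[p] <- old
        }
        if (done) break
      }
      if (done) fixed_one <- TRUE
    }
    if (!fixed_one && length(violations(chars))) {
      stop("could not repair internal stop codons in overlapping genes")
    }
  }
  if (length(violations(chars))) {
    stop("internal stop codons remain after repair")
  }

  # control-region tandem repeat
  ctrl <- f[f$gene_class == "control", , drop = FALSE]
  repeat_pos <- integer(0)
  if (nrow(ctrl) == 1L && spec$repeat_copies > 0L) {
    run <- strrep(spec$repeat_motif, spec$repeat_copies)
    local <- spec$repeat_local_start - 1L + seq_len(nchar(run))
    if (max(local) > ctrl$length[1]) stop("repeat run overflows control region")
    gp <- local_to_genome(local, ctrl[1, ], L)
    if (any(locked[gp])) stop("repeat run collides with a locked PCG position")
    chars[gp] <- seq_chars(run)
    repeat_pos <- gp
  }

  # residual background so the genome-wide composition meets the target
  pcg_pos <- unique(unlist(lapply(gene_info, `[[`, "cpos")))
  fixed <- union(pcg_pos, repeat_pos)
  free <- setdiff(seq_len(L), fixed)
  if (length(free)) {
    cnt_fixed <- table(factor(chars[fixed], levels = names(bf)))
    resid <- pmax(L * bf - as.numeric(cnt_fixed), 0)
    if (sum(resid) == 0) resid <- bf
    chars[free] <- sample(names(bf), length(free), replace = TRUE,
                          prob = resid / sum(resid))
  }

  seq <- paste(chars, collapse = "")
  genome <- circular_genome(seq = seq, features = f)
  # truth recomputed from the final sequence
  prof <- lapply(pcg$name, function(nm) translate_mito(extract_region(genome, nm)))
  names(prof) <- pcg$name
  truth <- list(
    spec = spec,
    proteins = lapply(prof, `[[`, "protein"),
    start_codons = vapply(prof, `[[`, character(1), "start_codon"),
    stop_statuses = vapply(prof, `[[`, character(1), "stop_status")
  )
  list(genome = genome, truth = truth)
}

#' Inject point variants into a genome sequence
#'
#' @param genome a [circular_genome()].
#' @param variants data.frame with `position` (1-based) and `base`.
#' @return nucleotide string with the substitutions applied.
#' @export
inject_variants <- function(genome, variants) {
  stopifnot(inherits(genome, "circular_genome"), !is.null(genome$seq))
  ch <- seq_chars(genome$seq)
  pos <- as.integer(variants$position)
  if (anyDuplicated(pos)) stop("injected positions must be distinct")
  if (any(pos < 1L | pos > genome$length)) stop("variant position out of genome")
  ch[pos] <- toupper(as.character(variants$base))
  paste(ch, collapse = "")
}

#' Haplotype panel with one sample per scheme label
#'
#' Builds an alignment containing the base genome plus one synthetic
#' sample per haplotype 4-mer of the scheme, each obtained by writing the
#' 4-mer's bases at the scheme positions. Classifying the panel recovers
#' every label exhaustively.
#'
#' @param base a [circular_genome()] (or result of [generate_genome()]).
#' @param scheme a [haplotype_scheme()] whose positions lie within the
#'   genome.
#' @return an [alignment_matrix()] with rows `base` and one per label.
#' @export
make_haplotype_panel <- function(base, scheme = haplotype_scheme()) {
  if (is.list(base) && !inherits(base, "circular_genome") &&
      !is.null(base$genome)) {
    base <- base$genome
  }
  stopifnot(inherits(base, "circular_genome"), !is.null(base$seq),
            inherits(scheme, "haplotype_scheme"))
  if (max(scheme$positions) > base$length) {
    stop("scheme positions exceed genome length")
  }
  seqs <- c(base = base$seq)
  for (key in names(scheme$labels)) {
    v <- data.frame(position = scheme$positions, base = seq_chars(key))
    seqs[[scheme$labels[[key]]]] <- inject_variants(base, v)
  }
  alignment_matrix(seqs)
}

#' Simulate an alignment down a tree under TN93
#'
#' Evolves sites independently along a tree with branch lengths in
#' expected substitutions/site, under the Tamura-Nei model with the given
#' stationary base frequencies and the two transition/transversion rate
#' multipliers. Deterministic per seed.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param length number of alignment columns.
#' @param base_freq stationary frequencies for A, C, G, T.
#' @param kappa1 purine-transition rate multiplier (A<->G) vs transversions.
#' @param kappa2 pyrimidine-transition rate multiplier (C<->T).
#' @param seed integer seed.
#' @return an [alignment_matrix()] with the tree's tip labels as rows.
#' @export
simulate_alignment <- function(tree, length,
                               base_freq = c(A = 0.31, C = 0.26,
                                             G = 0.13, T = 0.30),
                               kappa1 = 8, kappa2 = 8, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            length >= 1L)
  pi <- base_freq[c("A", "C", "G", "T")]
  pi <- pi / sum(pi)
  Q <- matrix(0, 4, 4, dimnames = list(MITO_BASES, MITO_BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    pair <- sort(c(MITO_BASES[i], MITO_BASES[j]))
    rate <- if (identical(pair, c("A", "G"))) kappa1
            else if (identical(pair, c("C", "T"))) kappa2
            else 1
    Q[i, j] <- rate * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q)) # expected substitutions per unit time
  Q <- Q / mu
  eg <- eigen(Q)
  Pmat <- function(t) {
    P <- eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors)
    P <- pmax(Re(P), 0)
    P / rowSums(P)
  }
  set.seed(as.integer(seed))
  tree <- stats::reorder(tree, "cladewise") # parents before children
  ntip <- base::length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, length)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    P <- Pmat(tree$edge.length[e])
    ps <- states[par, ]
    cs <- integer(length)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (base::length(idx)) {
        cs[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                              prob = P[s, ])
      }
    }
    states[child, ] <- cs
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(MITO_BASES[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  alignment_matrix(seqs)
}
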