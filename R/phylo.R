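# Encode an alignment row to integers 1..4 (A,C,G,T), NA otherwise.
encode_bases <- function(ch) {
  match(ch, MITO_BASES)
}

encode_alignment <- function(aln) {
  m <- unclass(aln)
  out <- matrix(match(m, MITO_BASES), nrow = nrow(m),
                dimnames = dimnames(m))
  out
}

#' Tamura-Nei (TN93) pairwise distance
#'
#' Maximum-likelihood distance under the Tamura-Nei 1993 model, which
#' distinguishes purine transitions (A<->G, proportion P1), pyrimidine
#' transitions (C<->T, proportion P2) and transversions (proportion Q),
#' with unequal base frequencies. Frequencies are the empirical pooled
#' frequencies of the two sequences over their shared usable columns
#' (pairwise deletion: any column where either base is not A/C/G/T is
#' excluded). With all frequencies equal and P1 = P2 the formula collapses
#' to the Kimura two-parameter distance.
#'
#' A saturated pair (any logarithm argument <= 0) is inapplicable and
#' returned as `NA` rather than NaN or Inf.
#'
#' @param seqA,seqB aligned sequences: strings, character vectors, or
#'   integer-encoded vectors (1..4 = A,C,G,T).
#' @return distance in substitutions/site (>= 0), or `NA` if inapplicable.
#' @export
tn93_distance <- function(seqA, seqB) {
  a <- if (is.numeric(seqA)) seqA else encode_bases(
    if (length(seqA) == 1L) seq_chars(seqA) else toupper(seqA))
  b <- if (is.numeric(seqB)) seqB else encode_bases(
    if (length(seqB) == 1L) seq_chars(seqB) else toupper(seqB))
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) return(NA_real_)
  # pooled base frequencies over usable columns of both sequences
  cnt <- tabulate(a, 4L) + tabulate(b, 4L)
  pi <- cnt / sum(cnt)
  names(pi) <- MITO_BASES
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- piA + piG; piY <- piC + piT
  diff <- a != b
  pur <- (a == 1L & b == 3L) | (a == 3L & b == 1L)     # A<->G
  pyr <- (a == 2L & b == 4L) | (a == 4L & b == 2L)     # C<->T
  P1 <- sum(pur) / n
  P2 <- sum(pyr) / n
  Q <- sum(diff & !pur & !pyr) / n
  if (P1 + P2 + Q == 0) return(0)
  k1 <- if (piR > 0) 2 * piA * piG / piR else 0
  k2 <- if (piY > 0) 2 * piT * piC / piY else 0
  k3 <- 2 * (piR * piY -
               (if (piR > 0) piA * piG * piY / piR else 0) -
               (if (piY > 0) piT * piC * piR / piY else 0))
  term <- function(k, w) {
    if (k <= 0) return(if (w < 1) NA_real_ else 0) # zero-weight class
    if (w <= 0) return(NA_real_)                   # saturated
    -k * log(w)
  }
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * piR) else 1 - (P1 > 0)
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * piY) else 1 - (P2 > 0)
  w3 <- if (piR * piY > 0) 1 - Q / (2 * piR * piY) else 1 - (Q > 0)
  t1 <- term(k1, w1); t2 <- term(k2, w2); t3 <- term(k3, w3)
  if (anyNA(c(t1, t2, t3))) return(NA_real_)
  max(t1 + t2 + t3, 0)
}

#' TN93 distance matrix for an alignment
#'
#' @param aln an [alignment_matrix()].
#' @return symmetric matrix of class `dist_matrix` with taxon dimnames;
#'   inapplicable (saturated) pairs are `NA`.
#' @export
tn93_distance_matrix <- function(aln) {
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- tn93_distance(enc[i, ], enc[j, ])
    D[i, j] <- D[j, i] <- d
  }
  class(D) <- c("dist_matrix", class(D))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q criterion
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j`. Branch lengths come from the
#' standard NJ formulas; the final three lineages are resolved by the
#' three-point closed form, producing an unrooted tree with a basal
#' trifurcation. Ties in Q are broken by the smallest `(i, j)` index pair
#' in the current ordering, making the algorithm fully deterministic.
#' Negative branch lengths are kept as computed (and reported via a
#' message) so that the additive-matrix recovery guarantee is exact; use
#' `clamp_negative = TRUE` for display trees.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @param clamp_negative clamp negative branch lengths to zero.
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(D, clamp_negative = FALSE) {
  D <- unclass(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3L,
            !is.null(rownames(D)))
  if (anyNA(D)) {
    bad <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop("inapplicable distance between '", rownames(D)[bad[1]],
         "' and '", rownames(D)[bad[2]], "'")
  }
  labels <- rownames(D)
  # active nodes carried as Newick fragments
  frag <- labels
  n <- length(frag)
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3L) {
    r <- rowSums(D)
    Qm <- (n - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    # smallest Q; ties -> smallest (i, j) in current order
    best <- which(Qm == min(Qm), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (!clamp_negative && (vi < 0 || vj < 0)) {
      message("nj_tree: negative branch length kept as computed")
    }
    if (clamp_negative) { vi <- max(vi, 0); vj <- max(vj, 0) }
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",",
                       frag[j], ":", fmt(vj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    n <- n - 1L
  }
  # resolve the last three lineages
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) { va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0) }
  nwk <- paste0("(", frag[1], ":", fmt(va), ",", frag[2], ":", fmt(vb),
                ",", frag[3], ":", fmt(vc), ");")
  ape::read.tree(text = nwk)
}

# Canonical key of the bipartition induced by a set of tip labels:
# the side NOT containing the reference taxon, sorted and joined.
split_key <- function(tips, all_tips) {
  ref <- sort(all_tips)[1]
  side <- sort(tips)
  if (ref %in% side) side <- sort(setdiff(all_tips, tips))
  paste(side, collapse = "\r")
}

# Non-trivial bipartition keys of a tree, named by the internal node that
# subtends each split in the tree's current (arbitrary) rooting. A split
# is non-trivial when both sides hold at least 2 tips.
tree_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  parts <- ape::prop.part(phy)
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    size <- length(parts[[k]])
    if (size < 2L || size > ntip - 2L) next
    keys <- c(keys, split_key(phy$tip.label[parts[[k]]], phy$tip.label))
    nodes <- c(nodes, ntip + k)
  }
  stats::setNames(keys, nodes)
}

#' Nonparametric bootstrap supports for a TN93 + NJ tree
#'
#' Builds the main tree from the full alignment, then resamples alignment
#' columns with replacement `replicates` times, rebuilds the TN93 distance
#' matrix and NJ tree for each replicate, and scores every internal edge
#' of the main tree by the percentage of replicate trees containing the
#' same leaf bipartition. The resample of replicate `r` is a pure function
#' of `(seed, r)`, so runs are reproducible and independent of evaluation
#' order. A replicate whose distance matrix contains an inapplicable
#' (saturated) entry is dropped and counted; more than 10% dropped is an
#' error.
#'
#' @param aln an [alignment_matrix()].
#' @param replicates bootstrap replicates (>= 1; published mitogenome
#'   trees conventionally use 1000).
#' @param seed integer seed for the replicate stream.
#' @param clamp_negative passed to [nj_tree()] for the main tree.
#' @return the main [ape::phylo] tree with integer support percentages as
#'   `node.label` (empty on the basal node), plus attributes
#'   `support` (named numeric, full precision), `replicates_used` and
#'   `replicates_dropped`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L,
                              clamp_negative = FALSE) {
  stopifnot(replicates >= 1L)
  enc <- encode_alignment(aln)
  ncol_a <- ncol(enc)
  main_D <- tn93_distance_matrix(aln)
  main <- nj_tree(main_D, clamp_negative = clamp_negative)
  main_splits <- tree_splits(main)
  counts <- stats::setNames(numeric(length(main_splits)), main_splits)
  dropped <- 0L
  used <- 0L
  taxa <- rownames(enc)
  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(seed, r))
    idx <- sample.int(ncol_a, ncol_a, replace = TRUE)
    sub <- enc[, idx, drop = FALSE]
    n <- nrow(sub)
    D <- matrix(0, n, n, dimnames = list(taxa, taxa))
    bad <- FALSE
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- tn93_distance(sub[i, ], sub[j, ])
        if (is.na(d)) { bad <- TRUE; break }
        D[i, j] <- D[j, i] <- d
      }
      if (bad) break
    }
    if (bad) { dropped <- dropped + 1L; next }
    rep_tree <- suppressMessages(nj_tree(D))
    rep_keys <- tree_splits(rep_tree)
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  if (dropped > 0.10 * replicates) {
    stop(dropped, " of ", replicates,
         " bootstrap replicates had inapplicable distances")
  }
  support <- 100 * counts / max(used, 1L)
  # attach as node labels (rounded integers, the usual display convention)
  nlab <- rep("", main$Nnode)
  for (k in seq_along(main_splits)) {
    node <- as.integer(names(main_splits)[k])
    nlab[node - length(main$tip.label)] <-
      as.character(round(support[[main_splits[k]]]))
  }
  main$node.label <- nlab
  attr(main, "support") <- stats::setNames(unname(support), main_splits)
  attr(main, "replicates_used") <- used
  attr(main, "replicates_dropped") <- dropped
  main
}

#' Support value of a given taxon bipartition
#'
#' Looks up the bootstrap support attached by [bootstrap_support()] for
#' the split separating `tips` from the rest of the taxa.
#'
#' @param tree tree returned by [bootstrap_support()].
#' @param tips character vector: one side of the bipartition.
#' @return support percentage, or `NA` if the main tree does not contain
#'   that split.
#' @export
split_support <- function(tree, tips) {
  sup <- attr(tree, "support")
  key <- split_key(tips, tree$tip.label)
  if (!key %in% names(sup)) return(NA_real_)
  unname(sup[[key]])
}

#' Root a tree on an outgroup
#'
#' Places the root on the outgroup's pendant edge. Node labels (bootstrap
#' supports) are kept attached to the same bipartitions via ape's
#' edge-label-aware rerooting.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup a tip label.
#' @return rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Write / read Newick trees
#'
#' Thin wrappers over ape's Newick serialization, fixing the conventions
#' used across the package: branch lengths with up to 6 significant
#' decimals, bootstrap supports as internal node labels, and an optional
#' display rule that blanks supports under a threshold (the usual
#' "values under 70 are not shown" figure convention).
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @param hide_below blank node labels under this support (NULL = keep all).
#' @return `path` (writer) or an `ape::phylo` (reader), invisibly.
#' @export
write_newick <- function(tree, path, hide_below = NULL) {
  if (!is.null(hide_below) && !is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label[!is.na(lab) & lab < hide_below] <- ""
  }
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write / read a labeled square distance matrix as TSV
#'
#' @param D distance matrix with dimnames.
#' @param path file path.
#' @return `path` (writer) or matrix (reader), invisibly for the writer.
#' @export
write_distance_tsv <- function(D, path) {
  utils::write.table(cbind(taxon = rownames(D), as.data.frame(unclass(D))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
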