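test_that("tn93_distance basics: identity, symmetry, pairwise deletion", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT"), 0)
  set.seed(4)
  for (i in 1:10) {
    a <- rand_seq(300); b <- rand_seq(300)
    expect_equal(tn93_distance(a, b), tn93_distance(b, a), tolerance = 1e-12)
  }
  # N/gap columns are excluded pairwise
  expect_equal(tn93_distance("ACGTN", "ACGTA"), 0)
})

test_that("tn93_distance matches the ape reference implementation", {
  set.seed(8)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length * 0.08
  aln <- simulate_alignment(tr, 1500, seed = 2)
  m <- unclass(aln)
  for (p in list(c(1, 2), c(2, 5), c(3, 6))) {
    bin <- ape::as.DNAbin(m[p, , drop = FALSE])
    oracle <- as.numeric(ape::dist.dna(bin, model = "TN93",
                                       pairwise.deletion = TRUE))
    expect_equal(tn93_distance(m[p[1], ], m[p[2], ]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("tn93 collapses to the K2P closed form at equal frequencies", {
  # build a pair with exactly equal pooled frequencies and P1 = P2
  m <- 50L; s <- 5L; v <- 3L
  blocks_a <- c(strrep("A", m), strrep("C", m), strrep("G", m), strrep("T", m),
                strrep("A", s), strrep("G", s), strrep("C", s), strrep("T", s),
                strrep("A", v), strrep("C", v), strrep("G", v), strrep("T", v))
  blocks_b <- c(strrep("A", m), strrep("C", m), strrep("G", m), strrep("T", m),
                strrep("G", s), strrep("A", s), strrep("T", s), strrep("C", s),
                strrep("C", v), strrep("A", v), strrep("T", v), strrep("G", v))
  a <- paste(blocks_a, collapse = ""); b <- paste(blocks_b, collapse = "")
  N <- nchar(a)
  P <- 4 * s / N; Q <- 4 * v / N
  k2p <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  expect_equal(tn93_distance(a, b), k2p, tolerance = 1e-10)
})

test_that("tn93 is monotone in injected mutations and flags saturation", {
  set.seed(6)
  base <- rand_seq(2000)
  ch <- strsplit(base, "")[[1]]
  prev <- -1
  mutated <- ch
  for (k in c(10, 50, 150, 300)) {
    idx <- seq_len(k) * 6L   # distinct, spread positions
    mutated2 <- ch
    mutated2[idx] <- vapply(ch[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    d <- tn93_distance(paste(ch, collapse = ""),
                       paste(mutated2, collapse = ""))
    expect_gt(d, prev)
    prev <- d
  }
  # saturation: log argument <= 0 -> inapplicable marker, not NaN
  expect_true(is.na(tn93_distance(strrep("A", 50), strrep("G", 50))))
})

test_that("nj_tree resolves three taxa by the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D)
  el <- stats::setNames(t3$edge.length,
                        t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["c"]), (4 + 5 - 3) / 2)
})

test_that("nj_tree exactly recovers additive matrices (path-length oracle)", {
  set.seed(12)
  for (n in 4:8) {
    tr <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr)    # oracle: brute-force path sums
    mine <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                           ape::unroot(tr))), 0)
    co <- ape::cophenetic.phylo(mine)[rownames(D), colnames(D)]
    expect_equal(co, D, tolerance = 1e-8)
  }
})

test_that("nj_tree is deterministic and rejects inapplicable entries", {
  set.seed(14)
  tr <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tr)
  expect_identical(ape::write.tree(nj_tree(D)), ape::write.tree(nj_tree(D)))
  D[2, 5] <- D[5, 2] <- NA
  expect_error(nj_tree(D), "inapplicable distance between")
  expect_error(nj_tree(D[1:2, 1:2]), "nrow")
})

test_that("bootstrap supports are reproducible and order-invariant", {
  tr <- two_clade_tree()
  aln <- simulate_alignment(tr, 800, seed = 20)
  b1 <- bootstrap_support(aln, replicates = 40, seed = 99)
  b2 <- bootstrap_support(aln, replicates = 40, seed = 99)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- attr(b1, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  # taxon reordering leaves split supports unchanged
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  aln_perm <- alignment_matrix(unclass(aln)[perm, , drop = FALSE])
  b3 <- bootstrap_support(aln_perm, replicates = 40, seed = 99)
  key_tips <- c("A1", "A2", "A3", "A4")
  expect_equal(split_support(b1, key_tips), split_support(b3, key_tips))
})

test_that("perfect clade signal yields 100% support everywhere", {
  set.seed(33)
  blockA <- strrep("A", 30); blockB <- strrep("G", 30)
  common <- rand_seq(400)
  seqs <- c(x1 = paste0(blockA, common), x2 = paste0(blockA, common),
            x3 = paste0(blockA, common), y1 = paste0(blockB, common),
            y2 = paste0(blockB, common), y3 = paste0(blockB, common))
  aln <- alignment_matrix(seqs)
  bt <- bootstrap_support(aln, replicates = 30, seed = 1)
  sup <- attr(bt, "support")
  expect_true(all(sup == 100))
})

test_that("outgroup rooting places the root on the outgroup edge", {
  tr <- nj_tree(ape::cophenetic.phylo(ape::read.tree(
    text = "((A:1,B:2):1,(C:3,D:4):2);")))
  rooted <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  root_children <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(which(rooted$tip.label == "D") %in% root_children)
  expect_error(root_with_outgroup(tr, "Z"), "not a tip")
  # rooting/unrooting preserves the bipartition set
  splits_before <- sort(unname(mitochar:::tree_splits(ape::unroot(tr))))
  splits_after <- sort(unname(mitochar:::tree_splits(ape::unroot(rooted))))
  expect_equal(splits_before, splits_after)
})

test_that("newick and distance-matrix files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".nwk")
  tr <- two_clade_tree()
  aln <- simulate_alignment(tr, 400, seed = 3)
  bt <- bootstrap_support(aln, replicates = 20, seed = 7)
  write_newick(bt, tmp)
  back <- read_newick(tmp)
  expect_equal(sort(back$tip.label), sort(bt$tip.label))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back),
                                         ape::unroot(bt))), 0)
  # support-hiding display rule blanks low labels only
  write_newick(bt, tmp, hide_below = 70)
  shown <- read_newick(tmp)$node.label
  lab <- suppressWarnings(as.numeric(shown[shown != "" & !is.na(shown)]))
  expect_true(all(lab >= 70))

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  D <- tn93_distance_matrix(aln)
  write_distance_tsv(D, tmp2)
  D2 <- read_distance_tsv(tmp2)
  expect_equal(unclass(D), D2, tolerance = 1e-12, ignore_attr = TRUE)
})
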