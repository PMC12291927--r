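test_that("extract_region is wrap- and strand-aware", {
  # wrapping slice on a 4 bp circle
  g <- circular_genome(seq = "ACGT",
                       features = gene_features("w", 3, 2, "+", "PCG", 4))
  expect_equal(extract_region(g, g$features[1, ]), "GTAC")
  # light strand: reverse complement of the H-strand slice
  g2 <- circular_genome(seq = "AAAC",
                        features = gene_features("l", 1, 4, "-", "tRNA", 4))
  expect_equal(extract_region(g2, "l"), "GTTT")
  # whole genome
  g3 <- circular_genome(seq = "ACGTACGT",
                        features = gene_features("all", 1, 8, "+", "control", 8))
  expect_equal(nchar(extract_region(g3, "all")), 8L)
})

test_that("composition_summary computes skews by the stated formulas", {
  s <- composition_summary(strrep("A", 340) |> paste0(strrep("T", 263)) |>
                             paste0(strrep("C", 278)) |> paste0(strrep("G", 119)))
  expect_equal(s$at_skew, (340 - 263) / (340 + 263))
  expect_equal(s$gc_skew, (119 - 278) / (119 + 278))
  expect_equal(s$at_percent, 60.3, tolerance = 1e-6)

  s2 <- composition_summary("ATATAT")
  expect_equal(s2$at_skew, 0)
  expect_true(is.na(s2$gc_skew))  # undefined, never coerced to 0

  # N excluded from denominators
  s3 <- composition_summary("AANN")
  expect_equal(unname(s3$percent[["A"]]), 100)
})

test_that("skews are antisymmetric under reverse complement", {
  set.seed(3)
  for (i in 1:20) {
    s <- rand_seq(200)
    a <- composition_summary(s)
    b <- composition_summary(revcomp(s))
    expect_equal(a$at_skew, -b$at_skew, tolerance = 1e-12)
    expect_equal(a$gc_skew, -b$gc_skew, tolerance = 1e-12)
  }
})

test_that("translate_mito classifies starts and stop completion", {
  tr <- translate_mito("ATGTGATAA")
  expect_equal(tr$protein, "MW")           # TGA is Trp, terminal TAA dropped
  expect_equal(tr$start_codon, "ATG")
  expect_equal(tr$stop_status, "complete")
  expect_false(tr$internal_stop)

  expect_equal(translate_mito(paste0("ATGAAACCC", "T"))$stop_status,
               "incomplete_T")
  expect_equal(translate_mito(paste0("ATGAAACCC", "TA"))$stop_status,
               "incomplete_TA")
  expect_equal(translate_mito("GTGAAATAA")$start_codon, "GTG")
  expect_equal(translate_mito("ATGAAACCC")$stop_status, "none")

  # AGA is a vertebrate-mitochondrial stop; internal stop is flagged
  tr2 <- translate_mito("ATGAGAAAATAA")
  expect_true(tr2$internal_stop)
  expect_equal(tr2$stop_status, "complete")

  # ATA codes Met under this code
  expect_equal(translate_mito("ATAAAATAA")$protein, "MK")
  expect_error(translate_mito("ATG"), "shorter")
})

test_that("rscu follows the family formula and conserves family sums", {
  r <- rscu(c(AAA = 5, AAG = 5))               # Lys family, uniform usage
  expect_equal(unname(r[c("AAA", "AAG")]), c(1, 1))

  r2 <- rscu(c(GGG = 8))                       # Gly family of 4, all in one
  expect_equal(unname(r2["GGG"]), 4)
  expect_equal(unname(r2[c("GGA", "GGC", "GGT")]), c(0, 0, 0))

  # family-sum conservation under randomized counts
  fams <- split(names(attr(r, "aa")), attr(r, "aa"))
  set.seed(5)
  for (i in 1:25) {
    counts <- stats::setNames(rpois(60, 4), names(attr(r, "aa")))
    rr <- rscu(counts)
    for (a in names(fams)) {
      fam_sum <- sum(rr[fams[[a]]])
      if (sum(counts[fams[[a]]]) > 0) {
        expect_equal(fam_sum, length(fams[[a]]), tolerance = 1e-9)
      } else {
        expect_equal(fam_sum, 0)
      }
    }
  }
  # stop codons are excluded from families
  expect_false(any(c("TAA", "TAG", "AGA", "AGG") %in% names(r)))
})

test_that("amino_acid_distribution pools residues and excludes symbols", {
  d <- amino_acid_distribution(c("LL", "II"))
  expect_equal(unname(d[c("I", "L")]), c(50, 50))
  expect_error(amino_acid_distribution(character(0)))
  expect_error(amino_acid_distribution("*"), "no residues")
  expect_equal(sum(amino_acid_distribution(c("LLIK*X"))), 100)
})

test_that("codon_profile reports per-gene start/stop classification", {
  out <- get_synth()
  prof <- codon_profile(out$genome)
  expect_setequal(prof$genes$name,
                  out$genome$features$name[out$genome$features$gene_class == "PCG"])
  expect_true(all(prof$genes$start_codon %in% c("ATG", "ATT", "GTG")))
  incomplete <- prof$genes$name[grepl("incomplete", prof$genes$stop_status)]
  expect_setequal(incomplete, c("nad1", "nad2", "cox2", "cox3", "nad3", "nad4"))
  expect_false(any(prof$genes$internal_stop))
  expect_equal(sum(prof$aa_percent), 100)
})
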