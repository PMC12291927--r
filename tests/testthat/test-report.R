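# End-to-end characterization runs on the packaged synthetic fixture.

write_synth_inputs <- function(dir, seed = 7L) {
  out <- get_synth(seed)
  g <- out$genome
  fasta <- file.path(dir, "genome.fasta")
  annot <- file.path(dir, "annot.tsv")
  write_genome_fasta(g$seq, "synthetic_mitogenome", fasta)
  f <- g$features
  utils::write.table(
    f[, c("name", "start", "stop", "strand", "gene_class")], annot,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("name", "start", "stop", "strand", "class"))
  aln <- file.path(dir, "aln.fasta")
  write_aligned_fasta(make_haplotype_panel(out), aln)
  list(genome = fasta, annot = annot, aln = aln, g = g)
}

test_that("run_characterization writes every stage output", {
  dir <- withr::local_tempdir()
  inp <- write_synth_inputs(dir)
  cfg <- run_config(
    genome_fasta = inp$genome, annotation_tsv = inp$annot,
    alignment_fasta = inp$aln,
    stages = c("organize", "composition", "rscu", "repeats",
               "variation", "haplotype"),
    outdir = file.path(dir, "out"))
  paths <- run_characterization(cfg)
  expect_setequal(names(paths),
                  c("organization.tsv", "composition.tsv", "codon_rscu.tsv",
                    "pcg_codons.tsv", "aa_distribution.tsv", "repeats.tsv",
                    "polymorphic_sites.tsv", "variation_summary.tsv",
                    "haplotypes.tsv"))
  for (p in unlist(paths)) expect_true(file.exists(p))
  # organization summary block carries the fixture's censuses (9, 76, 10, 58)
  lines <- readLines(paths[["organization.tsv"]])
  expect_true(any(grepl("^# overlaps\t9\t76\t43$", lines)))
  expect_true(any(grepl("^# spacers\t10\t58\t32$", lines)))
  # no phylo stage -> no tree output
  expect_false(file.exists(file.path(dir, "out", "tree.nwk")))
  # every output announces the package version + config fingerprint
  expect_true(all(vapply(unlist(paths), function(p)
    grepl("^# mitochar ", readLines(p, n = 1)), logical(1))))
})

test_that("reruns with the same config are byte-identical", {
  dir <- withr::local_tempdir()
  inp <- write_synth_inputs(dir)
  run <- function(outdir) {
    cfg <- run_config(genome_fasta = inp$genome, annotation_tsv = inp$annot,
                      alignment_fasta = inp$aln,
                      stages = c("organize", "rscu", "repeats", "haplotype"),
                      outdir = outdir)
    run_characterization(cfg)
  }
  p1 <- run(file.path(dir, "o1"))
  p2 <- run(file.path(dir, "o2"))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = nm)
  }
})

test_that("configuration errors are raised before any work", {
  dir <- withr::local_tempdir()
  inp <- write_synth_inputs(dir)
  cfg <- run_config(genome_fasta = inp$genome, annotation_tsv = inp$annot,
                    stages = c("organize", "phylo"),
                    outdir = file.path(dir, "out"))
  expect_error(run_characterization(cfg), "require alignment_fasta")
  expect_false(dir.exists(file.path(dir, "out")))
  expect_error(run_config(stages = "nonsense"), "unknown stage")
  expect_error(run_characterization(
    run_config(annotation_tsv = file.path(dir, "missing.tsv"),
               stages = "organize", outdir = file.path(dir, "out2"))),
    "does not exist")
})

test_that("phylo stage writes a rooted Newick tree with supports", {
  dir <- withr::local_tempdir()
  tr <- two_clade_tree()
  aln_path <- file.path(dir, "sim.fasta")
  write_aligned_fasta(simulate_alignment(tr, 600, seed = 4), aln_path)
  cfg <- run_config(alignment_fasta = aln_path, stages = "phylo",
                    replicates = 25, seed = 2, outgroup = "E1",
                    outdir = file.path(dir, "out"))
  paths <- run_characterization(cfg)
  tree <- read_newick(paths[["tree.nwk"]])
  expect_setequal(tree$tip.label, tr$tip.label)
  expect_true(ape::is.rooted(tree))
  expect_true(file.exists(paths[["distances.tsv"]]))
})

test_that("config files merge under override precedence", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(replicates = 250, seed = 9, outdir = "from_file"),
                       cfg_path, auto_unbox = TRUE)
  cfg <- run_config(cfg_path, outdir = "from_flag")
  expect_equal(cfg$replicates, 250L)
  expect_equal(cfg$outdir, "from_flag")   # flags win
  expect_equal(cfg$seed, 9)
})

test_that("the command-line front end runs a stage end to end", {
  dir <- withr::local_tempdir()
  inp <- write_synth_inputs(dir)
  cli <- system.file("cli", "mitochar.R", package = "mitochar")
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2(rscript, c(cli, "organize", "--annot", inp$annot,
                       "--length", "16581", "--out", file.path(dir, "cli_out")),
            stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(file.path(dir, "cli_out", "organization.tsv")))
  expect_true(any(grepl("organization.tsv", res)))
})
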