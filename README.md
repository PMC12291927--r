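# mitochar

Characterization of circular mitochondrial genomes in R.

`mitochar` implements the analysis pipeline behind a typical vertebrate
mitogenome report — the kind written for a newly assembled ~16.5 kb
circle carrying 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and a
control region — for researchers in molecular ecology, conservation
genetics and phylogenetics who want those numbers reproducibly from code
rather than from a GUI:

- **Gene organization on the circle.** Wrap-aware 1-based inclusive
  coordinates, recomputed gene lengths, the signed intergenic column
  (`next.start − prev.stop − 1`, negative = overlap), overlap/spacer
  censuses, the H/L strand census, and the length of the union of PCG
  intervals (overlapping positions counted once).
- **Composition and strand asymmetry.** Base percentages, A+T content,
  and the skew statistics AT skew = (A−T)/(A+T), GC skew = (G−C)/(G+C);
  undefined skews (zero denominator) are reported as `NA`, never 0.
- **Coding-sequence statistics.** Translation under the vertebrate
  mitochondrial code (AGA/AGG stop, ATA = Met, TGA = Trp), start-codon
  and incomplete-stop (`T--`/`TA-`) classification, relative synonymous
  codon usage RSCU(c) = n_c · k / Σ_family n, and pooled amino-acid
  distributions.
- **Control-region tandem repeats.** Maximal runs of consecutive
  whole-motif copies with an optional per-copy mismatch budget, plus
  overlapping motif-occurrence (duplication) detection.
- **Variation and haplotyping.** Polymorphic-site census (gap/N are
  missing data, not alleles), amino-acid substitution mapping against a
  reference row, pairwise site differences, and the four-site
  cytochrome *b* haplotype classifier (E1/E2 European, A1/A2/A3 Asian
  lineages; positions fully parameterizable).
- **Phylogenetics.** Tamura–Nei (TN93) pairwise distances with pairwise
  deletion and pooled empirical base frequencies, Saitou–Nei neighbor
  joining with the Studier–Keppler criterion, seeded nonparametric
  bootstrap supports over leaf bipartitions, outgroup rooting, Newick
  output (supports as node labels).
- **Synthetic data with known truth.** A seeded generator that builds a
  pig-like mitogenome on a real 37-gene coordinate skeleton: valid ORFs
  across overlapping genes on both strands, configurable incomplete
  stops, a control-region repeat run, target base composition, variant
  injection, haplotype panels, and TN93 sequence simulation down a tree
  — so every stage is testable offline.

## Worked example

```r
library(mitochar)

out <- generate_genome(synth_spec(seed = 1))   # pig-like synthetic circle
g <- out$genome

organization_report(g)
#> <organization_report> 37 genes (28 H / 9 L)
#>   overlaps: 9 (76 bp total, max 43)
#>   spacers:  10 (58 bp total, max 32)

pcg_union_length(g)
#> [1] 11342

composition_summary(g$seq, "whole")
#> <composition_summary> whole 16581 bp  A+T 60.3%  AT skew 0.134973  GC skew -0.399301

ctrl <- g$features[g$features$gene_class == "control", ][1, ]
count_tandem_copies(extract_region(g, ctrl), "CGTACACGTG")
#> <repeat_report> motif CGTACACGTG: 9 tandem copies from position 705

classify_haplotypes(make_haplotype_panel(out))
#>   sample          haplotype
#> 1   base unclassified(ACAT)
#> 2     E1                 E1
#> 3     E2                 E2
#> 4     A1                 A1
#> 5     A2                 A2
#> 6     A3                 A3
```

The organization summary reads: 37 genes (28 on the heavy strand, 9 on
the light strand) with nine pairwise overlaps totalling 76 bp (longest
43 bp, between *atp8* and *atp6*) and ten intergenic spacers totalling
58 bp (longest 32 bp); the 13 PCGs cover 11,342 bp of the circle once
overlapping positions are deduplicated (68.4% of 16,581 bp). The
haplotype table shows the five-lineage cytochrome *b* classification
recovering each panel sample's label, while the unmodified base genome
falls outside the five canonical 4-mers.

A phylogenetic run on an alignment:

```r
aln <- read_aligned_fasta("aln.fasta")
tree <- bootstrap_support(aln, replicates = 1000, seed = 42)
tree <- root_with_outgroup(tree, "warthog")
write_newick(tree, "tree.nwk", hide_below = 70)
```

## Command line

```sh
Rscript inst/cli/mitochar.R synth genome --seed 1 --out genome.fasta --annot annot.tsv
Rscript inst/cli/mitochar.R all --genome genome.fasta --annot annot.tsv --out report/
Rscript inst/cli/mitochar.R phylo --aln aln.fasta --outgroup warthog \
    --replicates 1000 --seed 42 --out report/
```

Subcommands: `organize`, `composition`, `rscu`, `repeats`, `variation`,
`haplotype`, `phylo`, `synth`, `all`. A JSON config file can be passed
with `--config`; explicit flags win over file values. Every output file
carries a header line with the package version and a config fingerprint,
and reruns with identical configuration are byte-identical.

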