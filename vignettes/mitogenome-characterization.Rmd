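---
title: "Methods: characterizing a circular mitochondrial genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a circular mitochondrial genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

This vignette is the package's own account of its methods: the models and
conventions each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator emulates
(and deliberately does not), and the numerical choices that make results
deterministic. It states no empirical result that the test suite does not
itself compute.

## 1. The circle and its coordinates

A mammalian mitogenome is a circular molecule of roughly 16.5 kb carrying
37 genes (13 protein-coding genes, 22 tRNAs, 2 rRNAs) and one non-coding
control region (D-loop). `mitochar` represents it as a `circular_genome`:
a nucleotide string plus an ordered feature table with **1-based inclusive**
coordinates, the convention of published gene-organization tables. A
feature whose stop precedes its start *wraps* the sequence origin; the
canonical example is the control region of the packaged pig-like skeleton,
annotated 15,781 → 344 on a 16,581 bp circle, whose length is
`(L − start + 1) + stop = 801 + 344 = 1145` bp. Internal conversion to
0-based half-open coordinates never leaks into the API.

Three deliberate conventions:

* **Printed derived columns are checksums, not inputs.** The annotation
  reader recomputes every gene length from coordinates, because published
  organization tables occasionally carry transcription errors in the
  derived columns (the packaged skeleton's source prints one tRNA length
  as 1042 where the coordinates give 69). Extra columns in the TSV are
  ignored.
* **The intergenic column is a start-order walk.** For consecutive
  features in start order, `intergenic_nt = next.start − prev.stop − 1`;
  negative values are overlaps. The walk includes the circuit-closure pair
  (last feature back to first, measured around the circle). The control
  region participates in adjacency — so the first tRNA's gap is measured
  against it — but is excluded from the strand census, which counts genes
  only (37 = 28 heavy + 9 light on the skeleton).
* **PCG coverage is a union.** Mitochondrial PCGs overlap (on the
  skeleton: 43 + 1 + 7 + 17 bp of intra-PCG overlap), so the summed gene
  lengths (11,410 bp) exceed the positions actually covered (11,342 bp).
  `pcg_union_length()` merges intervals on the circle (wrapping features
  split in two); a brute-force position-set oracle backs it in the tests.

## 2. Composition and skews

`composition_summary()` reports counts, percentages, A+T content and the
strand-asymmetry skews

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

computed on whatever region it is handed (whole circle, one gene 5'→3' on
its coding sense, or a concatenation). `N` bases are excluded from every
denominator; a region with more than 10% `N` additionally triggers a
message. A skew whose denominator is zero is **undefined** and reported as
`NA` — never silently 0, which would claim perfect symmetry. Percentages
are kept at full precision internally; presentation rounding (1 decimal
for percentages, 6 for skews, mirroring the usual table formats) happens
only in report writers. Note that skews recomputed from percentages that
were themselves rounded to one decimal can differ from skews computed on
raw counts by up to about `2 × 0.05 / (x + y)` ≈ 0.0025; the acceptance
tests use exactly that analytic bound when checking published summary
rows.

## 3. Translation, stop completion, RSCU

The genetic code is fixed to NCBI translation table 2 (vertebrate
mitochondrial; AGA/AGG are stops, ATA codes Met, TGA codes Trp), obtained
from `Biostrings::getGeneticCode("2")` rather than hand-rolled.

Mitochondrial PCGs are often annotated with **incomplete stop codons**
completed post-transcriptionally by polyadenylation. Because annotation
gives only the boundary, classification is length-driven: a CDS of length
≡ 1 (mod 3) ending in `T` is `incomplete_T`; ≡ 2 (mod 3) ending in `TA`
is `incomplete_TA`; a final full codon in {TAA, TAG, AGA, AGG} is
`complete`; anything else `none`. An internal stop is flagged in the
result but not fatal — a real annotation with a frame problem should be
visible, not hidden behind an error.

RSCU follows the MEGA convention: for codon $c$ in a synonymous family of
size $k$, $\mathrm{RSCU}(c) = n_c \, k / \sum_{c' \in \mathrm{fam}} n_{c'}$,
with stop codons excluded from families and the family partition taken
from table 2 itself — so Leu and Ser have six codons, and Met is the
two-codon family {ATG, ATA}. An observed family's RSCU values sum exactly
to $k$; an unobserved family is all zeros. Two judgment calls: incomplete
final codons are excluded from the counts (whether published RSCU tables
include them is generally unstated), and the terminal stop codon is never
counted.

## 4. Control-region tandem repeats

`count_tandem_copies()` scores every window of motif length by Hamming
distance to the motif and chains non-overlapping windows spaced exactly
one motif length apart; the reported copy number is the longest such
chain (leftmost on ties), found by a linear dynamic program and verified
against an enumerate-every-run oracle in the tests. Defaults are strict:
**0 mismatches per copy**, because repeat "consensus" motifs in the
literature come without a stated distance rule — the knob is exposed for
degenerate repeats, and copy number is monotone in it. Whole copies only;
a trailing partial copy never counts. Coordinates are local to the region
(1-based); `local_to_genome()` maps them through a wrapping feature onto
the circle.

## 5. Variation and haplotypes

The polymorphism census treats gap and `N` as **missing data, not
alleles**: a column is polymorphic when at least two distinct bases among
{A, C, G, T} occur. This is the standard census convention, and the one a
reader should assume when no gap rule is published. Consequences follow
through: `site_diff()` counts only columns where both rows are
unambiguous, and `variable_fraction()` is simply
`100 × polymorphic / columns`.

Amino-acid substitution mapping translates an in-frame concatenated CDS
alignment row-by-row and reports codon positions where any sample differs
from a named reference row — reference-directed, matching how a focal
genome is compared against a panel. Codons containing missing data
translate to `X` and never count as substitutions.

The cytochrome *b* haplotype classifier reads four diagnostic positions,
joins the bases into a key, and looks the key up:
E1 = TGCG, E2 = TGTG (European); A1 = CATA, A2 = CATG, A3 = TATG (Asian).
The default positions (15,036 / 15,038 / 15,041 / 15,045) are
**reference-relative** — published schemes state them against a specific
reference coordinate system — so the whole scheme is a parameter, not
hard-coded biology. Unknown 4-mers return `unclassified(<key>)` rather
than an error (novel haplotypes are a finding, not a failure); any
missing base returns `incomplete`. Single-site lineage markers use the
same machinery via `site_lookup()`.

## 6. Distances, trees, supports

**TN93.** The Tamura–Nei (1993) distance separates purine transitions
(proportion $P_1$), pyrimidine transitions ($P_2$) and transversions
($Q$) with unequal base frequencies:

$$d = -k_1 \ln w_1 - k_2 \ln w_2 - k_3 \ln w_3,$$

with $k_1 = 2\pi_A\pi_G/\pi_R$, $k_2 = 2\pi_T\pi_C/\pi_Y$,
$k_3 = 2(\pi_R\pi_Y - \pi_A\pi_G\pi_Y/\pi_R - \pi_T\pi_C\pi_R/\pi_Y)$ and
$w_1 = 1 - P_1/k_1 - Q/2\pi_R$, $w_2 = 1 - P_2/k_2 - Q/2\pi_Y$,
$w_3 = 1 - Q/2\pi_R\pi_Y$. Design choices: frequencies are **pooled
empirical frequencies of the pair** over shared usable columns (the
MEGA-compatible choice); ambiguous columns are removed **pairwise**, not
by complete deletion, for robustness on ragged mitogenome alignments; and
a saturated pair (any $w \le 0$) is an explicit *inapplicable* marker
(`NA`), never NaN. With equal frequencies and $P_1 = P_2$ the formula
collapses to Kimura's two-parameter distance, which the tests assert
against the closed form; agreement with `ape::dist.dna(model = "TN93")`
is asserted to 9 decimals.

**Neighbor joining.** Saitou–Nei agglomeration with the Studier–Keppler
criterion $Q(i,j) = (n-2)\,d_{ij} - r_i - r_j$. Ties in $Q$ break to the
smallest index pair in the current ordering, making the output a
deterministic function of the matrix. Negative branch lengths are kept as
computed (with a message) so that recovery of additive matrices is exact
— the tests demand the input path-length matrix back to 1e-8 for up to 8
taxa — with an optional clamp for display. The final three lineages are
resolved by the three-point formulas.

**Bootstrap.** Columns are resampled with replacement; each replicate's
resample is a pure function of `(seed, replicate)`, so runs are
bit-reproducible and replicate order is irrelevant. Supports are the
percentage of valid replicate trees containing the same leaf bipartition
(canonicalized against the first taxon, so taxon order cannot matter).
Replicates hitting a saturated distance are dropped and counted; more
than 10% dropped is an error, because supports from a heavily-censored
replicate stream would be quietly biased. Supports are attached as
rounded-integer node labels (the usual figure convention, including the
optional "hide below 70" display rule in `write_newick()`); full
precision is kept in an attribute. Outgroup rooting delegates to
`ape::root(edgelabel = TRUE)` so labels stay with their bipartitions.

## 7. The synthetic world

`synth_spec()` fixes the generator's stated world: the packaged 37-gene
coordinate skeleton on 16,581 bp; H-strand base composition targets
A 34.0 / C 27.8 / G 11.9 / T 26.3 %; a 10 bp control-region repeat motif
(`CGTACACGTG`) in 9 tandem copies starting at local position 705; start
codons ATG everywhere except GTG on *nad4l* and ATT on *nad2* (a
published "ATN" start had to land on one gene; *nad2* is the package's
single arbitrary choice); and incomplete stops on *nad1*, *nad2*, *cox2*,
*cox3*, *nad3*, *nad4* — the six-gene configuration typical of Asian
wild-boar mitogenomes. None of these defaults is tuned per run.

Generation proceeds in phases, all from one seed:

1. background bases are drawn from the target composition;
2. PCG interiors are filled codon-wise — amino acids from a pig-like
   usage table (Leu ≈ 15%, Cys rarest at ≈ 0.7%), codons within each
   family weighted by the product of target base frequencies over the
   three positions, which produces the A/T third-position bias;
3. start codons, then stop codons (or `T`/`TA` tails) are written and
   **locked**; a stop codon overlapping an already-locked position is
   chosen from {TAA, TAG, AGA, AGG} compatibly (e.g. the *atp6* stop must
   end in the first base of the *cox3* start);
4. a repair pass removes internal stop codons by single-base edits that
   are checked against **every** overlapping gene's reading frame on
   either strand before being accepted — this is what keeps the 43 bp
   *atp8*/*atp6* overlap and the antiparallel *nad5*/*nad6* overlap
   simultaneously ORF-clean;
5. the repeat run is stamped into the control region;
6. all remaining free positions are redrawn from the *residual*
   composition (target totals minus what the fixed positions already
   contain), so the genome-wide composition hits the target in
   expectation — multinomial noise at this length is ±0.35 points, and
   the tests assert ±1.

What the generator does **not** emulate: real pig codon usage beyond base
composition, indels, heteroplasmy, repeat-unit degeneracy, or sequencing
error. A green test therefore establishes that the *accounting and
inference machinery* is correct against known truth — not that any
biological claim about real populations holds. Real-data analyses run the
same code paths on user FASTA/TSV/alignments.

`simulate_alignment()` evolves sites independently down a tree under TN93
(stationary frequencies + two transition multipliers, rate matrix
normalized to one expected substitution per unit branch length, transition
probabilities by eigendecomposition). It supports the estimator-recovery
and clade-support acceptance tests: an 8-taxon, two-clade tree with a
deep internal branch yields the expected monophyletic split with ≥ 90%
bootstrap support at 200 replicates — the qualitative "two clades" result
restated at the scale that synthetic data can literally test. Simulation
scales (5,000 columns, 200 replicates rather than full mitogenomes and
1000 replicates) were set for desk runtime; the API defaults keep 1000
replicates for real analyses.

## 8. The end-to-end run

`run_characterization()` wires the stages behind one `run_config`:
genome + annotation in, a directory of TSVs and a Newick tree out.
Configuration is a JSON file plus programmatic/flag overrides (flags
win); JSON was chosen over YAML because the JSON reader is a hard
dependency of the package anyway. Outputs are a pure function of
(inputs, config, seeds): every file opens with the package version and a
config fingerprint (FNV-1a over the canonical JSON serialization,
excluding the output directory), and reruns are byte-identical. A
configuration that cannot run — the phylogenetics stage without an
alignment, a missing input path — fails before any stage executes.

## 9. Known limitations

* No annotation inference from raw sequence (use MITOS/tRNAscan-SE class
  tools upstream), no multiple sequence alignment (alignments are
  inputs), no maximum-likelihood or Bayesian trees, no gamma-rate TN93
  variant, and no tRNA secondary-structure prediction.
* The haplotype scheme's default positions assume the classic reference
  coordinate system; on a different alignment the positions must be
  re-anchored by the caller.
* NJ is quadratic per join and the bootstrap rebuilds the full distance
  matrix per replicate; fine for the tens of taxa typical of mitogenome
  studies, not for thousands.
* The tandem-repeat counter counts a given motif; it does not discover
  unknown repeat units (TRF-style discovery is out of scope).
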