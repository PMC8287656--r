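---
title: "Models and conventions in mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions in mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope

`mitocomp` is a desk-scale toolkit for comparative analysis of annotated
fungal mitochondrial genomes: base composition and strand skews, per-gene
Kimura 2-parameter (K2P) distances with a neighbor-joining utility,
Nei–Gojobori (1986) Ka/Ks with positive-selection flagging, group-I intron
position classes (Pcls) mapped onto a reference coding sequence, circular
gene-order comparison with a signed breakpoint statistic, repeat and
tandem-repeat accounting, cohort summary tables, and a size-versus-intron
correlation. Annotations are consumed from GenBank flat files; the package
performs no read QC, assembly, or de-novo annotation, and no ML/Bayesian
phylogenetics.

Because the analyses target ~20–200 kb organellar genomes, everything runs
in plain R on one core. A deterministic synthetic-genome generator with a
ground-truth manifest makes every stage verifiable without downloads; the
test suite and `scripts/acceptance.R` are built entirely on it.

## Data model and coordinates

A `MitoGenome` holds one circular (or linear) uppercase ACGTN sequence plus
typed features (core PCG, rRNA, tRNA, intronic ORF, plasmid-derived ORF,
unknown ORF) and intron intervals. Coordinates are 1-based inclusive
externally, following GenBank. Exons are stored in coding order; for
minus-strand genes the spliced CDS is the reverse complement of the exons
read 3'→5' in genome coordinates, which is exactly how
`complement(join(...))` locations are resolved. Features spanning the
circular origin are not supported in v1: genomes are expected rotated so no
feature wraps (the generator always emits them that way). Ambiguity codes
other than N are rejected; N is carried but excluded from composition
denominators. Intron features absent from a record are inferred as the gaps
between consecutive CDS exons of the same gene.

Translation uses NCBI table 4 (mold/protozoan mitochondrial; TGA = Trp)
throughout, configurable per call. The paper trail for basidiomycete
mitogenomes supports table 4, but nothing in the code depends on the choice
beyond the codon tables.

## Composition and skews

AT skew = (A − T)/(A + T), GC skew = (G − C)/(G + C), GC content =
(G + C)/(A + C + G + T); N never enters a denominator and a zero
denominator yields NA rather than 0. `skew_profile()` evaluates the same
statistics in sliding windows, wrapping across the origin on circular
sequences so every base is covered equally. Reports round GC% to two
decimals; internal values keep full precision.

## K2P distances and neighbor joining

`pairwise_k2p()` removes columns where either sequence has a gap or N
(pairwise deletion — the common MEGA-style default), computes transition
and transversion fractions P and Q over the retained columns, and returns
d = −½·ln[(1 − 2P − Q)·√(1 − 2Q)]. A non-positive log argument means the
pair is saturated and the distance is reported as missing, never clamped
to a sentinel. Per-gene matrices are built on protein-guided codon
alignments (below), so only homologous codon columns are compared; gene
absent in a taxon gives NA, not 0, and per-gene means use available pairs.

`neighbor_joining()` is the canonical Saitou–Nei agglomeration with two
pinned conventions: ties in the Q-criterion resolve to the pair with the
lowest indices, and a negative branch length is clamped to zero with the
deficit moved to its sister so path lengths are preserved. The tree is
returned as an unrooted Newick string with a trifurcating root. This is a
light-weight utility for distance-level sanity checks, not a substitute
for likelihood phylogenetics.

## Codon alignment

`codon_align()` translates both CDS (dropping terminal stops), aligns the
proteins globally (Needleman–Wunsch, BLOSUM62, affine gaps with opening 10
and extension 0.5 — Biostrings defaults for this setting), and threads the
alignment back to nucleotides. Columns containing gaps, ambiguity, or
non-terminal stops are removed. The same alignment supplies the
nucleotide-level coordinate map used for intron position mapping. Exact
parity with any published aligner's output is not claimed; the conventions
are fixed and test-pinned.

## NG86 Ka/Ks

For each sense codon, the synonymous site fraction at each position is the
number of synonymous single-nucleotide changes divided by the number of
changes that do not create a stop codon, so s + n = 3 exactly per codon.
Differences between codon pairs are averaged over all minimal mutational
pathways (2 orderings for two differences, 6 for three); pathways crossing
a stop codon are excluded, and if every pathway crosses a stop the average
falls back to all pathways (a message is emitted — the original method is
ambiguous here, so the choice is documented and pinned by tests).
Proportions use site counts averaged over the two sequences,
S̄ = (S_a + S_b)/2, and receive the Jukes–Cantor correction
−¾·ln(1 − 4p/3). Undefined corrections (p ≥ 3/4) and Ks = 0 give a missing
ratio; uncorrected proportions are also reported (`ka_raw`, `ks_raw`)
because the upstream software convention is unstated. `positive_selection`
is flagged when Ka/Ks > 1. The whole pipeline is checked against an
independent brute-force enumeration (no shared code) to 1e−9 in the
acceptance suite.

## Intron position classes

An intron's position class is the 1-based nucleotide coordinate, on the
spliced reference CDS, of the last aligned query nucleotide 5' of the
exon junction, named `P<position>` (e.g. P383). Offsets landing in
reference gaps map to the nearest 5' non-gap position. Two conventions are
pinned rather than guessed: positions count from the reference start codon
as position 1 on the spliced CDS, and Pcl identity is exact position
(merge window 0) by default, configurable. Alignment support is the
fraction of identical nucleotides in a ±15 nt window around the mapped
site; a whole-gene amino-acid identity below a configurable floor (default
0.30) marks all of that genome's assignments low-confidence. Note that
global alignment of unrelated proteins already yields ~0.3 background
identity, so the default floor only catches outright garbage — raise it
for strict screening.

A Pcl present in strictly more than 1/5 of the species panel is *common*,
otherwise *rare*; prevalence of exactly n/5 is rare. `flag_disjunct_pcls()`
reports classes present in exactly one member of a focal clade but in at
least one other clade — the distribution pattern that suggests horizontal
intron transfer. The reference CDS is supplied by the user (a FASTA); no
reference sequence is bundled, keeping the package download-free.

## Circular gene orders

Orders are taken over a 17-gene panel (15 core PCGs + rns + rnl; tRNAs
excluded, panel configurable) in order of start coordinate. Canonical form
rotates cox1 to the front and, if cox1 lies on the minus strand, reflects
the order and flips all strands; with cox1 absent the lexicographically
smallest symbol anchors. Two orders are identical iff their canonical
forms match on the intersection of present genes. The breakpoint distance
counts orientation-aware circular adjacencies of one order missing from
the other; it is zero exactly for identical orders and is a metric on
canonical orders with equal gene sets. A gene is *rearranged* relative to
an ancestor when its unordered pair of neighbours (symbols with strands,
in canonical orientation) differs — so an inverted block flags its
interior and flanks, a moved gene flags itself, its old flanks and its new
flanks. This neighbour rule is this package's operationalization of
figure-level rearrangement calls in the literature; it is pinned by tests,
not claimed to reproduce any particular figure cell-for-cell.
`majority_ancestor()` returns the plurality arrangement and refuses ties.

## Repeats

`find_duplications()` is a deterministic seed-and-extend self-alignment:
11-mer seeds, ungapped x-drop extension with +2/−3 scoring, and
Karlin–Altschul E-values with fixed constants (λ = 0.625, K = 0.41 — the
published gapped-blastn values for this scoring). Parity with any NCBI
BLASTN build is explicitly not claimed; what is preserved is the
threshold semantics (default E < 1e−10) and determinism. Trivial
self-hits, mirror duplicates and overlapping self-matches are removed;
hits sharing ≥ 50% of the shorter interval merge, keeping the lower
E-value. With these constants an exact duplication must be ≥ ~34 bp to
clear E < 1e−10 in a 12–44 kb genome, comfortably below the 39–52 bp
range of interest. The same engine powers `cross_genome_fragments()`.

`find_tandem_repeats()` is a deterministic period scan, not a Tandem
Repeats Finder port: for each period p the match vector s[i] = s[i+p] is
run-length encoded; runs spanning a full period seed a greedy extension
that absorbs neighbouring runs while overall identity stays ≥ 80% and
gaps stay ≤ p. Arrays are reported once at their smallest qualifying
period, with copy number (run + p)/p, default minimum total length 11 nt
(i.e. > 10 bp) and ≥ 2 copies. In AT-rich mitochondrial sequence this
detector reports many short genuine microsatellite-like runs; filter on
total length or period downstream if only long arrays are wanted.
`repeat_fraction()` is the exact interval union (no double counting) as a
percentage of genome length.

## Cohort table and correlation

`comparative_table()` partitions every base of each genome into exactly
one of four classes with the priority intron > coding > RNA > intergenic,
so the percentages sum to 100. Intronic-ORF bases therefore count as
intronic; the alternative convention (counting them as coding) is reported
in a separate column because published percentages rarely state the rule.
`correlate_size_intron()` returns the Pearson product-moment r with the
exact two-sided t-test p-value and the Spearman rank rho (average ranks
for ties) with the usual t approximation — closed forms, no resampling.

## The synthetic world

The generator's defaults state the world the package is verified in: a
44,000 bp circular genome, GC 0.23, AT skew −0.03, GC skew +0.05 (the
paper trail for the target clade reports GC ≈ 22–23%, negative AT skew,
positive GC skew; the skew magnitudes are this package's choice since only
signs are published), the 17-gene panel with realistic per-gene lengths
(rnl 3,768 nt and rns 1,973 nt match reported means), 26 placeholder
tRNAs, and four group-I introns — three in cox1 at reference offsets 383,
717 and 1,107 (echoing the P383/P717/P1107 classes reported in
basidiomycetes) and one in cob — with one intronic ORF.

Background sequence is drawn per-base; coding sequence is drawn per-codon
from the product distribution with stop codons excluded. Excluding stops
enriches coding GC slightly, so the background base probabilities are
compensated analytically so the genome-wide expectation still hits the
targets; realized GC lands within ±0.5 percentage points at 44 kb
(≈ 2.5 binomial standard deviations — this is the verification band, not
a tuned number). Randomness is split into named substreams derived from
the master seed (genes, tRNAs, introns, repeats, spacers, mutations), so
planting one feature never shifts another's draws, and identical
seed + spec gives byte-identical output.

`mutate_genome()` applies substitutions only (no indels): inside CDS,
single-nucleotide changes are drawn to hit the per-gene synonymous and
nonsynonymous targets in expectation (Poisson counts over NG86 site
totals, transition:transversion weight κ = 2 by default) and never create
stops; elsewhere, a uniform per-site process applies. Cohorts share one
set of ancestor parts, so descendants are genuinely homologous; per-genome
gene-order edits (adjacent swap, block inversion, move) and per-genome
intron subsets (a planted Pcl presence table) are recorded in the
manifest as ground truth.

What the generator does *not* emulate — and hence what a green test does
not establish: realistic codon usage or among-site rate variation (draws
are i.i.d.), indels and alignment ambiguity beyond planted clean indels,
tRNA sequence realism (placeholder intervals only), features wrapping the
circular origin, introns in minus-strand hosts (the parser supports them;
the generator refuses to plant them), degenerate/nested repeats, and any
phylogenetic tree structure beyond star-like divergence from one ancestor.
Agreement with the brute-force oracles is evidence of implementation
correctness, not of biological fidelity.

The correlation-calibration check runs on a statistical cohort simulator
(`simulate_size_intron_cohort()`: bivariate normal at the generating r,
sizes and counts rounded, counts floored at 0 with negligible truncated
mass) rather than on thousands of full synthetic genomes — the quantity
being calibrated is the correlation statistic, and full-genome synthesis
at 1,000 replicates would add hours of runtime and no information.

## Numerical choices and degenerate inputs

Saturated K2P pairs, undefined Jukes–Cantor corrections, zero-variance
correlations and skews with empty denominators all return NA with a
warning where actionable — never a clamped or sentinel value. NJ requires
a complete matrix and tells the user to impute or drop taxa otherwise.
Report tables are written with fixed column order, tab separation and 6
significant digits, and inputs are sorted by genome id, so reruns are
byte-identical regardless of argument order. All seeds are plain 32-bit
integers fed through R's default generator via isolated substreams.

## Known limitations

GenBank ingestion covers the feature subset relevant here (gene, CDS,
tRNA, rRNA, intron; join/complement locations) — not the full flat-file
grammar (no trans-splicing, no external references in locations). The
duplication engine is ungapped, so diverged repeats interrupted by indels
are reported as fragments. The tandem detector's greedy extension is
deterministic but order-dependent at the margins of the 80% identity
band. Pcl mapping inherits any ambiguity of the underlying protein
alignment near the insertion point; the ±15 nt support score is the
intended diagnostic.
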