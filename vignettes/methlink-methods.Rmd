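---
title: "Methods: from sequencing kinetics to three-level co-occurrence"
author: "methlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sequencing kinetics to three-level co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
```

# The problem this package addresses

Small free-living bacteria with streamlined genomes can reshape their DNA
methylation pattern within a single growth experiment, and those changes may
co-occur with transcript- and protein-level expression shifts.  `methlink`
implements the full analysis chain for such a study in one tested package:
calling N6-methyladenine (m6A) and N4-methylcytosine (m4C) sites from
single-molecule sequencing kinetics, locating them relative to genes and
bipartite restriction--modification recognition motifs, testing transcript
and proteome contrasts, joining the three levels into co-occurrence
summaries, and running two auxiliary genome-scale computations
(nearest-neighbor duplex-stability profiles and a Ka/Ks purifying-selection
screen over ortholog pairs).

The coordinate frame is 0-based and half-open on the forward strand
throughout; exported GFF3 converts to 1-based inclusive.  Genomes are
treated as circular by default, so motif windows, gene bodies and upstream
windows may wrap across the origin; a single internal frame avoids
off-by-one drift between modules.

# Kinetic modification calling

Single-molecule sequencing measures the interpulse duration (IPD) between
base incorporations; methylated template bases delay the polymerase, so the
ratio of a sample's IPD to an unmethylated control at the same position and
strand is the detection signal.  `call_modifications()` emits a call when
three conditions hold: the base is adenine or cytosine (the two
modification chemistries detectable this way at ordinary coverage), the
per-strand coverage strictly exceeds `min_coverage_per_strand` (default 25,
a strict reading of a ">25x per strand" requirement), and the IPD ratio
reaches `min_ipd_ratio`.

The ratio default of 2.0 deserves a note.  Kinetic pipelines bury their
detection threshold inside modification-QV machinery and publish no single
ratio cutoff; 2.0 is a common heuristic for m6A-class signals at moderate
coverage.  It is configurable, echoed into every output header, and the
calling function is monotone in both thresholds (raising either never adds
calls), which the suite asserts.  Control IPDs are supplied per record
(two-sample design); a single-sample mode accepting a per-base expected-IPD
table exists but is not the default, because a measured control is the
cleaner contrast.

# Motif scanning and the methylome census

Type I restriction--modification systems recognise bipartite split motifs;
the default here is the 16-nt degenerate pair `CTAYNNNNNNNNTRTC` /
`GAYANNNNNNNNRTAG` (reverse complements of one another), methylated at the
adenine at offset 2 of the first written form.  `scan_motif()` matches
IUPAC patterns through `Biostrings` with three conventions chosen for
censuses rather than for speed:

* every matching window is reported, including overlaps (degenerate
  patterns legitimately overlap);
* genomic `N` never satisfies a non-N pattern code, so gap regions cannot
  produce phantom hits;
* on circular genomes, wrap-spanning windows are found and counted exactly
  once.

Because the two written motifs are each other's reverse complement, a
forward-strand scan for both patterns and a both-strand scan for one
pattern describe the same physical sites.  Published motif counts rarely
say which convention they use, so `motif_census()` reports both, plus a
strand-deduplicated window count.

`summarize_calls()` uses both-strand denominators: a genome of length $L$
without Ns has exactly $L$ adenine-or-cytosine sites across the two strands
(every base pair contributes one A or one C), an identity the suite
asserts and which makes the published site-percentage arithmetic
reproducible from the genome length alone.

# Feature assignment

`assign_sites()` categorises each call as `gene_body` (inside any gene's
span), else `upstream500` (inside the fixed window 5' of any gene's start,
strand-aware), else `intergenic`.  Three deliberate choices: the call's own
strand is ignored (a methylation on either strand of a gene's span counts
for that gene); upstream windows are full fixed windows, never truncated at
a neighbouring gene; and when a call sits in one gene's body and another's
upstream window the category is `gene_body` but both genes appear in the
locus-tag detail, so pooled body-or-upstream statistics are unaffected by
the precedence.  Published per-gene methylation percentages are ambiguous
between body-only and body-or-upstream counting, so
`percent_genes_methylated()` returns both.

# Expression statistics

Transcript contrasts use the unequal-variance (Welch) t-test on log2
intensities with the raw `p < 0.05` rule, matching the stated array
pipeline; BH q-values are attached for reference.  Proteome tables are
log2-transformed and missing values are imputed with the single lowest
observed log2 intensity in the matrix ("the lowest intensity", singular,
read as one global value; a per-sample mode is available), then tested with
a two-sample t-test under Benjamini--Hochberg control at `q < 0.05`.  The
proteome test defaults to Welch for robustness; a strict Student option
preserves the literal equal-variance reading.

One calibration fact matters when interpreting the null simulations: with
three replicates per group the Satterthwaite approximation is conservative,
so the Welch test's empirical type-I error at the 0.05 cutoff sits below
0.05 (the equal-variance Student test is exact there).  The acceptance
script measures this rate honestly on a 2,000-gene null; readers should
expect a value near 0.035 rather than exactly 0.05.

# Three-level integration

`build_trilevel()` joins, per gene: methylation counts by modification type
and region for the treatment condition, the transcript contrast and the
protein contrast against the control.  Genes absent from an assay are
marked absent, never zero.  `co_occurrence_summary()` then reports the
fraction of genes down- (or up-) regulated while methylated under both
candidate denominators (all genes, methylated genes — published phrasing
does not disambiguate them), the fraction traceable at all three levels
(methylated, transcript-significant and protein-significant in the same
contrast), and up/down fractions among methylation-associated DE genes
split by level and modification type; within each such cell group the up
and down fractions sum to 1 by construction.  Methylation deltas between
conditions are positional (same coordinate, strand and type), while
co-occurrence is gene-level, mirroring how count tables and gene plots
differ in this kind of study.

# Duplex-stability profiles

`duplex_dG37()` sums unified nearest-neighbor stack free energies
($\Delta G^\circ_{37}$, 1 M NaCl) plus terminal initiation terms and the
self-complementary symmetry correction; `window_profile()` averages stack
values over genome windows (default 100 kb, non-overlapping tiles; a
sliding mode exists because "scanning window" phrasing is ambiguous, and
tiling matches the visible resolution of published circular maps).  The
parameter set ships as a versioned plain-text table
(`inst/extdata/nn_unified_1M_NaCl.tsv`) so it can be audited or replaced;
the loader validates complementary-stack symmetry.  Signed
$\Delta G^\circ_{37}$ is stored internally; exporters negate on request for
"melting energy" plots.  Melting temperatures use
$T_m = \Delta H / (\Delta S + R \ln(C_T/x)) - 273.15$ with $x = 4$ for
non-self-complementary duplexes and $x = 1$ for self-complementary ones.

# Ka/Ks estimation and the selection screen

`kaks_pair()` implements NG86-class counting: fractional synonymous-site
counting per codon with mutations to stop codons excluded from each
position's denominator (so S + N = 3 per codon), equal-weight averaging
over minimal mutational pathways for multi-difference codons with
stop-crossing pathways excluded (all pathways used only if every one
crosses a stop), Jukes--Cantor correction
$K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, and a two-tailed Fisher exact
test of Ka $\ne$ Ks on the rounded site/difference table.  The published
analysis used a gamma-corrected approximate method and a model-averaged ML
method inside an external calculator; those carry unspecified
rate-heterogeneity machinery, whereas NG86 counting is fully specifiable
and the screen's deliverable — discriminating purifying from neutral
evolution — is robust to that substitution.  The genetic code defaults to
the standard table (identical to the bacterial table for codon-to-amino-acid
assignments) and is configurable.

`filter_pairs()` removes pairs with fewer than three substitutions or
Fisher p above 0.05.  The published removal sentence is ambiguous between
AND and OR; remove-if-either is the default (each removal carries a reason
tag) with a strict-AND option.  One consequence worth stating: the
significance filter is itself a neutrality test, so a truly neutral gene
set is mostly *removed* rather than misclassified — the package's neutral
simulation control therefore brackets 1 on unfiltered pairs, while the
purifying screen applies the full filters.

# The synthetic-data module

Every input format the pipeline reads can be generated with planted,
machine-readable truth under a single integer seed (`methylome_scenario()`
plus `generate_*()`; same seed, byte-identical outputs).  The default
desk-scale scenario is a 200-kb circular genome with 200 genes, 20 planted
motif instances and 3 replicates per condition across three conditions (a
control, a cold treatment, a UV treatment), chosen to preserve the
statistical structure of a small-bacterium three-treatment study while
running end to end in well under a minute.  Specific emulation choices:

* gene lengths are normal (mean 400 bp, floor 100 bp) laid out sequentially
  with Poisson intergenic gaps — dense prokaryotic architecture without
  infeasible-packing pathologies;
* motif sites are methylated with per-condition probabilities (0.97 for the
  control and cold conditions, 0.92 under UV); genes carry background
  body/upstream sites with per-condition probabilities (0.25 / 0.21 / 0.16)
  and strictly intergenic sites are planted separately, so the
  in-gene-or-upstream fraction of sites is a planted quantity near one half;
* kinetics: lognormal control IPDs, a 4x case multiplier at methylated
  positions, 10% multiplicative noise, Poisson coverage around a
  per-condition mean drawn from 54--70x.  At these defaults the separation
  is effectively deterministic (recall and precision 1), which is what
  makes exact planted-truth recovery assertable; overlap regimes are
  exercised by lowering the multiplier or coverage;
* expression: per-gene baselines (log2 mean 10, sd 1.5), replicate noise
  0.25 log2 units, DE status drawn conditional on planted methylation
  (P(down|methylated) = 0.62, P(up|methylated) = 0.17 against background
  rates 0.04/0.08), effect sizes |log2FC| ~ N(2, 0.5).  The conditional
  probabilities were chosen once so that the implied fractions of genes
  that are methylated-and-down and the down-fraction among
  methylation-associated DE genes sit in the ranges such studies report;
* proteome: transcript effects attenuated by 0.8 with extra noise and
  missing-not-at-random dropout, logistic in log2 intensity
  (P(missing) = plogis(1.2 (7 - x))), giving a realistic few-percent
  missingness concentrated at low intensity;
* ortholog pairs evolve from a random sense-codon ancestor by per-site
  single-base proposals (Poisson count, rate = branch length per codon).
  A proposal is drawn uniformly among the position's viable (non-stop)
  mutants, accepted always if synonymous and with probability omega
  otherwise.  Drawing among viable mutants (rather than rejecting stops
  after a uniform draw) keeps the simulator's synonymous/nonsynonymous
  opportunity ratio aligned with the per-position site normalisation of
  the counting estimator; with post-hoc rejection the estimator shows a
  systematic upward bias of about 10% at omega 0.2--0.5, with this scheme
  deviations are sampling noise.  This acceptance--rejection scheme is a
  simulator approximation: it discriminates omega regimes without full
  codon-model matrix exponentiation.

What the generator does **not** emulate: probe-level microarray artefacts
and normalisation, MS1 feature extraction and shared-peptide effects,
read-level sequencing errors, context-dependent kinetic signals,
transcription units/operons, or phylogenetic structure beyond a single
pairwise branch.  Passing recovery tests therefore demonstrates
correctness of the statistical chain under the stated generative
assumptions, not robustness to those real-data complications.

# Numerical and degenerate-input conventions

Zero-variance groups with equal means give p = 1 (and p = 0, flagged
degenerate, with unequal means), which is what makes noise-free planted
data exactly recoverable.  Empty assignment sets raise an error rather than
returning 0/0; undefined ratios (zero minus-strand calls, zero control
counts, Ks = 0, saturated Jukes--Cantor inputs) are returned as `NA` with
explicit `defined`/`saturated` flags, never silently as zero.  Windows
whose N fraction exceeds a configurable mask threshold are masked rather
than averaged over fewer stacks without notice.  BH adjustment follows its
p-values under permutation, asserted as a property.

# Problem sizes used by the checks

The test suite runs the full synthetic pipeline at a 50-kb / 60-gene
scenario, brute-force comparisons at 3--8 kb, a 1-Mb random genome for the
motif-rate law, estimator-consistency runs totalling 30k codons per omega,
and 1,000--2,000-gene null simulations; the acceptance script uses 50
ortholog pairs of 1,000 codons and a 2,000-gene null, the sizes at which
the corresponding claims are stated.  The reference-genome motif census
requires the published chromosome (about 2.2 Mb), which is not
redistributed with the package; the corresponding check looks for a local
copy under `tests/testthat/` and fails with instructions when absent.  The
site-percentage arithmetic, by contrast, depends on the genome only through
its both-strand A+C denominator — its length — and therefore runs on a
synthetic stand-in of the published length, labelled as such.

# Known limitations

Methylation-fraction estimation (partial methylation per site) is out of
scope, as are operon inference, promoter discovery, array normalisation,
MS search internals, codon-model maximum-likelihood Ka/Ks variants, and
causal claims about methylation driving expression: the package computes
co-occurrence, and the direction of any mechanistic arrow is for
experiments, not this code, to establish.
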