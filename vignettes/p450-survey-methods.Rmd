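---
title: "Methods: genome-wide P450 family surveys with p450tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide P450 family surveys with p450tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p450tools)
```

This vignette records the models behind each stage of the pipeline, the
parameters that matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer would want written down.

## Candidate identification

Cytochrome P450s are diagnosed by four conserved regions. Three have
published A-type / non-A-type consensus pairs (heme-binding
`PFGXGRRXCXG`/`XFXXGXRXCXG`, PERF `FXPERF`/`FXPXRX`, I-helix
`AGXDT`/`AGX[D/E]T`); each A-type consensus is a strict special case of
its non-A counterpart, which is why `classify_type()` tests A-type
first — otherwise every A-type protein would also satisfy the non-A
pattern and the split would be vacuous. The K-helix region has no
published variant split; we default to the canonical `EXXR`, exposed in
`signature_patterns(khelix = )`. In a consensus, `X` means any of the 20
residues (or `X` itself) and `[D/E]` exactly D or E — a literal reading
of the printed patterns.

`screen_candidates()` preserves the two-evidence structure of
HMM-plus-BLAST identification without external binaries: a candidate
needs *domain-type* evidence (≥1 signature region by default, or an
ingested `hmmsearch --domtblout` row at E ≤ 1e-10) *and* *similarity*
evidence (an ingested DIAMOND/BLAST tabular row at E ≤ 1e-10, or global
identity ≥ 30 % over ≥ 150 aligned residues to any reference P450).
Fragments under 100 residues are removed. E-values cannot be recomputed
without the external tools, so the internal similarity route is an
identity floor rather than an E-value — the *intersection* of two
independent evidence types is what is preserved. Both thresholds are
config. Note that the short `EXXR` K-helix consensus matches a random
~400-residue protein about once by chance, so on real data the domain
criterion is effectively carried by the three long motifs plus
similarity; decoys in the simulator are scrubbed of all four regions so
the screen's discrimination is tested at the rule level.

Molecular weight uses average (not monoisotopic) residue masses plus one
water; `X` contributes the mean residue mass. The isoelectric point
solves net charge = 0 under a Henderson–Hasselbalch model (free termini;
D, E, C, Y acidic; H, K, R basic) with the EMBOSS pKa set, by bisection
to 1e-4 pH — tighter than the 0.01 pH that would suffice for reporting,
so that the net charge at the reported pI is within 1e-3 of zero.

## Nomenclature tiers

Family naming follows the identity conventions of P450 nomenclature:
strictly more than 40 % identity to a named reference places the query in
that family, more than 55 % in the subfamily, more than 95 % makes it an
allelic variant; at or below 40 % the call is `NEW_FAMILY`. The
thresholds are strict inequalities because the conventions say "more
than" / "exceeds". Identity is computed as identical columns divided by
alignment columns after trimming terminal-gap columns, under a global
Needleman–Wunsch alignment (Gotoh affine gaps, BLOSUM62, gap open 10,
extend 1). We use percent *identity* rather than a scoring-dependent
similarity because it is reproducible across substitution matrices; the
thresholds are config for users who prefer another convention.

Determinism choices: the traceback prefers diagonal, then the gap
consuming the first sequence, then the other; and each pair is aligned in
a canonical orientation (lexicographically smaller sequence first) so
identity is exactly symmetric. Best-reference ties break by higher
aligned length, then lexicographic reference id.

Tree-based clan confirmation is out of scope; instead the clan is
inherited from the best reference, and a message is emitted when the top
three references *above the family threshold* disagree on clan —
disagreement is surfaced, never silently resolved. A ten-clan, 48-family
clan↔family map ships with the package (`clan_family_map()`); placements
for the multi-family CYP72/CYP85/CYP86 clans follow the standard plant
P450 clan tables.

## Genome context

The cluster rule is our operationalisation (the underlying literature
reports clusters without defining them): a cluster is a maximal run of
≥ 3 family-assigned genes in which adjacent members are separated by at
most 10 non-member genes *and* at most 200 kb. Both limits are config
(`cluster_config()`), and unassigned genes never seed or join clusters.
Intron phase is defined on CDS (not UTR-containing exons) as the
cumulative upstream CDS length modulo 3, matching the usual 0/1/2 phase
labels in gene-structure figures.

## Duplication modes

Collinear blocks are chains of anchor pairs (all-vs-all identity ≥ 0.40)
whose gene ranks are strictly monotone on both chromosomes, with rank
gaps ≤ 25, found per chromosome pair and orientation by
longest-chain dynamic programming; chains need ≥ 5 anchors. Chains are
extracted best-first (longest; ties prefer the `same` orientation, then
the lexicographically smallest anchor sequence), and each anchor belongs
to at most one block — this determinism is what lets the test suite
compare the DP against exhaustive chain enumeration exactly.

Modes follow the DupGen_finder-style precedence WGD > TD > PD > TRD >
DSD: block anchors are WGD; same-chromosome adjacency is tandem;
≤ 10 intervening genes proximal; a pair with exactly one member inside
any collinear block is transposed; the rest dispersed. Proper transposed
calls normally date ancestral loci with outgroup genomes; with a single
genome we substitute "membership in any intra-genome collinear block" for
ancestral status and record that simplification here and in the output
evidence strings. All-vs-all anchor discovery uses a shared-6-mer
prefilter (≥ 8 exact shared 6-mers before paying for an alignment);
random unrelated proteins essentially never reach the bar, while
duplicates above ~60 % identity always do. The prefilter is a speed
heuristic, off-switchable, and is disabled for the small within-family
pair search where the 0.40 floor must be exact.

## Ka/Ks

The estimator is Nei–Gojobori (1986) with Jukes–Cantor correction. It is
fully enumerable: per-codon synonymous site fractions come from the nine
single-base mutations of each sense codon; mutations that would create a
stop codon are excluded from the denominators by default (a config
switch counts them as nonsynonymous instead); sites are averaged over
the two sequences; multi-substitution codons average their observed
synonymous/nonsynonymous steps over all orderings of the single-base
changes with equal weights, discarding orderings that pass through a
stop. Proportions at or above 3/4 are flagged `saturated` and the
corresponding estimate left undefined — saturated pairs are surfaced,
not clipped. Maximum-likelihood and approximate-method estimators (GMYN,
YN00, codeml) are deliberate non-goals: the enumeration-based NG86 can
be verified codon-by-codon against an independent oracle, which the test
suite does for all 61 sense codons.

WGD-mode pairs with Ks in the inclusive window [0.15, 0.30] are flagged
as descendants of the recent whole-genome duplication; the window is
config (`evolution_config()`).

## Expression and the metabolite screen

FPKM is `counts × 10⁹ / (gene length × library size)`, with optional
averaging of replicates after normalisation. The candidate screen first
removes genes whose *maximum* stage FPKM is below 10 — the maximum, not
the mean, so a gene strongly expressed in one stage survives; the mean
is a config alternative. Stage 1 then keeps genes whose Pearson
correlation with the total-flavonoid series is significant (two-sided
p < 0.05 from t = r·√((n−2)/(1−r²)) on n−2 df); stage 2 repeats the test
against the component-sum series; candidates are the intersection. Raw
p-values are the decision criterion (mirroring the two-sided p < 0.05
convention of such screens); Benjamini–Hochberg q-values are reported as
extra columns for reference only. A constant expression vector is an
error upstream but is reported as NA within the screen (the gene simply
cannot be a candidate), never a silent NaN.

Retention mechanisms are a quantitative reading of qualitative
descriptions, with thresholds in the open: a stage is "expressed" at
FPKM ≥ 1; one copy silent everywhere → specialization-or-
nonfunctionalization (the two are indistinguishable without an outgroup,
hence the merged label); disjoint expressed-stage sets →
subfunctionalization; r ≥ 0.8 with both copies expressed in at least
half the stages → dosage balance; otherwise unclassified.

qRT-PCR fold changes use 2^−ΔΔCt against a reference gene and calibrator
sample; the calibrator's fold is exactly 1 and any per-sample constant
shift in Ct cancels.

## The synthetic-data generator

`simulate_genome()` builds the study conditions every stage is verified
against: 8 chromosomes × 40 gene slots (one gene per 30 kb); six CYP
families (CYP71, CYP75, CYP98 A-type; CYP72, CYP85, CYP86 non-A) whose
founders carry the planted signature regions; five scattered members per
family mutated to the identity ladder 0.33/0.47/0.62/0.75/0.88 — each
target at least five points from the 40/55/95 thresholds so tier
recovery is well-posed; an 8-gene duplicated segment (Ks 0.22, ω 0.15 —
inside the recent-WGD window, purifying); two 3-gene tandem arrays
(Ks 0.05, ω 0.3); two proximal, two transposed and two dispersed copies;
and one additional 4-member spaced cluster. Planted single-copy genes
keep ≥ 7 rank spacing from other family genes: at 30 kb per slot a
7-rank gap exceeds the 200 kb cluster limit, so no unplanned clusters
form and the planted cluster truth is exact. Decoys are random proteins
scrubbed of all four signature regions.

`evolve_cds()` diverges a CDS with two Poisson event streams —
synonymous events with expectation Ks × (NG86 synonymous sites) and
nonsynonymous events with expectation ω × Ks × (nonsynonymous sites) —
each event drawn uniformly from the currently possible single-base
changes of its class, stop-creating changes never being candidates. The
estimator recovering ω from these simulations is a parameter-recovery
check, not a fit to any published table.

`simulate_expression()` gives every gene a five-stage mean-FPKM profile
(stages labelled 15/45/90/120/145 days after flowering): planted drivers
share one rising profile that also generates the metabolite series;
planted retention pairs get complementary, parallel or one-silent
profiles; other genes draw rising/falling/flat/low patterns. Counts are
Poisson around `FPKM × length_kb × depth/10⁶` at depth 2×10⁷ (a
`noise = "none"` mode rounds the means instead; overdispersed counts are
not modelled). Twenty high-expression background genes absorb the
library so computed FPKM values sit on the intended absolute scale —
without them a small gene set would inflate every FPKM and the
FPKM ≥ 10 floor would lose its meaning. Metabolite noise is Gaussian
with sd = 0.17 × sd(series), chosen a priori by a Fisher-z power
calculation: it keeps the series' correlation with the noiseless driver
profile near 0.985, i.e. per-stage screen power ≈ 0.94 at n = 5 and
α = 0.05, joint two-stage power ≈ 0.9.

What the generator does *not* emulate: indels in family divergence
(substitution-only keeps identity targets tight; an indel option exists
but defaults off), intergenic sequence and repeats, overdispersed
counts, multiple interrelated genomes, and isoform variation. Passing
tests therefore demonstrate the correctness of the *rules* on data where
the rules' preconditions hold; on real genomes, alignment quality,
fragmented annotations and expression dispersion will add noise the
simulator deliberately leaves out.

## Problem sizes and determinism

The default simulated genome is 320 genes (about 54 planted P450s);
recovery suites use 100 ladder queries for nomenclature, 100 seeded
500-codon simulations for ω recovery, and 50 expression seeds for driver
sensitivity — sizes at which the stochastic checks are stable from seed
to seed. A single integer seed drives each generator through one RNG
stream whose state is saved and restored, so the same seed gives
byte-identical files and no caller's RNG is disturbed. The analysis
layer contains no randomness at all.

## Known limitations

- TRD calls rest on the single-genome ancestral-locus simplification;
  with outgroup genomes available, a dedicated tool will disagree on
  pairs whose ancestral locus is not syntenic within the genome.
- NG86 underestimates divergence relative to ML estimators at high Ks
  and ignores transition/transversion and codon-frequency bias; the
  `saturated` flag marks where the Jukes–Cantor correction gives up
  (p ≥ 3/4).
- The identity thresholds of P450 nomenclature were defined on long,
  largely complete sequences; for fragmentary queries the trimmed-column
  identity can exceed the whole-protein notion the convention assumes.
- `NEW_FAMILY` calls are flags for curation, not names — official naming
  is committee territory.
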