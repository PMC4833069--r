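---
title: "Models and methods in plastidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in plastidkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plastidkit)
```

plastidkit analyses deeply resequenced plastid (chloroplast) genomes: it
calls haploid variants from per-position allele-count pileups, detects
heteroplasmy left behind by occasional biparental chloroplast inheritance,
tests which lineage donated the paternal plastids of a hybrid, builds an
SNV phylogeny, dates its nodes, scans genes for clade-specific shifts in
dN/dS, and calls large deletions with breakpoint microhomology. Because
the statistics act on read counts rather than reads, every stage can be
exercised offline against a seeded simulator with known truth.

## The haploid variant matrix

The chloroplast is effectively haploid, so each sample's genotype at a
position is the majority allele of its covering reads — but only when that
allele is supported by at least 90% of them (`genotype_support_min`,
inclusive at the boundary); anything less is recorded as MISSING, and zero
coverage carries a distinct no-coverage flag. Calls with support in
[0.90, 0.95) carry a machine-readable review flag, a deterministic
replacement for by-eye curation in a genome browser. A position enters the
multi-sample matrix only if at least one sample's call differs from the
reference; positions where *every* sample carries the same non-reference
allele are reported separately as reference discrepancies (legacy errors
in the reference assembly, not variation in the panel).

Regions of the plastid genome with nuclear homologs attract mismapped
nuclear reads, so they are masked. `find_homologous_regions()` is an
ungapped seed-and-extend local aligner (11-mer seeds, +1/−2 scores,
X-drop 20) whose hits are filtered by the canonical threshold triple —
length > 100 bp, identity ≥ 90%, e-value < 1e−4 — with a
Karlin–Altschul-style e-value `E = K·m·n·exp(−λS)` using the ungapped
constants λ = 1.33, K = 0.621. Masking depends only on the thresholds, not
on the aligner brand, which is why a transparent in-package scorer is used.
The mapping-quality threshold (≥ 29) that upstream read pipelines apply is
kept as metadata only: the package consumes count tables, and acting on it
here would double-filter.

Indels are left-aligned and anchored; exonic indels are frameshift iff
their net length change is not a multiple of 3, and in-frame insertions
that duplicate the adjacent reference tract are labelled duplications.
Variant densities divide window counts by the *unmasked* window length.

## Heteroplasmy and the paternity test

A single heteroplasmic position (SHP) is a site whose minor allele is
supported by at least 5 reads out of at least 1,000 (both thresholds
inclusive), evaluated only at the nonredundant SNV positions of the panel
— restricting to segregating sites is the error-control step that makes a
5/1000 rule workable at ~2,000× coverage. When two minor alleles tie at or
above the read threshold the position is emitted once per allele and
flagged ambiguous.

Cluster sharing statistics use the historical convention: the cluster
total is the mean per-sample SHP count for clusters of four or more
members and the minimum otherwise, and the reported percentage is the
rounded ratio of shared (heteroplasmic in ≥ k members) to total.

The paternity (maternity-check) test asks, for each candidate paternal
parent, at how many of the hybrid's SHPs the candidate's *called* allele
equals the hybrid's *minor* allele. Candidates with MISSING calls at a
position are excluded from both counts there; known hybrids are never
candidates; the compatibility ratio is compatible/(compatible +
incompatible), and only candidates with more than 70 compatible positions
are flagged reported. Ancestral origins of SHPs are mapped with a
single-origin (Dollo-like) rule to the MRCA of the carriers: heteroplasmy
transmitted from one hybridization event has a single origin by
construction, which is exactly the signal the mapping is meant to display.

## Phylogeny and the clock test

The alignment concatenates variable SNV columns (indels excluded, MISSING
propagated, invariant columns dropped). The tree is neighbour joining on
p-distances with pairwise deletion, with bipartition supports from
site-resampled bootstrap replicates; heuristic maximum-likelihood or
Bayesian tree search is deliberately out of scope, and an externally
estimated newick can be supplied anywhere a tree is consumed.

`fit_gtr()` evaluates the GTR likelihood by Felsenstein pruning over
unique site patterns. MISSING states are marginalized (all-ones tip
partials) rather than deleted — the information a sample does carry at
other sites is kept. Branch lengths (or, in clock mode, node heights
reparameterized as proportions of the parent height, which enforces
ultrametricity by construction) are optimized by bounded quasi-Newton,
alternating with exchangeability updates until the log-likelihood improves
by less than 1e−6; base frequencies are empirical. Rate heterogeneity
(+Γ) is intentionally not fitted: the model is plain GTR, and a
documented switch would be the place to add it. The clocklikeness test is
the standard LRT, χ² = 2(−lnL_clock − (−lnL_free)) with N − 2 degrees of
freedom for N taxa.

Numerical notes: the likelihood uses the symmetrized eigen-decomposition
of the reversible rate matrix (stable for any admissible π); clock fits
start from both an ultrametricized version of the unconstrained branch
lengths and a flat-proportion start, keeping the better optimum; pattern
likelihoods are not log-scaled, which is safe for the alignment sizes this
package targets (hundreds of taxa would need scaling). Tests verify the
pruning value against exhaustive enumeration over internal-state
assignments on small instances, with transition matrices from an
independent matrix exponential.

## Divergence dating

Dating works on integer branch substitution counts `x_b` (fitted branch
length × alignment length, rounded). The Poisson log-likelihood
`Σ_b x_b ln(r_b d_b) − r_b d_b` is maximized over node ages (durations
`d_b`) and rates. Ages are reparameterized as proportions of each node's
feasible interval — floor = max(oldest child, minimum-age constraint),
ceiling = min(parent age, maximum-age constraint) — so parent > child and
every calibration constraint hold for any parameter value; infeasible
constraint sets are rejected up front.

* **Langley–Fitch** uses one global rate, profiled in closed form given
  ages.
* **Penalized likelihood** gives each branch its own rate and subtracts
  λ·Φ(r), where Φ sums squared rate differences between each branch and
  its parent branch and adds the sample variance of the root-adjacent
  rates (the standard convention for the root, where no parent rate
  exists). The optimizer starts from the Langley–Fitch solution with
  per-branch rates shrunk toward the global rate, so λ → ∞ recovers the
  clock solution smoothly (tested to within 0.1%) and λ = 0 reproduces
  per-branch maximum-likelihood rates x_b/d_b.
* **Cross-validation** chooses λ by leave-one-terminal-branch-out: refit
  without a terminal branch, predict its count from the parent branch's
  rate (mean of the other root-adjacent rates when the parent is the
  root) times its refitted duration, and score Σ(x − x̂)²/x̂ over a
  default grid of 10^(−2..3) in half-log steps, taking the first argmin on
  ties. Zero-length terminal branches are excluded from the folds.

A root-age scan (default 8–20 My in 1-My steps) reports per-node age
stability across root choices. Uncertainty over a sample of dated trees is
summarized per clade (matched by descendant leaf sets) as mean ± 2 SD.
Branch rates are grouped by one-dimensional K-means (50 seeded restarts,
labels ordered by class mean; k falls back to the number of distinct rates
when necessary).

## Selection scan

The selection module is a counting-based surrogate for codon-model branch
tests, preserving the decision rule — a clade is under positive (negative)
selection when its foreground ω exceeds (falls below) 1 *and* the
likelihood differs significantly from an ω = 1 model. Ancestral codons
come from Fitch parsimony per codon column (ties resolved toward fewer
nonsynonymous changes, then lexicographically); branch differences are
decomposed into synonymous/nonsynonymous counts by NG86 pathway averaging
(orderings through stop codons excluded), and N/S site totals are NG86
site counts averaged over the leaf sequences, so N + S = 3 × codons.

Per branch, `n_b ~ Binomial(n_b + s_b, p(ω))` with
`p(ω) = ωN/(ωN + S)`. Three models — ω = 1 everywhere, one global ω, and
a two-ratio foreground/background model — have closed-form maximum
likelihood estimates (the global MLE is `(n/N)/(s/S)`); the
positive-selection LRT compares the two-ratio model against the nested
null that fixes the foreground ω at 1 with the background free (df = 1).
The `scan_selection()` driver iterates genes × internal-edge clades and
reports Benjamini–Hochberg q-values across all tests alongside raw
p-values, since the historical analyses do not state a multiple-testing
procedure. Genes with fewer than `min_subs = 5` total substitutions are
verdict "filtered" — the "few mutations" filter made concrete. Whether
that threshold and the df are appropriate for a given dataset is exposed
as arguments rather than hard-coded.

Codon alignments concatenate exons (reverse-complemented for minus-strand
genes, only outside the inverted repeats). Codons touched by a deletion in
any sample are removed across all samples; an in-frame insertion of length
l at anchor p masks the reference codons overlapping [p − l, p + 1) in
every sample, because a duplication aligns ambiguously against the tract
it copies; a frame-violating insertion drops that sample, as does an
internal stop.

## Deletions and microhomology

Large deletions are called per sample from the base-supporting depth
profile: maximal runs of at least 50 positions below `drop_ratio = 0.2`
times the flanking median. The residual reference fraction (interior
median / flanking median) distinguishes homozygous deletions from
heteroplasmic ones (flagged at residual ≥ 0.005 — half a percent of reads
still carrying the undeleted haplotype). Breakpoints under flanking
homology are ambiguous by nature; calls are left-aligned to the leftmost
equivalent representation, and the inherent error bound equals the
homologous track length. `annotate_breakpoint_homology()` reports the
longest shared breakpoint context up to 25 bp per side (e.g. a TCCT
tetranucleotide, or a homopolymer unit with run lengths), the signature of
crossover between short homologous tracks. Identical-breakpoint deletions
shared by several samples are a single event at the carriers' MRCA;
overlapping but breakpoint-distinct deletions stay independent events and
are flagged as an overlap group.

## The simulator and what it does (not) show

`sim_config()` describes a circular ~160-kb plastid-like genome with two
inverted repeats (the second written as the reverse complement of the
first), optional nuclear-homologous tracts (copied into a decoy nuclear
sequence for masking tests), a stop-free tiled gene model, GTR
substitutions along a timed tree (Poisson per branch), indels with a
geometric-decay length distribution over 1–36 bp (ratio 0.825, so ~90% are
shorter than 13 bp and 1-bp events are modal; 59% insertions), large
deletions applied between planted flank motifs on a named carrier leaf,
hybridization events in which a paternal donor leaves its alleles at a
leakage fraction in (0, 0.5), and Poisson-depth pileups (~2,000×) with a
uniform per-base error rate (0.1% default). One master seed derives
independent per-stage streams, and identical configs are byte-identical.

Two named fixtures exist: `toy8` (20 kb, 8 taxa, one hybrid at 5% leakage,
one TCCT-flanked deletion) and `citrus34` (160,129 bp, 34 taxa in an
11-clade ladder rooted at 16 My, substitution and indel rates calibrated
to yield roughly 1.5k SNVs and 300 indels panel-wide, two TCCT-flanked
deletions of 388 and 207 bp, two hybrids). Simplifications to keep in mind
when reading green tests: coordinates are linear on [0, L) and events
never span the circular origin; indel placement is uniform outside the
IRs with no sequence-context hotspots; sequencing error is uniform and
read-independent (no mapping bias, no strand effects); pileup depth is
independent across positions. Recovery rates measured on this generator
therefore bound what alignment artifacts, chimeric reads and
context-dependent error would do to real data, they do not replace it.

Problem sizes used in the shipped tests and the acceptance script — the
8-taxon/20-kb fixture for end-to-end recovery (100 seeded replicates for
donor recovery), ≤ 4-taxon instances for the enumeration oracles, 500
replicates for the type-I study — were chosen so each check isolates one
property at full strength; the 34-taxon fixture exercises scale in the
clock-recovery test and is regenerable with `write_fixtures("citrus34", …)`.

## Known limitations

* No Γ rate heterogeneity or partitioned models in the likelihood.
* The NJ + bootstrap tree is a stand-in for full tree search; supply your
  own newick for publication-grade topologies.
* The selection surrogate counts substitutions by parsimony, which
  undercounts on long branches; ω estimates are best treated as ordinal
  (above/below 1) exactly as the decision rule uses them.
* The deletion caller is single-sample and coverage-only; a consensus
  hook (`assign_origins()` on externally produced calls) is the intended
  route for read-evidence callers.
* Insertions, inversions and duplications are not called as structural
  variants.
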