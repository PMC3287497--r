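---
title: "Promoter methylation and miRNA target burden: models and methods"
author: "methmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter methylation and miRNA target burden: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Gene repression operates at (at least) two stages. Promoter CpG methylation
acts transcriptionally: a heavily methylated promoter is typically silenced.
miRNA targeting acts post-transcriptionally: each predicted target site in a
3'UTR is an opportunity for repression of the mature transcript. If the two
layers complement each other, genes under strong promoter-methylation
control should need — and empirically carry — fewer miRNA target sites, and
vice versa. `methmir` turns that question into a reproducible pipeline: it
computes per-gene methylation measures, target-site burden, expression
summaries and 3'UTR evolutionary rates, joins them into one gene feature
table, and runs a rank-based correlation and group-comparison battery over
it.

## Measures and their definitions

**Methylation broadness (mCG/CG).** For a promoter window (default −1000 to
+200 bp around the TSS, strand-aware; the minus-strand window is the mirror
image `[tss − 200, tss + 1000)`), mCG/CG is the number of covered CpG sites
called methylated divided by the number of covered CpG sites. CpG
dinucleotides are enumerated on the forward strand (the site is palindromic)
and calls are attributed from the gene's annotated strand when per-strand
records exist; merging both strands is a configuration option. Sites below
the coverage floor (default 1 read) are excluded from numerator and
denominator; a promoter with no covered CpG is missing, not zero. The site
caller is pluggable: a one-sided binomial test of `mc_reads` out of
`total_reads` against a read error rate (default 1%) at a BH q-value of
0.01, or a simple methylation-fraction threshold. The binomial caller is
the default because "detected as methylated" in single-base bisulfite data
is conventionally a read-level test, but both callers feed the identical
downstream machinery.

**Normalized CpG content (CpG O/E).** `n_CpG · L / (n_C · n_G)` over the
promoter sequence; dinucleotides are counted by overlapping scan and the
denominator uses sequence length `L` (not `L − 1`) — the most literal
reading of "frequency of CpG over frequencies of C and G"; the difference
is O(1/L) and immaterial at 1200 bp. Positions containing N are excluded
from all counts and from `L`. Because methylated cytosines deaminate over
evolutionary time, low promoter CpG O/E is a fossil record of germline
hypermethylation, which is why the battery treats it as a third methylation
measure with the opposite sign convention.

**CpG islands.** The generator and pipeline count islands with the
Gardiner-Garden–Frommer rule: 200-bp windows slid 1 bp at a time qualify at
GC ≥ 0.5 and windowed O/E ≥ 0.6; islands are maximal runs of consecutive
qualifying window starts. Under this rule two dense CpG blocks merge into
one island exactly when their separation is ≤ 100 bp (half a window), which
matches the intuition that a window must stay majority-island to bridge a
gap.

**Target burden.** `Nt` and `Np` count unique (miRNA, site-position) pairs
per gene from two prediction sources, falling back to unique miRNAs when
positions are absent (both "unique sites" and "unique miRNAs" modes exist
because prediction tables vary in what they report; unique sites is the
default). Genes absent from a table are 0 only when the table is flagged
genome-wide — in a partial-coverage table absence is missingness, and
conflating the two would bias every correlation toward zero. 3'UTR length
`UL` is carried as a labeled burden proxy.

**Expression.** Probe-level matrices are collapsed by (1) averaging
replicate columns sharing a label, (2) dropping `_x_at`/`_s_at`
low-confidence probes, (3) averaging remaining probes per gene. Expression
broadness EB counts tissues at or above an intensity threshold (default
200; "at or above" because the threshold is stated as a threshold, not a
strict bound). No log transform is applied before averaging; the battery is
rank-based so any monotone transform is irrelevant downstream.

**3'UTR evolution.** The Kimura two-parameter distance over ungapped,
non-N columns: with transition proportion `P` and transversion proportion
`Q`, `K = −½ ln[(1 − 2P − Q)√(1 − 2Q)]`, missing (saturated) when a log
argument is non-positive. Focal-lineage indels use strict unanimity
parsimony: a run of columns where the focal row is gapped and *all*
non-focal rows have bases is a focal deletion; the reverse is a focal
insertion; columns where non-focal rows disagree are not counted. Rates are
total event lengths over total aligned columns. Unanimity is the most
conservative polarization and keeps the operation deterministic;
probabilistic ancestral reconstruction is out of scope.

**Segmentation.** DMRs: fixed non-overlapping windows (default 1 kb); per
window a 2×2 table of called site states (methylated/unmethylated ×
cell line) is tested one-sided for higher methylation in the second
methylome by Fisher's exact test; BH correction across windows (the only
place the package applies multiple-testing correction — it constructs this
family of tests itself, whereas the headline correlations are single
tests); significant windows merge when separated by less than one window.
Counting *sites* rather than reads follows the region definition being
about methylated sites; a read-count mode would weight high-coverage sites
more. PMDs: non-overlapping 10-kb windows; read-weighted mean methylation
`Σ mc / Σ total`; windows strictly below 0.70 merge, and merged runs of at
least 10 kb are reported. The threshold is strict ("less than 70%"), so a
window at exactly 0.70 is not a PMD. Genes are assigned to regions by ≥1 bp
promoter overlap, since the downstream comparison concerns promoter
methylation.

## The statistical battery

Spearman's ρ is Pearson's correlation of midranks; p-values use the
t-approximation with n − 2 df. Confidence intervals use the Fisher
z-transform with the Fieller-adjusted standard error `1.03/√(n − 3)` —
adequate for the profile plots they serve. The partial correlation is the
standard first-order formula on pairwise Spearman correlations,

ρ_xy·z = (ρ_xy − ρ_xz ρ_yz) / √((1 − ρ_xz²)(1 − ρ_yz²)),

with `t = ρ√((n − 3)/(1 − ρ²))` on n − 3 df. Conditioning covariates
default to the same cell line's expression for mCG/CG rows and to mean
germline expression for the CpG O/E row: CpG O/E records *germline*
methylation history, so the germline panel is the matched covariate; both
are configurable. Mann-Whitney U is exact for a smaller sample of ≤8
without ties and normal-approximated with tie correction otherwise; exact
Fisher and χ² (no continuity correction by default) cover the count
comparisons. Missing values are removed complete-case per test and the n
actually used is reported.

## The synthetic generator

`simulate_bundle()` is the package's study-conditions definition, not a
mock. Per gene a methylation propensity `m* = Φ(z_m)` is drawn and all
other latents couple to it through a Gaussian copula:

- target counts are `qnbinom(Φ(z_t))` with the latent correlation
  *calibrated by Monte Carlo* so the population Spearman between `m*` and
  the count hits its target (default −0.29) despite count ties — the
  sin-formula `r = 2 sin(πρ_s/6)` seeds the calibration and two fixed-point
  iterations correct the discreteness attenuation; an unreachable target
  errors with the achievable bound;
- expression couples at −0.47, and part of the methylation–target coupling
  is routed *through* expression (expression–target Spearman +0.25), so
  partial correlations genuinely shrink without vanishing — mirroring the
  mediation structure the battery is designed to expose (implied partial
  ≈ −0.20 at the defaults);
- CpG O/E loads at −0.8 on `z_m`, germline expression couples to CpG O/E at
  +0.37, and the true K2P rate couples to `m*` at +0.15;
- cancer labels are drawn with probability increasing in rank(−m*) +
  rank(Nt), dominant:recessive 4:1, plus a few ambiguous labels that
  belong to the all-cancer group only.

Sequences are built from 2-mer tokens that cannot create a CpG across a
junction, so a promoter has *exactly* its intended CpG count and an exact
CpG O/E of `k/75` (1200 bp, 300 C, 300 G, k CpGs); CGI-like promoters arise
for high-O/E (low-methylation) genes automatically. The intergenic
background is a repeat unit with one CpG per 20 bp methylated at 0.95; the
density and level are chosen so a 10-kb window's expected methylation can
only approach the PMD threshold where planted, keeping segmentation
recovery attributable to the planted signal. One known consequence of desk
scale: gene loci sit every 6 kb, ~50× denser than a mammalian genome, so
occasional adjacent pairs of hypomethylated CGI-like promoters can pull a
single background window under 70% and yield a short spurious PMD — real
methylomes show the same phenomenon at CGI clusters; tests therefore assert
boundary recovery of planted PMDs rather than absence of extra calls.
Methylation states are Bernoulli per site (probability `m*` in promoters,
overridden inside planted DMRs to `min(m* + 0.6, 0.95)` in cell line B and
inside PMDs to 0.4), coverage is Poisson(20) with zero-coverage sites
dropped, and read counts are binomial at a 1% error rate. DMRs are planted
at CpG-rich (`k ≥ 40`) hypomethylated (`m* < 0.35`) promoters, matching the
CGI-associated character of developmental DMRs. 3'UTR ortholog pairs are
evolved under the exact K2P transition probabilities at ts/tv rate ratio 2;
alignments for indel rates plant disjoint insertion/deletion runs whose
realized rates are recorded exactly in the ground truth.

What the generator does *not* emulate: realistic chromatin domain
structure, non-CpG methylation, read-level bisulfite sequences, alignment
error, annotation error beyond the planted ambiguous-TSS/UTR decoys, and
realistic gene density (above). Passing tests demonstrate the pipeline's
correctness and calibration under the stated couplings, not performance on
real genomes.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere internally; GTF (1-based
  closed) converts on read.
- Major transcript: longest CDS, then longest genomic span, then smallest
  `transcript_id` — deterministic and order-invariant.
- TSS ambiguity uses absolute genomic distance (>200 bp excludes); 3'UTR
  ambiguity is pairwise reciprocal overlap < 0.8 or strand disagreement
  among UTR-bearing transcripts.
- Zero-variance inputs to correlations error (naming the offending column
  in the battery); conditioning on a variable rank-identical to an input
  errors as degenerate; a 2×2 table with a zero margin returns p = 1
  flagged degenerate rather than erroring, because region/label scans
  legitimately produce empty margins.
- DMR windows with no covered sites are skipped; PMD runs are broken by
  windows without data.
- All randomness in the generator flows from one integer seed; the pipeline
  itself is deterministic, so a bundle and configuration reproduce every
  report byte for byte.

## Problem sizes

The shipped tests run the full battery at 5000 genes (the default
configuration, ~30 Mb of genome, ~1.3M CpG calls per methylome) and
segmentation recovery at 600 genes with 20 planted DMRs and 5 planted PMDs;
oracle-equivalence checks use ≥1000 randomized instances per operation.
`scripts/acceptance.R` re-runs both scales from a command-line seed in
about a minute.

## Limitations

Desk-scale synthetic genomes cannot validate performance on real,
repeat-rich, unevenly covered methylomes; the DMR caller is a transparent
windowed Fisher test, not a smoothing caller; PMD detection is a windowed
mean, not an HMM; miRNA target sites are consumed from prediction tables,
never predicted; and the CGI χ² comparison dichotomizes island counts
(≥1 vs 0), which is one of several defensible readings of "χ² on CGI
counts".
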