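---
title: "Methods: allele typing, chain-length dispersity, and the vitreousness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele typing, chain-length dispersity, and the vitreousness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svkit)
```

# The scientific problem

Quality Protein Maize combines the high lysine of the *opaque-2* mutation
with hard, vitreous kernels. Two starch enzymes are candidate drivers of
the vitreous phenotype: pullulanase (*Zpu1*), which debranches small
glucans, and starch synthase III (*SSIII*), which elongates glucan chains.
The analytical chain this package implements runs from sequence to
statistics: type the parental alleles (SNPs, indels, coding effects, a CAPS
restriction marker), quantify the fine structure of amylopectin through the
dispersity of its glucan chain-length distribution, and test how enzyme
activity and dispersity associate with kernel vitreousness across a panel
of recombinant inbred lines (RILs) carrying the four combinations of
QPM-derived (Q) and *opaque-2*-derived (W) alleles at the two loci.

# Allele analysis

Allele cDNAs of one gene are >99% identical, so global alignment is the
natural model. `align_global()` is Needleman–Wunsch with affine gaps
(defaults match +1, mismatch −2, gap open −6, extend −1, all configurable);
the dynamic program itself is delegated to `Biostrings::pairwiseAlignment`.
Aligner tie-breaking among equal-score gap placements is not contractual:
`call_variants()` merges maximal gap runs into single indel events and
**left-normalizes** them (shifting each indel to its lowest equivalent
reference position), the convention used in variant normalization, so
reported coordinates are deterministic regardless of the backend. All
coordinates are 1-based on the forward strand of the reference; a deletion
is reported at its first deleted base, an insertion at the base after which
material is inserted.

Coding effects come from conceptual translation. A SNP is silent iff the
substituted codon translates identically; codons containing ambiguity codes
translate to the unique shared residue of their concrete resolutions, else
`X`. Deletions of length divisible by 3 are in-frame (with the removed
residues and their 1-based amino-acid position recorded; a non-codon-aligned
in-frame deletion records the fused-codon outcome), others are frameshifts.
*Zpu1* positions in the literature are mRNA coordinates with an unstated
CDS start, so `classify_effects()` takes an explicit `cds_offset`; *SSIII*
clones are CDS from base 1 (offset 0). `ssiii_domain_map()` carries the
three annotated SSIII domains by amino-acid interval (1–768, 769–1226,
1227–1674); nucleotide bounds are derived as 3×aa, because the published
nucleotide bounds are internally inconsistent with the amino-acid bounds by
one codon and amino-acid position is what domain assignment actually uses.

# CAPS restriction typing

`find_sites()` scans both orientations for an IUPAC-degenerate recognition
pattern with *subset* semantics: an ambiguous sequence letter matches a
pattern position only if every concrete base it could be is permitted —
the conservative choice for genotyping, where a dubious site should not be
called. `digest()` converts site starts to top-strand cut positions
(`start − 1 + cut_offset`) and reports fragment lengths whose sum always
equals the sequence length; cuts that would fall outside the sequence are
skipped with a warning. Fragment lengths are top-strand segment lengths,
matching agarose-gel sizing. One consequence, verified in the tests: for an
enzyme with a staggered cut such as BslI (`CCNNNNN^NNGG`, 3-nt 3′
overhang), digesting the reverse complement reproduces the reversed
fragment list only up to the overhang at the terminal fragments; the
identity is exact for blunt cutters. `differential_sites()` aligns two
alleles and maps site positions through the alignment to report gained and
lost sites in reference coordinates — the CAPS-marker prediction.

# Chain-length dispersity

FACE yields, per sample, percent peak area A at each integer degree of
polymerization DP. The moment definitions treat A as a count weight:
number-average `x_n = ΣA·DP / ΣA`, mass-average
`x_w = ΣA·DP² / ΣA·DP`, and dispersity `PDI = x_w / x_n`. All three are
invariant to rescaling of A (normalization to ΣA = 100 is provided but
never changes results), and `x_w ≥ x_n` by Cauchy–Schwarz with equality
iff one DP carries all area. The tests verify agreement to 1e-12 with a
brute-force oracle that expands integer areas into individual chains.
"Average glucan chain length" is reported as the number-average `x_n` —
the only unweighted mean the moment definitions provide — with the
mass-average available by option. Replicate (ear) handling follows the
replicate-mean path: moments are computed per ear and then averaged; the
dispersity of pooled areas is a different quantity and is deliberately not
reported. The default DP window is 6–60 (debranched-amylopectin FACE
traces are conventionally read from DP 6); rows outside are dropped with a
warning, configurably.

# Association statistics

*Slope ANOVA.* Correlations are tested as ordinary least squares with the
F statistic on (1, n−2) df for slope = 0 — algebraically identical to the
squared Pearson-correlation t-test, which the tests assert numerically.

*Letter displays.* "Each pair t test" is implemented literally: two-tailed
two-sample t-tests with per-pair pooled variance and no multiplicity
correction, alongside Tukey HSD (Tukey–Kramer studentized-range p-values
from the one-way MSE). Both feed an insert-and-absorb compact letter
display; the construction guarantees the biconditional that two groups
share a letter iff their pairwise test is non-significant at α, and the
suite checks that property on every output rather than trusting the
algorithm. Letters follow decreasing group means. Note the unadjusted
pairwise-t p-value is not mathematically guaranteed to lie below the Tukey
p-value when group variances differ (the two use different variance
estimates); the conservativeness property is therefore tested in its exact
form, against the LSD test sharing Tukey's MSE and df.

*Exponential fit.* Vitreousness is modeled as `V = a·exp(r·PDI)`, the
two-parameter exponential growth model: the study's report names only a
"Growth Rate", and a two-parameter form keeps `r`'s interpretation clean.
Fitting is nonlinear least squares (`stats::nls`, Gauss–Newton with a
`scaleOffset` so zero-residual data converge; port-algorithm fallback),
initialized from the log-linear regression of `log(max(V, ε))` on PDI. The
95% interval for `r` is the approximate Wald interval
`r̂ ± t(0.975, n−2)·SE(r̂)` — mirroring the "approximate 95% confidence
interval" a SAS PROC NLIN analysis reports — and the relationship is
declared significantly positive when the interval excludes 0. A
non-convergent fit returns `converged = FALSE` and no interval rather than
a number.

*Aggregation level.* Published panels plot one point per RIL (the mean of
three ears), so `run_association_suite()` aggregates to RIL means by
default; `level = "ear"` uses all replicate rows. For a nonlinear response
the mean of `a·exp(r·PDI)` over ears is not `a·exp(r·mean PDI)` (Jensen's
inequality), so parameter-recovery and coverage tests run at ear level,
where the fitted model is exactly the generating model.

# The synthetic-data generator

The generator's defaults are a stated world, chosen once:

* **Allele pairs** (`allele_sim_spec`): a random CDS (ATG…stop, no internal
  stops), default 300 nt with 4 SNPs of which 3 silent — the planted
  structure mirroring the *Zpu1* allele contrast. Silent SNPs go to third
  positions whose substitution the codon table guarantees synonymous;
  missense SNPs avoid creating stops; in-frame deletions remove whole
  codons and are only planted where left-normalization cannot move them, so
  the returned truth equals the caller's left-normalized output exactly.
  All planted events occupy distinct, non-adjacent codons (≥ 3 nt apart).
* **Chain-length distributions**: a two-component mixture of discretized
  lognormals over DP 6–60 — short A-chain mode at `exp(meanlog) = 12.5`
  (sdlog 0.30), long B-chain tail at 38 (sdlog 0.22) — with per-bin
  lognormal noise (sd 0.05) and renormalization to 100. Genotype classes
  differ only in the long-tail weight (W-Q 0.30, Q-Q/Q-W 0.22, W-W 0.15),
  reproducing the observed *ordering* of average chain length
  (W-Q > Q-Q ≈ Q-W > W-W) but not published magnitudes, which the source
  does not give in tabular form. A degenerate component (sdlog 0) yields a
  monodisperse check case.
* **RIL panels**: default 14 RILs × 3 ears, classes assigned round-robin so
  all four are always present. Vitreousness is `a·exp(r·PDI)` per ear with
  a = 0.15, r = 4 (the center of the plausible growth-rate range for this
  system) and additive Gaussian noise (sd 5 pixel-intensity units,
  truncated at 0, since vitreousness is a nonnegative pixel average).
  Pullulanase A490 is affine in vitreousness with noise solved from the
  target population R² (default 0.38) via
  `sd_e = sd(signal)·sqrt((1−R²)/R²)`. DSC onset/maximum/enthalpy get
  class-dependent means reproducing the qualitative genotype contrasts
  (Q-W hottest; enthalpy W-Q high, Q-Q low).

Everything is driven by one RNG stream seeded once per run, so whole panels
replay exactly. What the generator does **not** emulate: raw
electropherograms and peak integration, within-RIL genetic heterogeneity,
spatial/field effects, DSC thermogram shapes, or any dependence of
chain-length parameters on vitreousness other than through the stated
model. A green test therefore establishes that the pipeline recovers the
structure it assumes — not that real kernels obey that structure.

# Numerical choices and degenerate inputs

Alignment scores use penalty convention `gap(L) = open + L·extend`. Moment
computations are plain double arithmetic (exact well beyond the 1e-12 test
tolerance for the sizes involved). `slope_anova` refuses constant x and
n < 3; the letter displays refuse groups of n < 2 and define p = 1 (or 0)
for zero-variance ties; the exponential fit refuses n < 4 and constant x,
and handles constant y (exact fit with r ≈ 0, interval containing 0).
Digest cut positions at or beyond the last base are skipped with a warning
rather than fabricating empty fragments.

# Known limitations

* The published RIL-level numbers (R² = 0.3762 for pullulanase against
  vitreousness; growth-rate interval 3.0167–5.1769) depend on unpublished
  phenotype and FACE tables and therefore anchor the generator's defaults;
  they are not reproduced as values.
* Sequence-level comparisons against the six GenBank alleles require the
  user to download the accession FASTAs (see README); the package performs
  no network access.
* Multi-allele comparison is pairwise against a designated reference; no
  true multiple alignment is constructed.
* Restriction digestion ignores methylation sensitivity, star activity and
  partial digestion, and reports top-strand fragment lengths only.
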