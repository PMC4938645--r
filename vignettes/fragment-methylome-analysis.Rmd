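---
title: "Fragment-level comparative methylome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level comparative methylome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methfrag)
```

## The analysis unit: MspI fragments

Reduced representation bisulfite sequencing (RRBS) libraries are built
from MspI-digested genomic DNA, size-selected to 40–220 bp before
adaptor ligation. MspI cuts the palindrome CCGG between the first and
second base (C^CGG), so every sequenced molecule begins and ends at an
MspI half-site. methfrag takes the restriction fragment — not the
individual CpG and not an arbitrary tiled window — as the unit of
methylation analysis. The biological motivation is that the fragment is
the physical unit of the library: all CpGs on one fragment are sequenced
together, and their counts can be pooled into one well-covered
methylation estimate.

`mspi_digest()` scans the forward strand only (the site is palindromic),
places a cut at motif start + 1, and drops each chromosome's leading and
trailing piece — those lack an MspI end, so no adaptor could ligate
there and they are never observed in a real library. Three invariants
are enforced by the test suite: concatenating the dropped ends and the
fragments reconstructs the chromosome exactly; every fragment starts
with `CGG` with a `C` immediately before it; and digesting the reverse
complement yields the mirror-image fragment set (shifted by the 2-bp
overhang of the asymmetric cut). Size-selection bounds are inclusive,
40 ≤ length ≤ 220; the protocol language does not force a strict or
non-strict reading, and the inclusive one is adopted here and used
consistently. Ambiguity codes (`N`) never match CCGG or CG.

Coordinates are 1-based inclusive inside R — the GenomicRanges
convention — while fragment identifiers (`chrom:start-end`) and all BED
output use the 0-based half-open BED convention. Bismark-style coverage
input is 1-based by default; a `zero_based` flag switches dialect
explicitly, with no autodetection.

## Fragment methylation and the coverage filter

For one sample, a fragment's methylation is the read-pooled ratio

$$m = \frac{\sum_i M_i}{\sum_i (M_i + U_i)}$$

over its CpG sites, where $M_i$ and $U_i$ are methylated and
unmethylated read counts at CpG $i$. Pooling reads (rather than
averaging per-CpG fractions) weights each CpG by its coverage and
matches the fragment-as-unit philosophy; the two estimators differ only
when coverage is very uneven within a fragment. Records split across
rows at the same coordinate are pooled before anything else, so the
estimate is invariant to how the input file batches its counts.

A fragment passes the coverage filter for a sample when at least 2 of
its CpGs each carry at least 10 reads (the "F2 t10" criterion; both
numbers are arguments). *Comparison fragments* are those passing in at
least 6 individuals of each of the two groups. Downstream statistics
use only the passing samples of each fragment; a non-passing sample is
treated as missing for that fragment rather than contributing a noisy
estimate. The filter is monotone — raising either threshold can only
shrink the pass set — and the comparison-set rule is symmetric in the
group labels; both properties are asserted in tests.

Global summaries weight each fragment by its CpG-site count
(`global_weighted_mean()`), and two groups are compared as the relative
reduction $100\,(m_\mathrm{ref} - m_\mathrm{test})/m_\mathrm{ref}$.
Methylation categories use inclusive bounds: low $\le 0.30$,
high $\ge 0.70$.

## Differential methylation: ANOVA with Bonferroni control

Each comparison fragment is tested by a two-group one-way ANOVA on the
per-sample fragment methylation values, $F = MS_b/MS_w$ with
$(1, n_1+n_2-2)$ degrees of freedom; for two groups this is exactly the
squared pooled-variance t statistic, an identity the tests exploit as an
oracle. Degenerate fragments are clamped deterministically: when
$MS_w = 0$ with equal means, $F = 0,\ p = 1$; with unequal means,
$p = 0$. Mean equality is judged with a small tolerance because values
like 0.1 are not exact in binary floating point.

Family-wise error is controlled by Bonferroni: the per-test cutoff is
$\alpha / n$ with $\alpha = 0.05$ and $n$ the number of comparison
fragments, and the comparison is inclusive ($p \le$ cutoff). A fragment
is a differentially methylated fragment (DMF) when it passes the
adjusted cutoff **and** its absolute group-mean difference is at least
0.25 — the two conditions are conjunctive, so an arbitrarily significant
fragment with a 0.24 difference is not a DMF. The difference is taken
between group means of per-sample values (not pooled-read group
methylation), which keeps it symmetric and consistent with the ANOVA
input. Direction is relative to the test group: `hypo` when the test
group's mean is lower. Full-precision cutoffs are used for calling;
rounding to 3 significant figures is display-only.

The per-fragment ANOVA is computed by row-vectorised matrix operations
rather than per-fragment model-fit calls, for speed at genome scale;
agreement with `stats::aov`, `oneway.test` and the scalar t² identity to
1e-10 is asserted in the tests, including under missing-value patterns.

## Logit-scale Gaussian mixture decomposition

Fragment methylation histograms pile up against 0 and 1. The logit
transform $\mathrm{logit}(m) = \ln(m/(1-m))$ spreads both shoulders so
that sub-populations become resolvable as Gaussian components on the
log-odds scale. Exact 0 and 1 values are clamped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.005$ (configurable)
before transforming; the clamp keeps every value finite and affects only
fragments whose every read agrees.

`fit_mixture()` is a standard univariate EM: responsibilities from
normalised component densities (computed in log space with log-sum-exp),
then closed-form weight/mean/variance updates. Convergence is declared
when the log-likelihood gain drops below 1e-8 or at 1000 iterations; the
log-likelihood is non-decreasing every iteration, and the tests assert
this on the recorded trace. Ten seeded restarts are run — the first from
quantile-spaced means, the rest jittered — and the best likelihood wins;
a restart whose component standard deviation collapses below 1e-6 is
discarded, and an error is raised only if every restart degenerates.
Components are always reported sorted by mean, making fits invariant to
input order and label permutation. The number of components is chosen by
BIC, $-2\log L + (3k-1)\ln n$, over candidates $k \in \{1,2,3\}$; BIC's
complexity penalty is what lets a genuinely bimodal methylome reject the
third component. An independent mixture implementation (mclust, run at a
tightened convergence tolerance) reproduces our means to 1e-3 and our
log-likelihood to 1e-6 in the cross-check test.

## Annotation: genomic elements and repeat classes

Fragments are assigned one primary element by the precedence
**promoter > exon > intron > intergenic**, with the promoter defined as
the strand-oriented window −5 kb to +1 kb around the TSS and intergenic
requiring no gene-body overlap and more than 5 kb distance from every
TSS. The precedence rule resolves fragments overlapping several
elements (for instance an exon inside a neighbouring gene's promoter
window) deterministically. This four-way partition leaves one residual
undefined: a fragment within 5 kb of a TSS that touches neither the
promoter window nor the gene body. Such fragments receive a fifth label,
`tss_proximal`; with gene models whose bodies exceed 5 kb the class is
essentially empty, but silently folding it into "intergenic" would
contradict the >5 kb definition. Fixed ±200 bp / ±500 bp / ±1 kb TSS
windows are reported as additional flags, not as primary elements.

Repeat overlap uses a ≥1 bp rule; a fragment carries every repeat class
it touches and is a *retroelement* fragment when any of those classes is
SINE, LINE or LTR (the union rule — "retroelement-containing" is a
property, not a partition). Fragments overlapping only Satellite,
Low_complexity or Simple_repeat are repeat-containing but
non-retroelement. Unknown class labels warn and count as
non-retroelement. In per-class summaries a fragment contributes to every
class it overlaps, which can double-count a small fraction of fragments
that span two annotations; the alternative (unique assignment) would
need an arbitrary precedence among repeat classes.

Regulatory-feature enrichment uses the stricter *strong overlap* rule:
at least 50% of the fragment's length must be covered, and the ≥ (not >)
reading of the threshold is adopted, so a fragment exactly half-covered
qualifies.

`retention_table()` restricts to fragments highly methylated in the
reference group (> 0.7) and reports, per repeat family and for the
non-retroelement remainder, the fraction retaining > 0.8 methylation in
the test group — the summary that exposes class-specific resistance to
hypomethylation.

## Genome landscape statistics

`density_tiles()` tiles each chromosome into 1-Mb windows from
coordinate 0, assigns fragments by midpoint (the choice for
boundary-straddling fragments; any-overlap would double-count), and
scores each tile as DMFs per comparison fragment, separately for hypo-
and hypermethylated DMFs. Tiles with fewer than 3 comparison fragments
are excluded from scores and correlations. Gene density is the TSS
count per tile and CpG density the genomic CG-dinucleotide count (not
the covered-CpG count), and Pearson correlations of density score
against both are reported per direction.

PMD overlap is tested with the upper-tail hypergeometric probability
$P[X \ge k]$ (population: comparison fragments; successes: fragments
overlapping a PMD by ≥1 bp; draws: hypomethylated DMFs). Feature
enrichment builds, per feature track, the 2×2 table of strong overlap
versus DMF/non-DMF membership and applies the chi-square test with
Yates continuity correction,
$\chi^2 = \sum (\max(|O-E| - 0.5,\, 0))^2/E$, with the continuity term
floored at zero. A feature covering everything (or nothing) collapses a
margin and raises an explicit error rather than returning a meaningless
statistic.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated
against a known truth. It emulates the statistical structure of a
two-tissue RRBS comparison; its defaults are the study conditions and
are not tuned per experiment.

**Genome.** Each chromosome is a random background sequence constructed
to contain no CG dinucleotide at all, into which exact CCGG motifs
(Poisson-placed at `ccgg_rate` per kb, default 4) and extra CG
dinucleotides (`cpg_rate` per kb, default 15) are inserted with A/T
flanks. The flanks guarantee that insertion cannot create or destroy
sites, so the motif count is exactly the Poisson draw, and
`ccgg_rate = 0` yields a genome with no CCGG substring — properties the
tests assert directly. The default 4 sites/kb is denser than a
mammalian genome; on a miniature 2-Mb genome it yields a few thousand
size-selected fragments, enough for stable distributional tests, which
on a real genome would come from the genome's own length. Repeat
intervals (150–600 bp) are placed per family to human-like target
fractions across SINE/Alu, SINE/MIR, LINE/L1, LINE/L2, the four LTR/ERV
families, Satellite, Low_complexity and Simple_repeat; genes (5–30 kb
bodies, 2–8 exons, random strand) are placed at 10 per Mb.

**Methylation truth.** Each group has a logit-Gaussian mixture: by
default a bimodal low/high mixture for the neutrophil-like group and a
trimodal mixture for the placenta-like group with weights
0.215/0.638/0.147 and log-odds means −3.34/0.10/2.45 (component sd 0.8
— the published decomposition reports weights and means but no
spreads, so the sd is a modelling choice, and mixture-recovery tests
check only weights and means against published values). A design point
worth spelling out: each fragment draws **one** latent quantile
$u \sim U(0,1)$, and group $g$'s true methylation is
$F_g^{-1}(u)$ through its own mixture quantile function. Each group's
marginal therefore follows its own mixture exactly (asserted by a
Kolmogorov–Smirnov test at the pre-registered 0.05 threshold with
n ≥ 5000 fragments), while fragments remain maximally coupled across
groups — in particular, when both groups share a mixture, every
unplanted fragment has *identical* truth in the two groups, which is
what makes the planted-DMF truth set a meaningful benchmark.
Independent per-group draws would instead scatter large "differences"
over all fragments and make sensitivity/FDR against the planted set
meaningless.

A `dmf_fraction` of fragments (default 3%) is planted as true DMFs: the
second group's value is set `dmf_min_shift` (≥0.25) plus a uniform
0–0.15 extra below (90% of plants, mirroring the strong hypomethylation
skew of the placental comparison) or above the first group's value; if
the shift would leave [0,1] the direction flips, so the planted
difference is always achieved exactly and the truth invariant
|difference| ≥ `dmf_min_shift` holds unconditionally.

**Reads.** Per sample and per CpG, total reads are negative binomial
with mean 30 and size 8 (roughly the coverage at which the 2-CpGs-at-10×
filter passes most but not all fragments, giving the filter something to
do), the CpG's own methylation is a Beta draw around the fragment truth
with concentration 50 (sd ≈ 0.07 at m = 0.5; the within-fragment
dispersion of real data is not published, so this is a documented
modelling choice), degenerate at exactly 0 or 1, and methylated reads
are binomial. Only covered positions are emitted, as in real coverage
files. Randomness uses one seed with named substreams per stage
(genome, repeats, genes, truth, planting, one per sample), so enlarging
the design leaves the genome and earlier samples byte-identical — a
property the tests check, along with byte-identical file output under a
fixed seed.

**What the generator does not emulate.** Per-sample biological
variation beyond read sampling (all samples of a group share the
fragment truth), bisulfite conversion failure, mapping bias,
fragment-length-dependent coverage, CpG islands, and correlated
neighbouring fragments. Passing tests therefore demonstrate the
statistical machinery — calibration of the F test under Bonferroni,
recovery of planted effects at realistic depth, mixture identifiability
at realistic n — not robustness to every artefact of real libraries.

## Problem sizes and numerical choices

The calibration suites run at the sizes the analysis plan fixes: 5000
fragments × 11 vs 11 samples × 200 replicates for the null family-wise
error rate (expected ≤ 0.05 plus three Monte-Carlo standard errors);
the same scale with 250 planted shifts of 0.3 at 30× depth for
sensitivity (≥ 0.9 expected) and empirical FDR (≤ 0.05); n = 30,000 for
mixture recovery, matching the order of the comparison-fragment count
of the motivating study; and a 2-Mb, 22-sample genome for the
end-to-end run. Mixture quantile functions are inverted on a 4001-point
grid spanning ±6 component sd (interpolation error far below any
tolerance used); EM tolerance is 1e-8 absolute log-likelihood gain;
ANOVA mean-equality clamps use a 1e-9 relative tolerance; and the
hypergeometric and chi-square routines delegate tail computation to R's
`phyper`/`pchisq`.

## Known limitations

Only two-group designs are supported (the F test generalises, the
direction labels do not); Bonferroni is the only multiplicity control,
by design; the mixture model assumes Gaussian components on the logit
scale, which cannot represent skewed components; element assignment
depends on the completeness of the supplied gene models; and the
per-class repeat summaries double-count fragments spanning two repeat
classes, as discussed above.
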