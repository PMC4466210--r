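---
title: "Methods: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonuclear)
```

## The scientific question

Animals produced by somatic-cell nuclear transfer (SCNT) are usually
heteroplasmic: their mitochondria come from the recipient oocyte while the
nuclear genome comes from the donor cell. Oxidative phosphorylation (OXPHOS)
requires stoichiometric assembly of subunits encoded by both genomes, so a
natural question is whether the *coordination* between nuclear-encoded and
mtDNA-encoded mitochondrial gene expression survives cloning — and whether
its loss tracks clone viability. This package implements the full analysis
chain needed to ask that question with a two-channel cDNA microarray study of
cloned piglet lung tissue: maternal-lineage calling from an ND1 SNP panel,
array QC and normalization, genome-of-origin partitioned clustering,
differential expression with gene-set enrichment, and comparative-CT qPCR
validation. A deterministic synthetic-data generator reproduces the study's
design so every stage is testable without the original hybridizations.

## Maternal-lineage calling

Large White and Duroc maternal lineages differ at seven positions of the ND1
coding region (342, 369, 420, 438, 459, 489, 712; coordinates 1-based with
base 1 at the ND1 start). `assign_lineage()` scores each candidate reference
by exact base matches at the *discriminating* positions — positions where the
references differ — and assigns the unique maximizer; ties and all-zero
scores return `UNRESOLVED` rather than a guess. This replaces whole-fragment
alignment scoring: alignment bit scores depend on scoring matrices and
fragment length, while the panel alone determines every assignment in the
printed genotype table (each printed animal is a clean 7/7 match).

Conventions fixed here:

* **Heteroplasmy and ambiguity codes.** An IUPAC ambiguity call counts as a
  match to a reference base only when it is explicitly flagged as a mixed
  sequencing peak; a bare `N` never matches. This stops missing data from
  inflating scores. Mixtures are considered sequencing-detectable only when
  the minor-haplotype fraction strictly exceeds 25%
  (`detect_heteroplasmy()`), matching the detection limit of dye-terminator
  traces.
* **Private variants** are panel positions where the observed base matches
  *no* reference (e.g. the printed C at position 528 in the deceased-group
  animals, where both references carry T). They are reported, classified
  against the reference coding sequence, and never scored.
* **Reading frame.** Codon-effect classification assumes base 1 is the first
  base of codon 1. Whether the fragment's "base 1" (stated as the
  transcription start) coincides with the translation start is not asserted;
  the frame assumption is a documented convention. One consequence: a T→C
  substitution can never create a stop codon under the vertebrate
  mitochondrial code (no stop contains C), so the generator's optional
  "nonsense at 528" feature plants a codon (`TAT`) whose position-528
  alternative `A` genuinely creates `TAA`.
* The genotype-table parser accepts printed artifacts of the form `T2`
  (base + trailing digits) as the base, with a warning.

`classify_codon_effect()` uses a hard-coded vertebrate mitochondrial code
table (AGA/AGG/TAA/TAG stop, ATA Met, TGA Trp); the test suite checks it
against an independent whole-sequence translation oracle on 1,000 random
substitutions.

## Two-channel array processing

The pipeline starts from per-probe pixel summaries (foreground and local
background medians per channel, plus the fraction of feature pixels more than
two SD above background). Stages, with their boundary semantics taken
verbatim from the study's wording:

1. **Background subtraction**: `max(foreground − background, 0.5)`, floored
   probes flagged and excluded from normalization.
2. **Present call**: at least 70% of pixels above background + 2 SD in
   *either* channel (inclusive).
3. **Lowess normalization**, per slide, in dye space: `A = 0.5·log2(Cy5·Cy3)`,
   `M = log2(Cy5/Cy3)`; a locally weighted regression (tricube weights,
   3 robustifying iterations, span 0.3 by default) of M on A is subtracted.
   The fit is done before orienting M to sample/reference so that the
   dye-specific bias — which lives in dye space — cancels correctly across a
   dye swap. No between-slide scale normalization is applied.
4. **Dye-swap combination**: both slides oriented sample/reference, averaged;
   a probe missing on one slide takes the other's value.
5. **Informative filter**, three clauses, all required: present in more than
   90% of slides in the sample channel *or* the reference channel (strict);
   median background-corrected intensity above 100 (strict) in a channel that
   passed the presence clause; SD of combined log ratios below 1.4 (strict).
   Every exclusion is attributed to at least one named clause
   (`filter_detail`), so informative + excluded = total by construction.

The study does not say whether its "raw expression values > 100" and
"SD < 1.4" were computed on single-channel intensities, ratios or the
software's internal values; the interpretation above (median corrected
intensity in the presence-passing channel; SD of normalized log ratios) is a
documented choice, and both cutoffs are parameters of
`filter_informative()`.

**Numerical note on the smoother.** `stats::lowess` fits local *linear*
regressions, which systematically underfit strong curvature at wide spans:
for a planted bias of `0.1·(A−10)²` over `A ∈ [5, 17]` the default span 0.3
leaves per-decile median residuals up to ~0.07, while span 0.2 brings every
decile below 0.05. The bias-removal tests therefore use span 0.2; the
pipeline default stays at the conventional 0.3 because real dye bias is far
gentler than that stress case. Similarly, the subtracted trend is an
*estimate* with sampling wiggle of order `sd(M)/sqrt(span·n)`; "exact"
recovery statements only hold at the raw-ratio stage or in the many-probe
limit.

## Clustering and the coordination readout

Samples are clustered on three informative-probe subsets: all (global),
nuclear-encoded mitochondrial-function, and mtDNA-encoded. The clustering
software used in the original analysis does not document its metric or
linkage; this package fixes `1 − Pearson` distance (pairwise-complete) with
unweighted average linkage (UPGMA) and deterministic smallest-index
tie-breaking — the standard two-channel expression convention — implemented
in-package and verified against `stats::hclust` merge-for-merge.

Two statistics operationalize the qualitative published readout:

* **Coherence r**: mean within-treatment pairwise Pearson correlation. The
  original figures annotate an undefined "r" per group; mean pairwise
  correlation is the simplest quantity with the right behavior (an
  alternative — cophenetic correlation — is noted but not implemented as the
  default).
* **Treatment-separation purity**: cut the dendrogram into two clusters;
  purity is the fraction of samples whose cluster's majority treatment is
  their own. "Clustered by treatment" ≙ purity near 1; "intermixed" ≙ purity
  near the majority-class proportion (0.58 for 7 clones vs 5 controls).

`coordination_contrast()` reports `purity(nuclear-mito) − purity(mtDNA)` and
labels the group "disrupted" when the difference exceeds a margin
(default 0.2, configurable). With only 32 mtDNA probes the purity of the
mtDNA subset is intrinsically noisy, so the contrast is a statement about
regimes, not a precise effect size.

## Differential expression and enrichment

Per group (deceased or live), clones are compared with their age-matched
controls. Fold change is `2^(mean log ratio clones − mean log ratio
controls)` — a geometric-mean ratio, the natural arithmetic for a common
reference design. A probe is differentially expressed when the fold change is
at least 1.5 in either direction (down-regulation as FC ≤ 1/1.5, matching
printed down-regulated ratios like 0.65) *and* the Welch-t p, adjusted by
Benjamini–Hochberg across the informative probes, is at most 0.05. The DE
wording in the source is grammatically ambiguous about whether the 0.05
applies to raw or adjusted p; adjusted is the default, raw is a flag. Both
boundaries are inclusive. Welch's test runs on log ratios (not linear
ratios), with the Welch–Satterthwaite degrees of freedom; probes missing in
more than half of either group are dropped with a recorded reason.

BH adjustment is the step-up transform; note it is *not* idempotent (the
property tests assert determinism, permutation-equivariance and monotonicity
instead). Enrichment replaces an external annotation web service with
Fisher's exact test over packaged gene sets: two-sided p by the
minimum-likelihood convention (sum of conditional table probabilities not
exceeding the observed one — conventions differ, so this is stated
explicitly), Haldane 0.5 correction applied to the odds ratio only, never to
the p, and BH across sets.

## qPCR validation

`comparative_ct()` implements ΔΔCt with a perfect-efficiency assumption
(2-fold per cycle, no standard-curve correction): replicate Cts averaged,
ΔCt against the internal-control gene (TBB2), ΔΔCt against the calibrator
(pooled reference RNA), `rq = 2^(−ΔΔCt)`. Two invariants pin the arithmetic:
rq is unchanged by any per-sample Ct offset (internal-control cancellation),
and re-choosing the calibrator rescales all samples by one shared constant.

Group comparison follows the published recipe: an F-test for equal variances
(classical two-sided pretest at α = 0.05), then a one-sided t-test in the
direction the microarray reported, pooled-variance when the pretest passes.
The source is silent on the branch when the pretest *fails*; a one-sided
Welch test is used there, as the least-surprising completion. Significance is
declared at p < 0.05 (strict). The exact two-sided pretest power at variance
ratio 16 (n = 5/5) is 0.684 — a one-sided larger-variance-on-top convention
would give 0.80 — which is why the branch-rate test compares against the
F-distribution closed form rather than a fixed percentage.
`concordance()` reports per-gene directional agreement between platforms,
with genes absent from either side reported missing rather than discordant.

## The synthetic-data generator: what it emulates

Defaults reproduce the stated study design: 13,310 probes (534
nuclear-encoded mitochondrial-function, 32 mtDNA-encoded), 7 deceased clones
with 5 controls and 5 live clones with 5 controls, two dye-swap slides per
sample (44 arrays), a qPCR panel of nine validation genes plus TBB2.

The latent expression model, per probe i and sample j (log2 ratio against
the common reference):

```
x_ij = b_i + l_i · F_j + δ_i · clone_j + ε_ij
```

* `b_i ~ N(0, 1)` is a tissue-versus-reference baseline shared by all
  samples — the reason any two lung samples correlate ~0.9 against a pooled
  fetal reference, and the backdrop against which treatment structure must be
  detected.
* `F_j` is the nuclear-mitochondrial program score `f_j` for nuclear-mito
  probes and `h_j = √ρ·f_j + √(1−ρ)·g_j` for mtDNA probes, with `g_j` an
  independent mitochondrial factor. The coordination parameter ρ
  (`coordination_rho`) is the quantity of interest: at ρ = 1 the mtDNA
  program tracks the nuclear one — treatment response included — and at
  ρ = 0 it is decoupled, which is exactly the published deceased-group
  phenotype.
* Clones receive a program shift (`treatment_factor_shift = 1.5`) and
  per-probe effects `δ_i ~ N(0, 0.5)` on the probes in scope (default: all
  non-mtDNA probes), and are more variable than controls both on the program
  score (SD 0.7 vs 0.4) and per measurement (biological SD 0.4 vs 0.15) —
  the published coherence gap between clones and controls is a direct
  statement of this extra variability.
* Loadings `l_i ~ |N(0.6, 0.4)|`: the loading *spread* matters, because
  Pearson correlation across probes centers each profile, so only the
  heterogeneous part of a program shift survives into correlation structure.

Slides are generated in dye space (`M = ±x + bias(A) + noise`,
`Cy5 = 2^(A+M/2)`, `Cy3 = 2^(A−M/2)`) with a mild quadratic dye bias by
default, per-probe baseline intensities spanning ~1e2–1e5 (so the >100
filter clause is exercised), additive local backgrounds, and pixel-presence
fractions drawn so that ~20% of probes fail the 70% rule. Pixel statistics
are simulated directly as fractions — the present call consumes nothing
else. Ct values are `baseline_gene − x + noise`, so the comparative-CT
method inverts the generator exactly at zero noise.

Slide-level variance components (array and spot effects) are documented
constants, not inferences from data; the generator emulates the statistical
structure the analysis *assumes*, not raster images, trace files or PCR
kinetics. A green synthetic test therefore establishes that the pipeline
detects the structure it is designed to detect — it cannot certify the
published biological values, which require the original hybridizations (the
published per-group informative counts, Fig-1 r values, DE gene lists and
enrichment statistics are explicitly out of reproduction scope; the
defaults land in the same regime, e.g. ~70% informative probes, which is a
sanity check rather than a target).

Null calibration is checked with both treatment knobs at zero
(`treatment_effect_sd = 0`, `treatment_factor_shift = 0`): clones keep their
larger variance (Welch's test is the reason that is legitimate), no probe has
a true mean shift, and any discovery is false by construction.

## Determinism and numerical conventions

Every generator seeds its own RNG stream (derived from the config seed by
fixed offsets) and restores global RNG state, so identical configurations
give bit-identical outputs regardless of call order. Ties in agglomeration
break toward the smallest original sample index; heights follow the
Lance–Williams average-linkage update. The two-sided Fisher p compares table
probabilities with a `1 + 1e-7` relative tolerance, matching common
practice, and caps at 1. Thresholds (0.70, 0.90, 100, 1.4, 1.5, 0.05, 0.25,
span, purity margin) live in a single run configuration
(`default_run_config()`), so the "published defaults" are one named preset.

## Known limitations

* The mtDNA subset has 32 probes; purity and coherence on it are noisy, and
  the coordination contrast should be read as a regime label, not an effect
  estimate.
* The lineage caller scores a fixed panel; it does not align reads, call
  bases from traces, or handle indels.
* Lowess span is a bias/variance trade-off the source does not pin down;
  strongly curved bias needs a finer span than the default (see above).
* The generator's breed assignment mirrors the printed cohort when counts
  match the default design and falls back to round-robin otherwise; it does
  not model oocyte sourcing.
* Enrichment uses packaged gene sets over the informative universe; numbers
  from annotation services with proprietary backgrounds are not comparable.
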