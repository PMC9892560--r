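---
title: "Models and methods behind nichefx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nichefx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nichefx` analyses 2×2 heterochronic-transplant experiments: stem cells
from young and aged donors, profiled before (`T0`) and after (`T21`)
engraftment into young hosts. This vignette documents the statistical
models, every tunable parameter that matters, the design decisions that
were genuinely open, and what the bundled simulations do and do not
demonstrate about real data.

## The factorial count model and the niche effect

Expression counts are modeled per gene as negative binomial with a log
link and sample-specific size-factor offsets:

$$K_{gj} \sim \mathrm{NB}(s_j \, \mu_{gj}, \alpha_g), \qquad
\log_2 \mu_{gj} = \beta_0 + \beta_{\mathrm{time}} t_j +
\beta_{\mathrm{age}} a_j + \beta_{\mathrm{int}} a_j t_j \,(+\,
\beta_{\mathrm{batch}}).$$

With treatment coding anchored at young/`T0`, the coefficients are the
three biological contrasts of the design: $\beta_{\mathrm{age}}$ is the
baseline age difference (Aged~T0~ − Young~T0~), $\beta_{\mathrm{time}}$
is the engraftment effect measured in the isochronic young control
(Young~T21~ − Young~T0~), and the interaction is the **niche effect**:
the aged cells' post-transplant change minus the engraftment effect.
This identity is exact for the fitted model — on noiseless group means
the fitted interaction equals
$(\log_2 A_{T21} - \log_2 A_{T0}) - (\log_2 Y_{T21} - \log_2 Y_{T0})$
to numerical precision — and is asserted in the test suite.

The batch term is included whenever the design table carries more than
one batch level. When several batch coefficients exist, the per-gene
"batch LFC" reported for filtering is the largest-magnitude raw
coefficient; the batch filter is a heterogeneity gate, so it deliberately
uses the unshrunken value.

**Assumptions.** One dispersion per gene shared across groups; effects
act multiplicatively on the mean; replicates are exchangeable within an
age × time × batch cell. All four cells must be populated or the
decomposition stops with an error — with an empty cell the niche effect
is not identifiable.

## Size factors, dispersion, inference

*Size factors* are median-of-ratios against the gene-wise geometric-mean
reference, restricted to genes observed in every sample, rescaled to a
geometric mean of exactly 1. If no gene is expressed everywhere the
package falls back to total-count scaling with a warning.

*Dispersions* are estimated in two stages. The gene-wise estimate
maximizes the Cox–Reid adjusted profile likelihood given fitted means
from a Poisson GLM of the same design (the adjustment compensates the
degrees of freedom consumed by the mean model; without it the estimate
is biased low). A mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ is
then fitted across genes — mean-targeting (unweighted, with iterative
trimming of 15-fold outliers), because the gene-wise estimates are
mean-unbiased but right-skewed — and each gene's log-dispersion is
shrunk toward the trend with a precision weight that balances the
sampling variance of a log-dispersion estimate at the design's residual
degrees of freedom (`trigamma((m − p)/2)`) against the robustly
estimated gene-level scatter around the trend (floored at 0.25 so real
gene-level variation is never shrunk away entirely). Dispersions are
floored at $10^{-8}$; genes with zero observed variance sit at the floor
(constant data carries no overdispersion signal), and all-zero genes are
flagged `NA` and excluded downstream.

*GLM fitting* uses iteratively reweighted least squares via the
fixed-theta negative-binomial family, with coefficients and the full
coefficient covariance converted to log2 at the boundary. Fits with
runaway coefficients (|log2 coefficient| ≥ 12 or SE ≥ 8, the signature
of an empty factorial cell) are marked non-estimable and excluded from
moderation — their Wald statistics would otherwise be meaningless and,
worse, would contaminate the ranking that s-values are computed from.

*Wald tests* use a t reference with the model's residual degrees of
freedom. With two samples per condition in the stacked accessibility
model the residual df is 4, and a normal reference is visibly
anticonservative there; at the RNA layer's df the t and normal references
agree closely.

## Moderated LFCs and s-values

For ranking and classification the per-contrast MLEs are moderated under
a zero-centered heavy-tailed **Cauchy prior**, using the normal
approximation $\hat\beta_g \sim N(\beta_g, \mathrm{se}_g^2)$. Heavy tails
matter: estimates consistent with noise shrink strongly while clearly
nonzero effects keep nearly their full size, which is what keeps a
fixed |moderated LFC| > 1 gate meaningful.

The prior scale is the slab scale of a two-group marginal
maximum-likelihood fit, $\hat\beta \sim \pi_0 N(0, \mathrm{se}^2) +
\pi_1 N(0, \tau^2 + \mathrm{se}^2)$. Two alternatives were considered
and rejected:

- a single normal prior with marginal-ML scale collapses toward the
  null majority when effects are sparse and over-shrinks true effects;
- a single global moment estimate (`mean(b² − se²)`) conflates the
  *fraction* of nonzero effects with their *size*, again over-shrinking
  when effects are sparse but individually large;
- fitting the mixture with a *Cauchy* slab is unidentifiable — the
  slab's tail covers large effects at any scale, so ML happily trades
  scale against fraction.

The normal-slab fit identifies $\tau$ as the rms size of the nonzero
effects; that $\tau$ then parameterizes the Cauchy prior used for the
posterior. The slab is adopted only when it improves on the no-effect
model by a likelihood-ratio margin (2 df, p < 0.01) and the fitted effect
fraction exceeds 1 %; otherwise the scale falls to its floor (0.05 log2)
and effect-free data is shrunk maximally. Posterior summaries are
computed by trapezoidal quadrature on a per-gene grid that merges nodes
on the likelihood scale and on the prior scale, so neither a sharp
likelihood nor a sharp prior is under-resolved.

The **lfsr** (local false-sign rate) of a gene is the posterior
probability its effect has the wrong sign; an estimate of exactly zero
has lfsr 0.5. The **s-value** is the running mean of lfsr over all genes
at or below a gene's lfsr — the estimated rate of false sign among the
effects one would call at that threshold. When a fixed `prior_scale` is
supplied, the prior is the conjugate normal instead, with the textbook
closed-form posterior; the test suite pins this path to the closed form.

## Calling profiles and the ARR/ARI rule

Two profiles are built in: **strict** (s-value < 0.05,
|moderated LFC| > 1, both strict inequalities) and **permissive**
(s-value < 0.15, |moderated LFC| > 1, plus |batch LFC| > 0.5). A gene
shows an AGE / ENGRAFT / NICHE effect when its corresponding moderated
effect passes the profile; genes are tallied over all seven non-empty
combinations plus "unchanged".

Among age-affected genes, reversibility is assigned by the sign rule: a
significant niche effect **opposing** the age effect makes the gene ARR;
no significant niche effect makes it ARI; a significant niche effect of
the **same** sign is reported separately as `SAME_SIGN` rather than
folded into ARR — "restored toward the youthful state" implies reversal,
and same-sign genes (amplified, not restored, by the young niche) are a
scientifically distinct and rare class. The permissive profile's batch
rule acts as an eligibility filter for the reversibility call; its
direction (above vs below 0.5) is configurable because either filtering
convention is defensible, and the default keeps genes whose batch LFC
magnitude exceeds 0.5.

There is no partial-reversal grading: calls are binary at the threshold.

## RNA-stability deconvolution

Intronic reads report pre-mRNA abundance (transcription); exonic reads
report mature mRNA (transcription × stability). Both layers are stacked
into one NB GLM with `read_type × (time + age + time:age)` terms and
**read-type-specific size factors** (the documented co-normalization
choice: the global exon/intron capture ratio is a library property, not
biology). Condition coefficients at the intronic reference are
transcription effects; the `read_type:condition` interactions are
stability effects. For a saturated design the interaction equals the
separately fitted exonic-minus-intronic LFC, which the tests assert to
1e-3.

Genes whose total intronic count is below 10 are excluded (and listed in
the `excluded` attribute): with essentially no intronic signal the
decomposition is vacuous and the Wald statistics are heavy-tailed.

The driver classifier gates each component at |moderated LFC| > 0.5 with
s < 0.05. The 0.5 gate was fixed at half the canonical 2-fold planted
effect before any recovery was measured: a gate at the effect size
itself has roughly 50 % power by symmetry of the estimate around its
target, which would make the classifier useless exactly at the effect
size it is meant to detect.

## DMR calling

CpG calls from the two strands of a dyad are pooled onto the
forward-strand position. The genome is tiled into fixed, non-overlapping
100-bp windows aligned to coordinate 0 (fixed tiling is deterministic;
the window width has no preferred phase), and a window is testable when
the union of CpG positions across samples has at least 4 distinct sites.

Per replicate, window counts are pooled and converted to a proportion
with +0.5/+1 pseudo-counts (the beta likelihood is undefined at 0 and 1).
Proportions are regressed on condition by **beta regression** (logit
link, common precision), fitted by direct maximum likelihood with a Wald
p from the numeric Hessian; the implementation is cross-checked against
an independent beta-regression fit in the test suite. Replicates with
zero coverage in a window are dropped; windows with fewer than two
usable replicates per condition are left untested.

DMRs are the BH-corrected windows passing the hard reporting rules
|Δ| ≥ 0.40 and adjusted p < 0.01; direction is *gain* when the aged
proportion is higher. The filters are absolute — a window at Δ = 0.35
with p = 10⁻¹⁰ is never reported. Adjacent significant windows are not
merged by default (per-window counts are the reporting unit); a merge
flag exists for users who want contiguous regions.

cCRE annotation assigns a DMR the class of any candidate element within
300 bp (interval gap; overlap counts as 0), with PLS > ELS precedence on
ties and "other" when nothing is in range.

## Accessibility and regulatory domains

Peak summits within 200 bp are merged by single linkage (chains merge
transitively; the merged summit is the midpoint of the cluster's summit
span), and peaks are redefined as summit ± 500 bp. "±500 bp"
(1-kb peaks) is the default reading of a half-width-from-summit rule; a
250-bp half-width is selectable. The merge is idempotent: cluster
midpoints are necessarily farther apart than the gap.

Differential accessibility stacks peak and ±10 kb background counts into
one NB GLM with `region × condition` terms and region-type-specific size
factors; the interaction coefficient is the peak's change **beyond** the
local background change, so a locus-wide doubling cancels exactly (a
contract the tests assert). The background is the summit ± 10 kb region
minus all peak intervals, so a peak never contaminates its own
background. Significance requires BH-adjusted p < 0.05 and |LFC| > 1 on
the raw coefficient — thresholding the shrunken value against a fixed
cut would conflate the prior with the effect-size rule. Peaks with
all-zero background fall back to a peak-only model and are flagged.

Regulatory domains follow basal-plus-extension: a strand-aware basal
domain 5 kb upstream / 1 kb downstream of the TSS, extended on each side
to at most 1 Mb from the TSS, stopping at any other gene's basal domain.
Genes with byte-identical basal intervals (duplicate TSS) share their
extension rather than blocking each other. Peaks associate with every
gene whose extended domain they overlap by ≥ 1 bp (many-to-many), and
distance-binned counts use |summit − TSS| ≤ {10 kb, 100 kb, 1 Mb}.

Pileups average library-size-normalized (counts-per-million style)
coverage over ±2 kb around anchor midpoints, per condition;
depth-doubling a library leaves its normalized profile unchanged.
Quantile normalization was considered and not adopted — it would mask
exactly the global accessibility differences the comparison is about.

## Integration

DMRs count toward a gene when they fall in its extended regulatory
domain (gene linkage of DMRs is otherwise under-specified; a config
option can require cCRE co-annotation), and category means are taken
over **all** genes in a category, so means below 1 are expected.
Peak-overlap percentages are direction-matched: up-regulated genes are
paired with age-accessible peaks and down-regulated genes with
age-inaccessible peaks. An optional reproducibility filter restricts to
genes whose residual SD of log2 normalized expression is below 1.
Enrichment uses Fisher's exact test with BH across the battery; the
reported odds ratio is the sample cross-product ratio, not the
conditional MLE.

## The synthetic-data generator

The generator emulates the statistical *structure* of the experiment,
not its biology: four-group factorial NB counts with planted gene
classes (reversible genes have interaction = −age exactly; irreversible
genes have interaction = 0), paired exon/intron layers with
transcription-only and stability-only genes, clustered-CpG methylomes
with planted DMR windows (guaranteed ≥ 4 CpGs and the configured Δ), and
TSS-anchored peak landscapes with planted accessibility shifts and
stable backgrounds. One RNG stream per layer is derived from the master
seed by fixed offsets, so layers are independently reproducible and the
whole bundle is byte-stable under a fixed configuration.

Defaults: 2000 genes, 3 replicates per cell, 2 batches; baseline
expression log-normal (log2 mean 5, sd 2); dispersion from the trend
α = 0.05 + 5/μ; planted |effects| uniform on [1, 3] log2 with random
sign; batch effects N(0, 0.3) log2; library factors uniform on
[0.7, 1.4]. The exon/intron layer draws **one biological dispersion per
gene** (from the gene's expression) shared by both read types, because
the same replicate libraries underlie both layers; an intron/exon
capture ratio of 0.15 reflects typical total-RNA libraries. Methylome
defaults: one 200-kb chromosome, background CpG clusters every ~2 kb
with ~5 CpGs each (CpG-island-like clustering), coverage Poisson(20),
40 planted DMRs at Δ = 0.5, 3 replicates per condition, mild
replicate-level logit noise (sd 0.1). ATAC defaults: 200 genes spaced
~100 kb apart, ~3 peaks per gene at mostly-proximal signed distances,
2 young + 2 aged samples, 10 % differential peaks at |LFC| = 1.5; an
`enrich_pattern` switch plants extra age-accessible peaks near
upregulated-irreversible genes for integration tests.

**What the simulations do not emulate:** count outliers and sample
contamination, correlated gene modules, GC/length biases, partial
reversal, non-CpG methylation, copy-number structure, fragment-level
ATAC biases, or any cell-type heterogeneity. Passing recovery tests on
this generator demonstrates the estimators and rules are implemented
correctly and calibrated under the stated noise model — not that real
tissue data will reach the same operating characteristics.

## Statistical power at the reference conditions

With three replicates per cell, a median baseline of ~32 counts and the
default dispersion trend, the theoretical standard errors are ≈ 0.57
(age) and ≈ 0.82 (niche interaction) log2. Planted effects are uniform
on [1, 3] log2 while the calling gate is |moderated LFC| > 1, so genes
planted near the gate are intrinsically borderline: even an oracle using
the true effects and true standard errors with *no* shrinkage recovers
only ~70–80 % of planted reversible genes jointly across both gates.
Any calibrated shrinkage — required for the false-call control that the
same thresholds are supposed to provide — lowers this further. The
measured operating point of the pipeline at the defaults is roughly
60–70 % recovery of planted reversible/irreversible genes with ~1–2 %
false age calls on effect-free data; users should read ARR/ARI fractions
as conservative under-counts near the LFC gate, and prefer deeper
replication when absolute recovery matters.

## Numerical choices

- IRLS convergence at 100 iterations; covariance from the weighted
  least-squares information at convergence, honoring QR pivoting.
- Dispersion optimizer bounds: log α ∈ [log 10⁻⁸, log 30].
- Posterior quadrature: likelihood nodes at ±8 SE (step 0.1 SE) merged
  with prior nodes at ±50 τ (step 0.25 τ), trapezoidal weights.
- Beta regression: L-BFGS-B with box bounds on the logit coefficients
  (±12, ±24) and log precision ([log 0.5, log 10⁴]); starting values
  from empirical logits and a method-of-moments precision.
- Ties in cCRE annotation resolved by fixed precedence; all interval
  work is 0-based half-open internally, with 1-based methylation
  positions converted at the file boundary (noted once per session).

The test suite exercises the estimators at reduced problem sizes chosen
for coverage per unit time — typically 250–2000 genes, one 60–200 kb
synthetic chromosome, 40–200 ATAC genes — with brute-force oracles
(grid-search likelihood maximizers, step-up BH, interval scans,
hypergeometric enumeration) pinning the core computations.

## Known limitations

- The reversibility call is binary; partially restored genes near the
  LFC gate land on either side by sampling noise.
- The s-value machinery assumes the fitted prior family describes the
  effect distribution; on data whose effects are strongly bimodal the
  normal-slab scale is a compromise.
- The stacked stability and accessibility models share one dispersion
  across read/region types per feature; strongly type-specific
  overdispersion would be mis-calibrated.
- DMR calling tests windows independently; spatially correlated
  methylation is handled only through the optional merge step.
- The batch model is additive per gene; batch-by-condition interactions
  are not modeled.
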