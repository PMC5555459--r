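---
title: "Nucleus and chromocenter morphometry, heritability, and QTL mapping with chromomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleus and chromocenter morphometry, heritability, and QTL mapping with chromomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromomorph)
```

## The problem

In *Arabidopsis* interphase nuclei, repeat-rich heterochromatin condenses
into a handful of bright DAPI-stained foci, the chromocenters, embedded in
dimmer euchromatin. How condensed that heterochromatin is — and how large
and round nuclei and chromocenters are — varies between natural accessions
and is under genetic control. `chromomorph` implements the full quantitative
chain for dissecting that variation:

1. **Morphometry** of 8-bit microscopy images: per-object area, mean DAPI
   intensity ("density"), perimeter, roundness, heterogeneity, and the
   relative heterochromatin fraction (RHF) per nucleus.
2. **Population statistics** over recombinant inbred lines (RILs): outlier
   filtering, per-line aggregation, broad-sense heritability from one-way
   variance components, trait correlation networks, transgression ratios.
3. **Composite interval mapping** (CIM) with forward–backward cofactor
   selection, a cofactor exclusion window, and permutation-derived
   genome-wide LOD thresholds, yielding interval calls (start, end, top,
   LOD, additive effect, explained variance).
4. **Near-isogenic line (NIL) confirmation**: classifying each NIL's trait
   shift against the recurrent background and using introgression geometry
   to confirm QTL and refine their borders.

Because raw microscopy from such studies is rarely redistributable, the
package ships a first-class synthetic-data generator that renders nucleus
images with exact ground-truth masks and simulates RIL populations with
planted QTL, so every downstream stage is testable end to end.

## Morphometric model

For an object (nucleus *nu* or chromocenter *cc*) with pixel set $S$ and
image intensities $I$:

* Area $A = |S|$ (pixels; holes in the nucleus outline are filled before
  measurement, so area counts object pixels only).
* Intensity $\bar I = \frac{1}{A}\sum_{p \in S} I(p)$ — the quantity some
  output tables also label *density*; the two names denote one measurement.
* Perimeter $P$: Crofton 4-direction estimate,
  $P = \frac{\pi}{4}\left(n_0 + n_{90} + \frac{n_{45}+n_{135}}{\sqrt 2}\right)$,
  where $n_\theta$ counts intercept runs along direction $\theta$. This
  estimator is near-unbiased on digital discs, so the isoperimetric bound
  below holds to within raster error. A boundary-pixel count
  (`perimeter_method = "boundary_pixels"`) is provided for compatibility
  with legacy macros whose "outline length in pixels" is ambiguous.
* Roundness $= P^2 / (4\pi A)$; an ideal circle scores exactly 1 and any
  other shape scores above it.
* Heterogeneity $=$ fraction of $p \in S$ with
  $|I(p) - \bar I| > 0.10\,\bar I$ (strict inequality). We implement this
  definition literally; note that in the source literature the verbal
  polarity ("low value = high heterogeneity") and the formula disagree, and
  we follow the formula.
* RHF $= \dfrac{\sum_{cc} A_{cc}(\bar I_{cc} - b)}{A_{nu}(\bar I_{nu} - b)}$
  with $b$ the background intensity — the background-corrected share of the
  nucleus's DAPI fluorescence held in chromocenters. The numerator sums over
  all chromocenters of the nucleus (RHF is "the proportion of DNA in
  chromocenters", which requires the sum). Noise can push estimates outside
  $[0,1]$; values are clipped with a warning.

Background $b$ is the median intensity outside all nuclei after excluding a
2-px dilation rim, computed per image.

## Segmentation

`segment_nuclei()` smooths with a Gaussian (`smoothing_sigma`, default 2 px),
thresholds globally with Otsu's method on the integer 0–255 histogram,
fills holes, removes objects below `min_nucleus_area` and (by default)
objects touching the border — truncated objects would bias area and
perimeter. Labeling is 8-connected. Using whole-intensity histogram bins
makes the Otsu split exactly equivariant under integer intensity shifts, so
segmentation is invariant to additive exposure offsets (up to 8-bit
clipping).

`segment_chromocenters()` thresholds within each nucleus at
mean $+ k\cdot$SD of that nucleus's own pixels (`cc_threshold_k`, default
2): chromocenters are *relatively* bright foci, so a per-nucleus relative
cutoff tracks nucleus-to-nucleus intensity differences. Whether the original
macros thresholded per nucleus or globally is not documented; both are
available (`cc_threshold_scope`), per-nucleus being the default. Blobs
below `min_cc_area` (default 4 px) are discarded; every chromocenter label
carries its parent nucleus.

## Synthetic data: what it emulates and what it does not

`render_nucleus_image()` paints non-overlapping elliptical nuclei
(intensity ~90 of 255, emulating deliberately under-exposed captures at
30–50% of the gray scale) containing 0–12 brighter circular chromocenters
on a dark background, adds i.i.d. Gaussian noise, and clips to 8 bits. The
returned masks are the exact painted geometry. Chromocenter centres are
laid on a jittered hexagonal lattice inside the ellipse; plain rejection
sampling cannot reach 12 well-separated discs in a realistic nucleus (the
random sequential adsorption jamming limit is ~0.55 coverage).

The generator does **not** emulate: touching nuclei, nucleoli, irregular
("type 2/3") diffuse chromocenters, intensity gradients, or correlated
noise. Passing segmentation tests therefore demonstrates correctness of the
thresholding/labeling/measurement chain on well-formed fields, not
robustness to every real-world artefact.

`simulate_ril_genotypes()` models each selfed RIL as a Markov chain along
each chromosome: first marker A/B with probability ½, switch probability
$R = 2r/(1+2r)$ between adjacent markers, with $r$ from the Haldane map
function $r = (1-e^{-2d/100})/2$. The Haldane–Waddington transform gives the
same stationary two-locus behaviour as simulating the full selfing pedigree
while staying testable in closed form. Epistasis, dominance, segregation
distortion and residual heterozygosity are out of scope (RILs are treated as
fully homozygous).

`simulate_trait_values()` attaches each planted QTL to its nearest marker
(making ground truth unambiguous for recovery tests): line value
$= \sum_i a_i x_i + N(0, \sigma_\ell^2)$ with $x_i = \pm 1$, and each
nucleus adds $N(0, \sigma_n^2)$. Genotype class means therefore differ by
$2a$, matching the convention that the additive effect is the A-allele
deviation from the population mean. The table carries both the population
variance ratio (`h2_true`) and the ratio the draw actually realised
(`h2_realized`): with ~50 lines, the sample variance of the realised line
effects wobbles around $\sigma_\ell^2$ by ~20% (chi-square), and recovery
of the ANOVA estimator is judged against what was actually planted in the
dataset, not against the population parameter the generator was aimed at.

## Population statistics

Two single-pass outlier rules are implemented because the source protocols
used both: the central 95% empirical interval (default upstream of QTL
mapping) and mean ± 2 SD (used for distribution summaries). Each is applied
once, with statistics computed on the input — no iteration — so reapplying
with the original statistics is a no-op. Line inclusion defaults (≥26
nuclei from ≥2 plants) mirror the study design the pipeline targets.

Broad-sense heritability uses one-way method-of-moments components with the
unbalanced-design correction $n_0 = (N - \sum n_i^2/N)/(k-1)$:
$\hat\sigma^2_w = \mathrm{MSW}$,
$\hat\sigma^2_b = \max(0, (\mathrm{MSB} - \mathrm{MSW})/n_0)$, and
$H^2 = \hat\sigma^2_b/(\hat\sigma^2_b + \hat\sigma^2_w)$. In a one-way
layout a type-3 ANOVA reduces to this; the closed form is preferred over
REML because the estimand is defined as this variance ratio and the
closed form is directly testable. $H^2$ is invariant under affine trait
transformations, and the negative-component case truncates to 0.

Correlation networks report pairwise Pearson $r$ with two-sided p-values
over per-line means (parents and F1 may be pooled as extra rows), starred
at 0.05/0.01/0.001/0.0001 with no multiple-testing correction — edges
reproduce the raw star convention of the tables they emulate. Welch's
unequal-variance t-test, a 2×2 Pearson chi-squared for size-class
comparisons (continuity correction off by default, matching the classical
statistic), Shapiro–Wilk normality screening (the source's normality test
is unnamed; Shapiro–Wilk is our stand-in), and a compact-letter-display
utility round out the reporting layer.

## Composite interval mapping

Genotype probabilities on the evaluation grid (default step 1 cM, markers
always included) condition on the nearest non-missing flanking markers
under the same Markov model used for simulation; at observed markers they
are 0/1 indicators, beyond terminal markers the single nearest marker is
used, and a fully missing chromosome falls back to ½ with a warning.

Cofactor selection is stepwise linear regression on marker scores
($\pm 1$, expected scores where missing): forward-add the most significant
marker while its partial F-test p < `p_in` (0.05), then backward-drop any
included marker with p > `p_out` (0.05), to convergence. The cap
`max_cofactors` defaults to $\lfloor\sqrt{n}\rfloor$, guarding rank
deficiency at the 46-line scale. Ties break deterministically (smallest p,
then lowest marker index), so runs are bitwise reproducible.

The scan is Haley–Knott regression: at each position, phenotype on active
cofactor scores plus the expected genotype score $2P(A)-1$, where cofactors
within `window_cM` (10 cM) of the position on the same chromosome are
excluded. $\mathrm{LOD} = \frac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$,
ADD is the genotype-score coefficient, and $R^2$ is reported against the
total phenotypic variance of the line means (TSS) by default — the
literature rarely states the denominator, so `r2_denominator` exposes the
choice. With zero cofactors and the step aligned to markers the scan
reduces exactly to single-marker regression, which is the oracle the tests
pin it to ($10^{-8}$ agreement). Haley–Knott rather than EM maximum
likelihood: for homozygous RIL panels at these effect sizes the LOD
difference is negligible and the regression form is testable in closed
form. Positions whose active model leaves fewer than 3 residual degrees of
freedom are skipped with a warning.

Permutation thresholds permute the phenotype across lines, re-run the full
procedure (cofactor re-selection included — the statistically exact null;
`reselect_cofactors = FALSE` reuses the unpermuted cofactors as a fast
approximation), and take the order statistic of the genome-wide maxima with
index $\lceil (B+1)(1-\alpha)\rceil$. By exchangeability a fresh null scan
exceeds that cut with probability at most $\alpha$; the interpolated 95%
quantile is slightly anticonservative at $B = 200$. A threshold belongs to
the trait whose permutations produced it — calibration holds trait by
trait, which is how the tests verify the 5% genome-wide level (each null
trait against its own threshold). Calls are maximal runs of grid positions
with LOD at or above the threshold; the top is the leftmost argmax, and
LOD/ADD/$R^2$ are reported at the top. Runs on different chromosomes never
merge; colocation of two calls is closed-interval intersection.

## NIL confirmation

A NIL carries donor-genotype (B-type) introgressions in the recurrent
(A-type) background, so a QTL whose ADD (A-allele effect) is positive is
expected to show a *down* shift in a covering NIL, and vice versa — the
expectation is $-\mathrm{sign}(\mathrm{ADD})$. Each NIL is classified by a
two-sided Welch test (strong p < 0.01, weak p < 0.05). A call is
*confirmed* when at least one covering NIL shifts significantly (weak
suffices, matching the confirmation conventions of the tables this
reproduces) in the expected direction; *opposite_sign* when all covering
significant shifts contradict it; *not_confirmed* when all covering NILs
are ns; *not_covered* when no introgression intersects the interval. The
refined region is the QTL interval intersected with the union of confirming
introgressions, minus introgressions of covering-but-ns NILs — only
covering NILs subtract, and subtraction keeps shared boundary points, so
the classical "significant in [150, 173.2], silent in [150, 162], hence
the locus lies in [162, 173.2]" border logic falls out of the set
arithmetic. The result can in principle be several segments; it is returned
as a segment table. Refinement can never widen the original interval.

## Worked example

```{r example, eval = FALSE}
library(chromomorph)

map  <- make_genetic_map(5, 100, 5)
geno <- simulate_ril_genotypes(map, 46, seed = 1)
tt   <- simulate_trait_values(
  geno, map, data.frame(chromosome = 2, position_cM = 40, effect = 1),
  sigma_line = 0.9, sigma_nucleus = 2, n_nuclei_per_line = 30, seed = 2)

ls    <- line_summary(tt)
pheno <- setNames(ls$mean, ls$line_id)
grid  <- genotype_probs(map, geno, step_cM = 1)
res   <- qtl_scan(grid, pheno, cim_config(n_permutations = 200, seed = 3))
res$calls
```

`run_pipeline(pipeline_config(...))` chains all stages (simulation, image
rendering, segmentation, morphometry, line statistics, heritability, scan,
threshold, calls, NIL confirmation) and writes every artifact plus a
manifest with config and checksums; identical configuration and seed give a
byte-identical manifest.

## Numerical choices and degenerate inputs

* All tables are TSV (UTF-8, "." decimal); genotypes travel in a rotated
  CSV (one row per marker); cM intervals are closed, matching interval-call
  semantics.
* A constant image segments to an empty mask (not an error); a constant
  phenotype yields no cofactors, an all-zero LOD profile and a zero
  threshold.
* All randomness flows from explicit seeds; there is no hidden global
  state, and permutation streams are owned by the configuration seed.
* Problem sizes used by the validation suite — chosen as study-scale
  defaults: 46-line panels on 5×100 cM maps for mapping checks, 100
  rendered fields for segmentation recovery, 200 permutations per trait
  for level checks, 20–100 seed envelopes for recovery rates.

## Known limitations

* No watershed splitting: touching nuclei are not separated (fields of
  spread nuclei are assumed).
* No 3D/Z-stack support; single-channel 2D images only.
* Heritability is the one-way variance ratio, not a mixed-model estimate;
  plant-within-line structure is carried in the tables but not modelled.
* The scan fits a single-QTL working model per position; multiple-QTL
  model fitting and epistasis scans are out of scope.
* The visual nucleus type-1/2/3 classification (and the Heterochromatin
  Index based on it) has no quantitative published rule and is deliberately
  not implemented.
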