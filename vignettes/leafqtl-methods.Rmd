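---
title: "Methods: leaf trait modules, marker-based QTL scans and expression networks"
author: "leafqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf trait modules, marker-based QTL scans and expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafqtl)
```

# Scope and data model

`leafqtl` analyses leaf morphology in an outbred F1 (pseudo-testcross)
mapping population. Four typed containers carry the data: a `LinkageMap`
(markers ordered by linkage group and centimorgan position), a
`GenotypeMatrix` (per-marker genotype class labels, each marker declared as
`testcross2` — heterozygous in one parent, segregating aa:ab = 1:1 — or
`intercross3` — heterozygous in both, AA:Aa:aa = 1:2:1), a `PhenotypeTable`
(14 quantitative leaf traits tagged by module), and an `FpkmExperiment`
(a `SummarizedExperiment` of non-negative FPKM values, genes × tissues).
Validity methods enforce the invariants (unique ids, declared labels,
non-negative expression, ordered map positions) at construction, so
downstream code can assume clean inputs.

The trait schema has three modules: size (LA cm², LP cm, LL cm, LW cm),
shape (LLo, AR, P_L, P_LW, Rect, Cir) and colour (R, G, B, CV). The
chart-matched colour *name* is deliberately out of scope: it is a
categorical judgement against a physical reference chart, not an image
measurement.

# The marker-based likelihood-ratio scan

## Model

At a marker with genotype classes $j = 1, \dots, J$ the phenotype of an
individual in class $j$ is modelled as $N(\mu_j, \sigma^2)$, giving the
product likelihood $L(\Phi \mid y) = \prod_j \prod_{i \in j} f_j(y_i)$ with
$\Phi = (\mu_j, \sigma^2)$. The null collapses all class means to the grand
mean. Both fits are maximum likelihood: class means (or the grand mean) and
variance with divisor $n$, so

$$\mathrm{LR} \;=\; 2(\ell_1 - \ell_0) \;=\; n \ln \frac{RSS_0}{RSS_1}
 \;=\; n \ln \frac{1}{1 - R^2},$$

where $R^2$ is the one-way between-class coefficient of determination. PVE
is reported as $100\,(1 - RSS_1/RSS_0)$, and the genetic effects are
$\Delta = \mu_2 - \mu_1$ for two classes and
$a = (\mu_3 - \mu_1)/2$, $d = \mu_2 - (\mu_1 + \mu_3)/2$ for three, in the
declared class-label order. Each trait is scanned univariately; the variance
parameter is a scalar per trait. QTLs are assumed to sit at marker positions
— the map is dense enough that interval imputation between markers would add
little, and no imputation is performed.

Markers become ineligible when any declared class has fewer than
`minClassN` (default 5) informative individuals, or fewer than two classes
are observed; they are reported as skipped with reason `sparse_class`, never
silently fitted. A marker with zero residual variance under the alternative
is flagged with infinite LR and excluded from permutation maxima.

## Permutation threshold

Genome-wide significance comes from shuffling the phenotype vector against
whole individuals (preserving the LD structure among markers) `nPerm` times
and recording each permuted scan's maximum LR; the threshold is the
$\lceil (1-\alpha)\, n_\mathrm{perm} \rceil$-th order statistic of those
maxima. Thresholds are per trait, with no across-trait multiplicity
correction — the scans are reported trait by trait. The calibration study
(`nullCalibrationStudy`) verifies on 200 null datasets
(n = 179, 20 linkage groups × 20 markers, 300 permutations) that the
fraction of null scans exceeding their own threshold is close to
$\alpha = 0.05$; the acceptance band [0.02, 0.09] reflects the Monte-Carlo
error of that design.

## Co-location and Venn counts

A QTL call is a marker at or above its trait's threshold. Two traits
co-locate when they call the same marker (window 0, the default) or markers
within `colocWindow` cM on one linkage group. Venn counts per module
(size/shape/colour) use distinct called marker identities, with pairwise and
triple intersections.

# Morphometrics

Size traits come from the binary mask. Area is foreground pixel count times
scale². Perimeter is a sub-pixel contour length: the mask is box-smoothed
(3×3 mean, two passes) and the 0.5 level set is traced with marching squares
(`grDevices::contourLines`), closing any open loop. Raw boundary tracing of
a binary image overestimates perimeter by ~5–8% because the staircase
alternates only 0° and 45° segments, which would bias circularity downward
by >10%; smoothing first places the interpolated vertices on the true edge
and brings the error under 0.5% for circles and ellipses at any orientation.
A known limitation: the tracer has a scale-invariant residual bias of about
0.3%, so the perimeter error *saturates* there rather than vanishing as
resolution grows (area error does shrink with resolution). Length and width
are extents of the foreground pixel cloud along its principal axes
(plus one pixel for the half-pixel footprint on each side), so the bounding
rectangle is oriented, matching the rectangularity definition; axis ordering
enforces LW ≤ LL. Connected-component labelling and hole filling use
EBImage; masks with more than one component are rejected with the component
sizes listed.

Colour traits are channel means over foreground pixels, with
CV = 65536·R + 256·G + B computed from the (fractional) means. Lobe count is
an input — in the field it is counted manually, and automated lobe counting
is deliberately not implemented.

# Trait statistics and networks

`summarizeTraits` uses the sample (n−1) standard deviation, g1 skewness
$m_3/m_2^{3/2}$ and excess kurtosis $m_4/m_2^2 - 3$; this parameterization is
consistent with published leaf-trait tables whose kurtosis values are
negative. CV is $100\,s/\bar{y}$. Constant traits report zero
skewness/kurtosis/CV with a `degenerate` flag rather than NaN.

Both networks share one correlation engine: Pearson r on pairwise-complete
observations, two-sided p from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$
degrees of freedom (the exact t transform; Fisher's z would differ only in
the far tails at these sample sizes). The trait network keeps edges with
$|r| \ge 0.10$ **and** $p \le 0.05$; no multiple-testing correction is
applied across the 91 trait pairs because the reported screen is defined on
raw p-values. The co-expression network keeps $|r| \ge 0.95$ **and**
$p < 0.001$, implemented literally even though with few samples the p
condition dominates: at n = 6 tissues, r = 0.95 gives p ≈ 0.0037, so such a
pair is rejected. At n = 178 the trait network's p condition likewise
implies the |r| cutoff, so on independent noise the expected retention rate
equals p_max exactly — the tests therefore compare the realized rate to
p_max within Monte-Carlo error rather than asserting strict inequality.
Edge lists are undirected, simple, stored with node_a < node_b, and
filtering is monotone in both thresholds.

Expression clustering transforms FPKM to log2(FPKM+1) and z-scores each gene
(a standard variance stabilization; the raw-FPKM scale would let a handful
of highly expressed genes dominate the distances), then applies
average-linkage hierarchical clustering on Euclidean distances with a cut at
k = 3 by default. Rows are processed in gene-id order so dendrogram ties
break deterministically. 2^−ΔΔCt fold changes follow the usual two-step
differencing against a reference gene and calibrator sample; shifting all Ct
values by a constant cancels exactly.

# The synthetic-data generator

The generator's defaults are the study conditions the pipeline is meant to
face, not tuning knobs.

* **Cross**: 179 progeny; 20 linkage groups; evenly spaced markers with
  Haldane recombination $r = (1 - e^{-2d/100})/2$ (no interference — the
  simplest map function absent evidence for interference, with the spacing
  parameter as the hook for alternatives); a 50/50 split of test-cross and
  inter-cross markers (the true proportion among segregating SNPs is not
  documented, so this is a declared configuration, not a claim); coupling
  phase throughout. The desk-scale default is 100 markers per group at
  1.5 cM (2 000 markers, ~150 cM groups); the full 9 593-SNP scale is
  supported but not default. The simulation studies use 20 markers at 5 cM
  (95 cM groups) to keep 300-replicate designs in tens of seconds.
* **Phenotypes**: trait value = sum of planted class means at the
  individual's genotypes + $N(0, \sigma_r^2)$. The truth record carries the
  theoretical PVE from the expected segregation frequencies
  (e.g. test-cross means (0, 2) with $\sigma_r = 2$: between-class variance
  1, total 5, PVE 20%).
* **Leaf images**: the outline is the polar curve
  $\rho(\theta) = E(\theta)\,(1 + \alpha\,|\cos(k\theta/2)|^{p})$ around the
  ellipse $E$ with semi-axes L/2, W/2, so the lobe count k maps one-to-one
  onto the LLo trait; $\alpha < 0.6$ guards against self-intersection.
  Ground truth (area, perimeter, extents) comes from a 4096-vertex polygon
  of the same curve; the raster must give the long axis at least 200 px.
  Default dimensions and colour (15 × 13 cm, lobes ≈ 3, RGB ≈ (57, 74, 36))
  sit at the population means of the trait table the package targets.
* **Expression**: clusters of genes share a tissue template (up/down/flat at
  `baseFpkm` × `foldUp`^{±1}) with multiplicative log-normal noise
  (sd 0.3 on the natural-log scale — modest biological noise); the default
  emulates 75 candidate genes across five tissues in three clusters
  (14/16/45). The generating cluster is stored in `rowData()$cluster`.

What the generator does **not** emulate: genotyping error, segregation
distortion, epistasis, G×E, marker phase ambiguity, leaf petioles,
segmentation from cluttered backgrounds, or read-level expression noise.
Tests passing on generator output therefore demonstrate correctness of the
estimators under the stated model, not robustness to those artefacts.

# Reproducibility and numerical choices

One master seed drives every stage through `stageSeed(seed, stage)`, which
scrambles the (seed, stage-name) pair through a single Mersenne-Twister
draw. An earlier linear hash left fixed arithmetic offsets between the
seeds of different stages and measurably correlated their streams across
replicates (the null calibration drifted to 0.01 instead of 0.05); the
scrambled version restores exchangeability. Floats are serialized at 6
significant digits, making read→write→read cycles bit-stable. RSS values in
the vectorized scan are clamped at a relative tolerance of $10^{-12}$
before logs; phenotype columns with zero variance are an error, and
within-scan zero residual variance is flagged rather than propagated.

# Problem sizes

The bundled studies use 200 null datasets × 300 permutations and 100
recovery datasets (n = 179, 400 markers each), about a minute on one CPU;
the morphometrics suite rasterizes shapes at 300–460 px. These sizes hold
the Monte-Carlo error of each check comfortably inside its acceptance band
while keeping a full run at desk scale.
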