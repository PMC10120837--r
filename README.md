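# leafqtl

Leaf morphology — size, shape and colour — is a classic quantitative-genetics
target: in an outbred F1 (pseudo-testcross) mapping population of a tree
species, each leaf trait segregates with the markers that tag its underlying
loci. `leafqtl` is an R package for dissecting that architecture end to end:

* **morphometrics** — the 14 quantitative leaf traits measured from an RGB
  image plus binary mask, organized into three modules:
  size (area LA, perimeter LP, length LL, width LW), shape (lobe count LLo,
  aspect ratio AR = LL/LW, P_L = LP/LL, P_LW = LP/(LL+LW), rectangularity
  Rect = LA/(LL·LW), circularity Cir = 4πLA/LP²), and colour (masked channel
  means R, G, B and the composite CV = 65536·R + 256·G + B);
* **single-marker QTL scans** — at each marker the trait is modelled as a
  mixture of genotype-class normals with common variance,
  L(Φ|y) = ∏ⱼ ∏ᵢ fⱼ(yᵢ), Φ = (μⱼ, σ²); the test statistic against
  H₀: μⱼ = μ is the log-likelihood ratio LR = n·ln(RSS₀/RSS₁), with
  phenotypic variance explained PVE = 100·(1 − RSS₁/RSS₀) and genetic
  effects Δ = μ₂ − μ₁ (test-cross 1:1 markers) or a = (μ₃ − μ₁)/2,
  d = μ₂ − (μ₁+μ₃)/2 (inter-cross 1:2:1 markers);
* **permutation thresholds** — genome-wide significance from the upper order
  statistic of per-permutation maximum LRs, plus QTL calling, cross-trait
  co-location and per-module Venn counts;
* **networks** — the thresholded trait-correlation network
  (|r| ≥ 0.10, p ≤ 0.05) with module annotations, the gene co-expression
  network (|r| ≥ 0.95, p < 0.001) with hub ranking, FPKM heat-map clustering,
  and 2^−ΔΔCt qPCR fold changes;
* **simulation** — an F1 cross simulator (Haldane recombination, test-cross
  and inter-cross markers), phenotypes with planted QTLs and known
  theoretical PVE, parametric lobed-leaf images with exact polygon ground
  truth, and block-structured FPKM matrices — so every stage is testable
  without external data.

## Worked example

Simulate a 179-progeny cross, plant one circularity QTL with a theoretical
PVE of 20%, scan, and call QTLs against a 1000-permutation genome-wide
threshold:

```r
library(leafqtl)

cx  <- simulateCross(crossSpec(nProgeny = 179, linkageGroups = 5,
                               markersPerGroup = 20, markerSpacing = 5, seed = 20))
qtl <- qtlSpec("Cir", "lg03_m010", classMeans = c(0, 0.12),
               residualSd = 0.12, module = "shape")
sim <- simulatePhenotypes(cx$geno, qtl, seed = 20)

scan <- genomeScan(sim$pheno, cx$geno, cx$map, "Cir")
scan <- permutationThreshold(scan, sim$pheno, cx$geno, cx$map,
                             nPerm = 1000, alpha = 0.05, seed = 20)
scan
#> ScanResult for trait 'Cir': 100 markers scanned, 0 skipped
#>   genome-wide threshold (alpha = 0.05, 1000 permutations): LR = 13.697; 9 call(s)

qtlCalls(scan)[6, c("marker", "lg", "pos", "segType", "n", "LR", "pve", "delta")]
#>       marker   lg pos    segType   n       LR      pve     delta
#> 50 lg03_m010 LG03  45 testcross2 179 47.26973 23.20854 0.1259484
```

The planted marker is the scan maximum: LR = 47.3 far exceeds the
permutation threshold of 13.7, the estimated PVE (23.2%) brackets the
planted 20%, and the estimated class-mean gap Δ = 0.126 recovers the
planted 0.12. The flanking markers (5 cM away, genotype correlation ≈ 0.9)
are also called — the expected linkage shadow of a single true locus.
`plotScan(scan)` draws the Manhattan-style LR profile with the threshold
line, and `callAndColocate()` aggregates calls across traits into
co-location tables and module Venn counts.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/leafqtl.R`
(`leafqtl.R <simulate|measure|stats|scan|network> --config cfg.yaml --seed 1 --out dir`).

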