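---
title: "Methods: spike-in absolute quantification and dual-branch community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in absolute quantification and dual-branch community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htqs)
```

## The quantification model

Amplicon read counts are compositional; to obtain absolute abundances,
synthetic spike-in standards with conserved 16S primer-binding regions
are added to each sample's DNA at known copy numbers before PCR. `htqs`
assumes the spike-ins appear as ordinary OTUs in the count table, flagged
`spike_in` in the taxonomy.

Per sample, `fit_standard_curves()` regresses
$y = \log_{10}(\text{spike-in reads})$ on
$x = \log_{10}(\text{added copies})$ by ordinary least squares,
$y = a x + b$. Base-10 logarithms are used throughout because the
standards are decade-spaced. Spike-ins with zero reads are excluded from
the fit (no pseudocounts enter the calibration) and reported per sample;
fewer than three positive spike-ins is a calibration error, not a
warning, because a two-point line has no residual degrees of freedom.

`estimate_absolute_abundance()` inverts the curve for each biological
OTU with positive reads,
$Y_\mathrm{otu} = 10^{(\log_{10}(\text{reads}) - b)/a}$, and scales to
concentration units,
$$AB_\mathrm{otu} = \frac{Y_\mathrm{otu}}{R \cdot V}
\quad [\text{copies } \mathrm{L}^{-1}],$$
where $R \in (0,1]$ is the recovery ratio — the fraction of the DNA
extract that entered library preparation — and $V$ the liters of water
filtered. Dividing by $R$ scales the sequenced aliquot back up to the
whole extract; dividing by $V$ converts copies to a concentration. Zero
reads map to zero copies. A slope $a \le 0$ is rejected as a
non-monotone curve. Because the inversion is strictly increasing for
$a > 0$, the OTU ranking by copies per liter inside one sample equals
the ranking by relative abundance — the two branches can only disagree
*across* samples, where $R$, $V$, and the curve parameters differ. The
test suite carries a constructed two-sample case where an OTU's relative
abundance rises while its copies per liter fall.

Cleaning (`clean_biological()`) removes spike-in, archaeal, and
chloroplast OTUs plus *global* singletons (total count exactly 1 over
all samples, the convention of the usual upstream clustering tools);
unassigned OTUs are retained. The relative branch is rarefied
(`rarefy()`, sampling without replacement, exact per-sample totals); the
quantitative branch uses the unrarefied cleaned counts — rarefaction
would discard calibrated information, and the spike-in curve already
absorbs depth differences. This split is configurable.

## The synthetic generator: what it emulates

`generate_community()` + `simulate_sequencing()` state a world modeled
on a trans-basin surface transect:

* 20 stations on a monotone west-to-east transect crossing the
  antimeridian (longitudes 158.77°E to 126.21°W, latitudes declining
  28.96°N to 9.31°N), which exercises the wraparound handling in the
  great-circle code.
* Per-OTU lognormal base abundances (`lognormal_sigma = 2`, a typical
  skew for marine surface communities), rescaled so per-sample totals
  fall uniformly in 1.86×10^8^–1.14×10^9^ copies L^-1^.
* Spatial structure: each OTU's log abundance adds i.i.d. noise plus
  `spatial_decay` times a smooth random function (linear + one sine
  period) of normalized along-track distance. At `spatial_decay = 0`
  composition is spatially unstructured (Mantel r ≈ 0 against
  geographic distance); larger values give the distance-decay of
  similarity that biogeographic surveys report. The default 1.5 yields
  Mantel correlations against geodistance around 0.6–0.8, the range
  typical of basin-scale surveys.
* Environmental variables as bounded smooth gradients (logistic-squashed
  linear + sine fields) inside the configured ranges (temperature
  28.55–29.68 °C, salinity 33.66–35.12, NOx 0.014–0.104 µmol/L, DRP
  0.01–0.15 µmol/L, Si(OH)4 0.57–1.93 µmol/L, Chl a 5.4–48.8 ng/L,
  bacterial abundance 1.15–1.68×10^5^ cells/mL), filtered volumes
  4.25–7.3 L.
* Sequencing is **multinomial**: the pool is the spike-in panel at its
  added copies plus each OTU at `true_abundance * V * R` copies, scaled
  by per-taxon lognormal amplification efficiencies (CV = `noise_cv`,
  shared across samples — a PCR primer-bias surrogate; its magnitude is
  a free knob, not an estimate). Reads compete for the fixed depth, so
  library-size conservation and the relative/quantitative distinction
  are real. `sampling = "expected"` replaces the multinomial draw with
  largest-remainder apportionment of the expected counts — the
  noiseless limit used by the calibration-recovery checks.

**The recovery-ratio scale.** The generator draws
$R \sim U(3\times10^{-4}, 1.5\times10^{-3})$. With community totals of
order 10^9^ copies L^-1^ and 4–7 L filtered, an $R$ of order one would
put ~10^9^ biological copies in the sequenced pool against at most
10^6^ spike-in copies, and every spike-in would receive essentially zero
reads at any realistic depth — calibration would be impossible, which
contradicts how these experiments behave (strong linear curves across
all nine standards). Physically, $R$ is the sequenced-template fraction
of the extract: nanogram-scale PCR template from a microgram-scale
extract, i.e. 10^-4^–10^-3^. With this scale the spike panel takes a
realistic share of reads and the pipeline's estimate
$Y_\mathrm{otu}/(R V)$ recovers the true concentrations.

What the generator does **not** emulate: read-level errors and chimeras,
taxon-specific 16S copy-number variation, sample-specific (rather than
shared) PCR bias, realistic taxonomies beyond synthetic lineage labels,
and mesoscale oceanography beyond smooth gradients. A green end-to-end
test therefore establishes that the *computations* are correct and
internally consistent, not that the field protocol is unbiased.

## Numerical and statistical conventions

* **Chao 1** uses the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ by default (classic form by flag);
  it is defined even when no doubletons occur.
* **Shannon** defaults to log base 2, the historical default of the
  common alpha-diversity scripts; the printed index ranges of transect
  studies (≈4.5–5.8) are consistent with base 2. Natural log is
  selectable.
* **Faith's PD** includes the path to the root (the historical default
  of amplicon toolchains); a no-root variant subtracts the chain from
  the root to the observed MRCA.
* **Bray–Curtis** is computed as $1 - 2\sum\min/\sum(x_i+x_j)$;
  all-zero samples are an error rather than a silent 0/0.
* **PCoA** keeps only positive-eigenvalue axes (tolerance
  $10^{-9}\times$ the largest eigenvalue) and warns when meaningfully
  negative eigenvalues are dropped.
* **Procrustes** is symmetric (both configurations centered and scaled
  to unit trace), $M^2 = 1 - (\sum_i \sigma_i)^2$ from the SVD of the
  cross-product. The Monte-Carlo test permutes the rows of the *second*
  ordination (which branch is permuted is immaterial for the symmetric
  statistic; the choice is documented here) and uses the add-one
  convention $p = (1 + \#\{M^2_{perm} \le M^2_{obs}\})/(B+1)$, so
  $p > 0$ always. Axes are truncated to the shared positive-eigenvalue
  count rather than an arbitrary 2, so no real structure is discarded.
* **Networks** form edges at $|r| \ge 0.6$ and Benjamini–Hochberg
  adjusted $p < 0.05$ over all pairs. The absolute-value rule is
  deliberate: published attribute tables for both branches report
  negative edges, which a one-sided $r \ge 0.6$ rule cannot produce.
  The ">0.1% of total sequences" inclusion filter is an overall pooled
  proportion with strict `>` (per-sample mean by flag). Average path
  length averages over connected pairs only (the relative-branch
  network is typically many small components, where infinite distances
  must be excluded); clustering assigns 0 to degree-<2 nodes;
  modularity is Newman Q of a seeded Louvain partition on the
  unweighted, sign-ignored graph, so $Q \le 1$ by construction —
  attribute tables quoting modularities above 1 come from other
  definitions and are not reproduced.
* **Spearman p-values** use the t approximation with mid-ranks; at the
  cohort sizes involved (≥ 5, typically 20 samples) the approximation
  error is far below the FDR decision boundary. BH adjustment stands in
  for q-values: the q-value procedure needs a $\pi_0$ estimator with
  unstated tuning, while BH is conservative and exactly reproducible.
* **Mantel** defaults to Spearman on the unfolded upper triangles
  (matching the pervasive use of rank correlations in this literature;
  Pearson by flag), permuting rows/columns of the second matrix, add-one
  convention; for $n \le 5$ all $n!$ permutations are enumerated and the
  p-value is exact. Per-variable tests use Euclidean distance on the
  z-scored variable; the pooled environmental distance is Euclidean on
  all z-scored variables; geographic distance is haversine on a
  6371-km sphere.
* **VPA** Hellinger-transforms the community by default (the standard
  pre-transformation for species-abundance RDA; raw by flag), computes
  the three RDA $R^2$ as projection variance ratios, applies the
  Ezekiel adjustment per block, and reports possibly-negative adjusted
  fractions as computed. Raw fractions sum to 1 by construction. The
  pure fractions are tested by permuting reduced-model residuals with a
  partial pseudo-F statistic. The spatial block is longitude and
  latitude; spatial eigenfunction methods are out of scope.
* **sPLS** runs in regression mode: per component, alternating power
  iterations on the cross-covariance with the X loading
  soft-thresholded so exactly `keepX` entries remain nonzero, both
  blocks deflated by regression on the X score. Loadings are unit-norm
  with the largest-magnitude entry positive (a deterministic sign
  convention). With `keepX` = all columns the first component equals
  the leading singular pair. Defaults `ncomp = 2`; `keepX` is a tuning
  flag. The reported heatmap flags Spearman $|r| > 0.5$, the usual
  display convention for these taxon–variable panels.

## Degenerate inputs and tie-breaks

Constant OTUs or variables are excluded with warnings wherever a rank
correlation would be 0/0. All-zero samples propagate as zeros with a
warning in `to_relative()` but are errors where a distance would be
undefined. Spike-ins listed in the design but missing from the table are
recorded as zero reads (and thus dropped from fits) with a warning.
Longitudes are normalized to [−180, 180] on load, so a transect crossing
180° has one consistent convention everywhere.

## Known limitations

The package corrects neither 16S copy-number per genome nor PCR bias
beyond what the per-sample spike-in curve absorbs; quantitative
abundances are gene copies, not cells. The co-occurrence networks use
plain rank correlations, which are not compositionality-aware —
acceptable on the quantitative branch, debatable on the relative branch,
and retained because the attribute block is defined on exactly these
networks. Modularity values depend on the Louvain seed for graphs with
degenerate optima; the seed is therefore part of the configuration and
recorded in output headers.
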