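---
title: "episwitch: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{episwitch: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical model behind `episwitch`, how the
synthetic world is calibrated, and the numerical and design decisions taken
where the underlying methodology left choices open.  It states no empirical
result that the package's test suite does not itself compute.

## 1. The measurement model

A MeDIP-chip experiment hybridises immunoprecipitated methylated DNA (Cy5)
against total input DNA (Cy3) on a promoter tiling array.  For probe $p$ on
array $j$ the methylation read-out is the M-value
$M_{pj} = \log_2(\mathrm{Cy5}_{pj}/\mathrm{Cy3}_{pj})$, and
$A_{pj} = (\log_2 \mathrm{Cy5}_{pj} + \log_2 \mathrm{Cy3}_{pj})/2$ is the
mean log intensity.  The synthetic generator draws

$$\mathrm{Cy3}_{pj} \sim \mathrm{logN}(\mu_I, \sigma_I), \qquad
  \mathrm{Cy5}_{pj} = \mathrm{Cy3}_{pj}\,
  2^{\,M_{pj}^{\mathrm{sig}} + b(z_{pj})},$$

where the signal part decomposes as

$$M_{pj}^{\mathrm{sig}} = m_{r(p),\,o(j),\,t(j)}
  + d_{r(p),\,\delta(j)} + e_{r(p),\,j} + \varepsilon_{pj}.$$

Here $m$ is the true region-level methylation for the array's
(organ, treatment) cell, $d \sim N(0, \sigma_{\mathrm{donor}}^2)$ the donor
random effect (shared across organs and technical replicates — the
whole-plot error), $e \sim N(0, \sigma_{\mathrm{tech}}^2)$ the per
region-and-array technical error, $\varepsilon \sim N(0,
\sigma_{\mathrm{probe}}^2)$ probe-level noise, and $b(\cdot)$ a cubic
dye-bias polynomial in *standardised* A.  Switch genes additionally load a
shared per-donor latent activation $z_\delta \sim N(0,1)$: expression gains
$+\lambda_e z_\delta$ (log2) while promoter methylation loses
$\lambda_m z_\delta$, which is the simplest structure that produces the
donor-level anti-correlation the analysis is designed to detect.

The default design is 2 organs × 2 treatments × 10 donors/group with two
technical arrays per organ sample: 80 arrays, collapsing to 40 donor-organ
units after replicate averaging.

## 2. Calibration of the noise defaults

The study design states one variance anchor directly: the standard error
between donors of a group is about twice the within-donor (technical)
error, hence the invariant $\sigma_{\mathrm{donor}} = 2\,
\sigma_{\mathrm{tech}}$.  The *magnitude* is anchored on the strongest
reported locus: a methylation difference of $\Delta M \approx -0.305$
reaching $p \approx 1.2\times10^{-8}$ in a two-sample t-test with 10 + 10
donors (df = 18) implies a donor-level within-group SD of about
$0.073$.  The defaults are therefore

| parameter | default | units | role |
|---|---|---|---|
| `sigma_donor` | 0.07 | M units | donor random effect |
| `sigma_tech` | 0.035 | M units | per region-array error |
| `sigma_probe` | 0.05 | M units | probe-level scatter |
| `cy3_meanlog`, `cy3_sdlog` | 6, 1.7 | log-intensity | input channel |
| `saturation_ceiling` | 15,000 | raw intensity | Cy3 exclusion rule |
| `dye_bias_coefficients` | (0, 0.08, 0.03, −0.008) | M units | cubic in standardised A |
| `sigma_expr`, `sigma_expr_donor` | 0.5, 0.25 | log2 signal | expression noise |
| `coupling_expr`, `coupling_meth` | 0.5, 0.05 | log2 / M | switch-gene latent loadings |

Two generator choices deserve explanation because they interact with the
normalisation rather than with the biology:

* **Intensity spread.**  Because $A$ contains $M/2$, the per-array loess
  regression of M on A removes a shallow slope
  $\approx \tfrac{1}{2}\mathrm{var}(M)/\mathrm{var}(A)$ of genuine signal
  and, in doing so, converts intensity scatter into extra region-level
  noise.  With a narrow intensity distribution this normalisation-induced
  noise would rival the planted technical noise, and a variance-recovery
  experiment would measure the normaliser instead of the generator.  The
  default log-intensity SD (1.7 natural-log units ≈ 2.5 log2 units) is both
  realistic for tiling arrays and wide enough that the induced term is an
  order of magnitude below $\sigma_{\mathrm{tech}}^2$.
* **Standardised dye bias.**  The bias polynomial takes
  $z = (A - \mathrm{center})/\mathrm{scale}$ with the centre and scale
  tracking the intensity distribution, so its magnitude (~0.2 M units at
  $|z| = 2$) is comparable to the planted effects whatever the intensity
  spread, and remains recoverable by a span-0.3 loess.

Saturation is modelled as heavy-tailed Cy3 draws exceeding the ceiling
(~1.5–2% of probes), not as hard scanner clipping: the exclusion rule is
the analytically relevant mechanism, and clipping would destroy the exact
noise-free limit (`Cy5/Cy3` reproducing planted M) that the generator
guarantees and the tests use.

## 3. Methylome processing decisions

* **Saturation rule** is strictly greater: `Cy3 = 15,000` is retained,
  `15,001` excluded, per array.
* **Loess**: degree-1 robust local regression (`limma::loessFit`), span
  0.3, one initial fit plus three robustness iterations.  The method is
  named by the upstream methodology without parameters; these are limma's
  conventional defaults for MA-plot normalisation.  A local smoother is not
  a projection: re-normalising corrected values moves probes slightly
  (median ~2×10⁻³ M units on a 32k-probe array, more for isolated probes
  in the sparse intensity tails).  The test suite asserts this measured
  near-idempotence rather than an unattainable machine-precision bound.
* **Window aggregation**: per TSS the mean of probes whose midpoint lies in
  the closed interval `[-800, +100]` nt *along transcription direction*
  (mirrored for minus-strand promoters: a TSS at 10,000 on the minus strand
  covers genomic `[9,900, 10,800]`); for regions with alternative TSSs the
  median of per-TSS means.  Intergenic CpG islands carry a pseudo-TSS at
  the island midpoint.  Coordinates are 0-based half-open; a TSS is the
  0-based first transcribed base.  Regions with no usable in-window probes
  on an array yield `NA` and are excluded listwise from the per-region
  tests.
* **"Bringing chips to the same scale"**: the scaling statistic is not
  specified upstream; `episwitch` equalises the per-array median absolute
  deviation to the across-array mean MAD after median subtraction.  MAD is
  robust against the planted differential-methylation tails, and the
  operation preserves within-array rank order.
* **Differential methylation** runs on donor-averaged values (the
  methodology averages technical replicates "for further fold change
  analyses") with a pooled-variance two-sample t — the classical default
  for equal group sizes; Welch is available via `var_equal = FALSE`.
  Significance is the conjunction `p <= 0.01` and `|Δ| >= 0.2`.
* **Split-plot ANOVA** runs on the array-level region matrix (all 80
  arrays): the upstream description applies the ANOVA before donor
  averaging, and with technical replicates in the model the residual mean
  square estimates the technical variance, making the donor/technical
  variance decomposition interpretable.  Treatment is tested against the
  donor-within-treatment stratum (df 18); organ and organ×treatment
  against the residual.  Donor variance component:
  $(\mathrm{MS}_{\mathrm{donor}} - \mathrm{MS}_E)/(o\,r)$, truncated at 0.
  All-constant regions return F = 0, p = 1 by convention.

## 4. Transcriptome and integration decisions

* **Cascade boundaries are inclusive**: retained iff group mean ≥ 50 in at
  least one group; |FC| ≥ 1.5-fold (or ≤ 1/1.5); p ≤ 0.001.  "Excluded if
  less than / larger than" phrasing upstream implies inclusive retention.
* The t-test runs on **linear** MAS5-like signals, as the upstream wording
  implies; a log-scale option would be the more usual modern choice and is
  an easy configuration change, but the linear test is what the filter
  cascade describes.
* **Clustering**: Euclidean distance on per-probe z-scored log2 signals,
  average linkage, `stats::hclust` (deterministic for fixed input order).
* **Correlation test**: Pearson r of donor-level log2 expression against
  promoter M, pooled across both treatment groups (n = 20), with
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$, df 18.  Neither the test nor n is stated
  upstream; n = 20 was *inferred* and then verified: it is the unique
  sample size in 18–22 for which every published (r, p) pair is consistent
  with the t-transform once the 3-decimal rounding of the printed r is
  accounted for.  Expression is correlated on the log2 scale
  (variance-stabilised; configurable).
* **Gene table**: the representative probe set per gene is the one with the
  highest control-group mean; ranking is by linear fold change with
  alphabetical tie-break; CpG class is carried from the annotation.
* **CpG classification**: best 500-nt sliding window; *strong* if some
  window has GC > 0.55 and CpG observed/expected > 0.75, *poor* if no
  window reaches o/e 0.48, *weak* otherwise — the strong/weak/poor scheme
  of the MeDIP literature; thresholds are arguments, not constants.
  Sequences with > 10% ambiguous bases are unclassified.

## 5. Validation assays

All qPCR arithmetic assumes amplification efficiency 2 (the ΔΔCt
assumption); efficiency correction is out of scope.  Group summaries of
fold changes use the geometric mean (ratio scale).  IgG in ChIP is reported
as a parallel background track and never subtracted — subtraction would be
an unstated transformation; instead a locus is flagged uninformative when
IgG enrichment reaches the weakest specific antibody.  The dilution factor
in MeDIP-qPCR enrichment is a configuration input because the upstream
normalisation arithmetic is not fully specified.

## 6. What the generator does and does not emulate

Emulated: the full sampling design (80 arrays, 40 donor-organ units),
donor-vs-technical variance structure, intensity-dependent dye bias,
channel saturation by exceedance, alternative TSSs (second TSS 300–600 nt
downstream), intergenic CpG islands without symbols, multiple expression
probe sets per gene, planted organ effects, planted differential
methylation and expression, and latent-coupled switch genes.

Not emulated: sequence-level MeDIP enrichment, fragment-size effects, WGA
amplification bias, probe cross-hybridisation, spatial chip artefacts,
scanner clipping, background signal, and real CpG-density-dependent
methylation structure (CpG classes are labels, not consequences of
sequence).  A green recovery test therefore establishes that the pipeline
recovers planted effects under the stated noise model — not that it would
be robust to artefacts the generator does not produce.

By construction the planted differential-methylation and
differential-expression sets are disjoint except for the switch gene(s),
mirroring the finding that methylation and expression perturbations largely
fail to overlap; the uniqueness assertion in the acceptance suite tests
exactly this world.

## 7. Determinism and reproducibility

Every generator derives its RNG stream from the master seed through fixed
offsets, so each component is individually reproducible and the shared
pieces (donor effects, latent activations) agree across generators.  The
run manifest contains the stage list, configuration, seed and MD5 checksums
of every output file and no wall-clock information; a timestamp goes to a
separate `run.log`.  Two runs at the same seed are byte-identical,
manifest included.

## 8. Known limitations

* The split-plot model requires a balanced design; missing cells error
  rather than fitting an unbalanced mixed model (`lme4` would be the tool
  for that, at the cost of a different testing framework).
* The per-region listwise exclusion under saturation is conservative.
* The correlation test treats the 20 donor-level pairs as exchangeable
  across groups; with strong group separation the pooled r is dominated by
  the between-group contrast — which is precisely the read-out wanted for
  switch genes, but it should not be interpreted as a within-group
  association.
* CpG classes in the synthetic annotation are sampled labels;
  `classify_cpg()` is exercised on explicit sequences instead.
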