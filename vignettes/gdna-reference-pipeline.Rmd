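---
title: "Methods: quantifying MI/MII transcriptomes against a gDNA common reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying MI/MII transcriptomes against a gDNA common reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycodiff)
```

## The measurement model

Each array co-hybridizes one sample's Cy3-labelled cDNA with the same
Cy5-labelled *S. coelicolor* genomic DNA. Genomic DNA is copy-number flat
across the chromosome, so the Cy5 channel is a per-probe sensitivity
reference shared by all arrays, and

$$ M_g = \log_2 \frac{I_{\mathrm{Cy3}}}{I_{\mathrm{Cy5}}} $$

behaves like an absolute log-abundance: two arrays can be compared probe
by probe without a common sample. The study design is four developmental
stages (MI at 16 h as reference; MII at 24, 48 and 72 h) in three
biological replicates — twelve arrays.

**Background correction.** Net intensity per spot and channel is
foreground mean minus background median. When the subtraction is negative
or *strictly smaller* than the background pixel SD, the SD is used as a
surrogate intensity. Two consequences drive the implementation: the net
signal is always positive (so every probe has a defined log-ratio), and
weak probes are censored at a floor rather than dropped. We read
"negative or lower than the SD" strictly: a difference exactly equal to
the SD is kept. Both channels get identical treatment; whether the
original analysis evaluated the rule per channel independently is not
documented, and per-channel is the only reading that keeps both ratios
defined.

**Probe weights.** Probes matching more than one gene and probes in
intergenic regions carry weight $10^{-6}$; valid probes weigh 1. On the
published 4×44k layout this is 43,798 probes with 943 cross-hybridizing
and 7,234 intergenic, leaving 35,621 valid. Non-valid probes are kept in
the matrix (every array must share one probe set) but have negligible
influence on normalization and gene summaries — e.g. probes at Mg 1 and
100 with weights 1 and $10^{-6}$ average to $(1 + 10^{-4})/(1 + 10^{-6})
\approx 1.0000990$.

## Normalization

Cyclic loess with span 0.3, three iterations and degree-1 local fits,
followed by median normalization; probe weights enter both steps.

For every unordered array pair $(j, k)$ the difference $M = Mg_j - Mg_k$
is loess-regressed on the average abundance $A = (Mg_j + Mg_k)/2$ with
tricube distance weights multiplied by the probe weights. Design choices
where the procedure was genuinely open:

* **"Window of 0.3" is the loess span** — the standard meaning of the
  parameter in two-color normalization.
* **"Three iterations" are three full cycles over all pairs**, not
  robustifying reweighting iterations.
* **Simultaneous, symmetric updates.** Within one iteration every pair
  trend is estimated from the same snapshot of the matrix and array $j$
  receives $-1/n$ of each of its pair trends ($+1/n$ on the other side).
  With two arrays this is exactly "half the trend off each array"; with
  $n$ arrays it is the unique symmetric split that (i) makes the
  procedure exactly invariant to array order (sequential pair updates are
  not, at any tolerance) and (ii) removes the full pairwise trend per
  cycle in the linear regime, so three iterations converge. Splitting
  literally half per pair and averaging instead contracts deviations only
  by $\tfrac{n-2}{2(n-1)}$ per cycle ($\approx 0.45$ for 12 arrays) and
  leaves ~10 % of an injected bias after three cycles.
* **Median normalization equalizes each array's weighted median to the
  global weighted median**, not to zero: Mg against a gDNA reference
  carries absolute meaning that centering would discard. The target is
  configurable. The weighted median interpolates the cumulative-weight
  quantile function, so a $10^{-6}$-weight outlier moves it negligibly.

Two numerical caveats, both visible in the tests:

* **Attenuation.** Loess absorbs whatever part of a real effect looks
  smooth along $A$. Differentially expressed genes move along $A$ by half
  their effect, so when they are common, large, and one-sided, the fitted
  trend eats into them. At the study-like prevalence (~13 % of genes
  changed, ~2 % beyond 4-fold, both directions) the pipeline-wide mean
  absolute error of Mc at noise SD 0.2 stays below 0.15; a deliberately
  hostile configuration (30 % of genes at +3) can lose ~0.4. This is a
  property of the method, not of this implementation.
* **Sparse-tail wobble.** At the extremes of $A$ the span-window holds
  few effective points and repeated loess fits differ by fit noise. The
  idempotence contract (second pass changes nothing by more than 0.01) is
  therefore tested on data with bounded abundance support at array-like
  probe counts; on Gaussian-tailed simulated data the violation is
  confined to the ~1 % of probes in the sparse tails.

## Gene-level inference

Valid probes of one gene are averaged (weighted by the validity weights)
*before* model fitting — the sentence order of the source protocol, and
the only order under which its probe-count bookkeeping makes sense. A
one-way group-means model per gene over the four stages gives
$Mc_c = \bar{Mg}(c) - \bar{Mg}(\mathrm{MI16})$ with pooled residual
variance on $12 - 4 = 8$ degrees of freedom.

Variances are shrunk by empirical Bayes:
$s^2_{\mathrm{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with the prior
$(d_0, s_0)$ estimated by the method of moments on $\log s^2$ (trigamma
inversion by Newton iteration; $d_0$ capped at $10^6$ to represent
"effectively infinite" when variances are homogeneous). The moderated
$t = Mc / (s_{\mathrm{post}} \sqrt{1/n_c + 1/n_{\mathrm{ref}}})$ is
referred to $t_{d_0 + d}$. With $d_0 = 0$ this reduces exactly to the
ordinary t-test; the suite also cross-checks the whole chain against the
reference empirical-Bayes implementation on shared data. FDR adjustment
is Benjamini–Hochberg step-up within each contrast — the protocol says
only "FDR-corrected", and BH was the default method of the named package
at publication time.

## The selection cascade

* **Reliability:** keep a gene only when its p-value is below 0.05 in
  *all three* MII/MI contrasts. The protocol's "p-values" are read as the
  raw ones (it computed both; the filter is quoted without the
  correction), configurable to FDR.
* **Significance limit ±1** (2-fold) for calling a direction; fold
  magnitudes are $2^{|Mc|}$ reported at the source's mixed precision:
  nearest integer from 5-fold up, one decimal below (169, 24, 6 versus
  4.3, 2.5, 3.5).
* **Candidate tier:** unknown function, conservation (minimum percent
  similarity across five *Streptomyces* genomes, consumed as a
  precomputed annotation) strictly above 75 %, and $|Mc| \ge 2$ in some
  contrast.
* **Top tier:** $|Mc| \ge 3$ in some contrast. The comparison is $\ge$,
  not $>$: the printed top-tier table contains a gene whose maximum
  printed value is exactly 3.0, so strict inequality would contradict the
  printed membership. On printed one-decimal values this is the only
  defensible convention.

The printed per-gene tables ship as tab-separated fixtures and every
package operation runs on them directly; the 53-gene tier count, the
41-gene unknown block, and the narrative fold statements are recomputed,
not stored.

## qPCR cross-validation

Livak ΔΔCt with amplification efficiency fixed at 2 (the source verified
absence of primer-dimers but reports no efficiency correction): technical
triplicates are averaged within each of two biological replicates, the
per-replicate ΔΔCt against the internal-control gene and the MI
calibrator is averaged, and the replicate SD is the reported dispersion.
Two invariances pin the arithmetic: the calibrator's relative expression
is exactly 1, and adding any constant to every Ct changes nothing.
Array-vs-qPCR concordance is an ordinary least-squares fit of qPCR log2
ratios on array Mc with the Pearson correlation.

## What the simulator emulates — and what it does not

`generate_array_dataset()` draws a log-normal per-probe gDNA intensity
(log2 mean 10, SD 2 — a realistic scanner dynamic range) shared across
arrays; Cy3 multiplies the same probe intensity by
$2^{\text{baseline} + \text{effect} + \text{noise} + \text{offset}}$.
Defaults state the world once:

| parameter | default | meaning |
|---|---|---|
| conditions, replicates | 4 stages × 3 | the published design |
| `frac_crosshyb`, `frac_intergenic` | 943/43798, 7234/43798 | published probe classes |
| `base_sd` | 2 | log2 spread of baseline expression |
| `noise_sd` | 0.2 | probe-level log2 noise (chosen for testability; the source reports no magnitudes) |
| `array_offset_sd` | 0.05 | per-array labelling-efficiency offset, removed by median normalization |
| `dye_bias` | 0 | polynomial in the array's standardized abundance profile, scaled per array by U(−0.5, 0.5) |
| `frac_surrogate` | 0.01 | probes with baseline 8 log2 units down, so the surrogate branch fires naturally |
| `bg_level`, `bg_sd` | 50, 5 | background pixel statistics |

Cross-hybridizing probes see the mixture of their two genes' abundances;
intergenic probes sit near the background floor. One integer seed drives
every draw, and identical configurations are byte-identical.

Not emulated: pixel grids (statistics are emitted directly), spatial or
print-tip artifacts, saturation, array-quality differences, and any
biological correlation structure between genes. A green simulation test
therefore establishes the *arithmetic* of the pipeline under the stated
noise model — not robustness to artifacts the generator does not produce,
and not the study's actual gene lists, whose raw arrays are not publicly
deposited (which is also why the 1901-gene and 122-gene counts are out of
scope for testing).

The zero-noise exactness contract (recovered Mc equal to configured
effects to $10^{-9}$) is checked with normalization disabled and without
cross-hybridizing probes: loess inevitably absorbs part of a real effect
on a noise-free matrix, and a $10^{-6}$-weight cross-hybridizing probe
shifts a gene mean at the $10^{-6}$ level by construction. Both
mechanisms are deliberate features of the method, so the exactness
statement is only well-posed on the path that excludes them; the full
normalized path is held to the looser stochastic tolerances above.

## Known limitations

* Whether the original cyclic loess ran across all 12 arrays or within
  replicate groups is unstated; this implementation normalizes across all
  arrays.
* The narrative "up to 11-fold" (aerial-mycelium activators) and
  "13.5-fold" (sporulation regulators) statements cannot be reconciled
  with the maxima of the printed table and are not used as checks; the
  seven statements that do verify are.
* Raw p-values feed the reliability filter by default; switching to FDR
  makes the cascade strictly more conservative.
* The ΔΔCt model assumes perfect doubling; no efficiency calibration is
  implemented.
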