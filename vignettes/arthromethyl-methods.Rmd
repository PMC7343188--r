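---
title: "Methods and design notes for arthromethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for arthromethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind each stage of the
package, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the underlying methodology left choices open.

## 1. Site-level model

A CpG dyad carries a latent methylation probability $p_i$. Bisulfite
sequencing observes, per strand, $t$ reads of which $k$ support methylation;
the per-dyad fraction pools both strands,
$m_i = (k_+ + k_-)/(t_+ + t_-)$. Unmethylated cytosines fail conversion at a
small rate $\varepsilon$, so the expected observed fraction is
$q_i = p_i(1 - f) + (1 - p_i)\,\varepsilon$, with $f$ the (normally
negligible) failed-conversion rate of methylated cytosines.

**Coverage filter.** Sites with fewer than 10 reads *on either strand* are
excluded (`filter_sites`, `min_per_strand = 10`). The rule is per-strand,
not pooled: a site with 30 reads on one strand and 9 on the other is
dropped.

**Non-conversion floor.** $\varepsilon$ is estimated by pooling counts over
all sites of an unmethylated spike-in (`estimate_nonconversion`), with a
Clopper–Pearson 95% CI. This is the error floor of every downstream call.

**Genome-wide percentage.** "Percent of CpG sites methylated" is not a
uniquely defined statistic; the binarisation rule behind published figures
is usually unstated. We therefore expose two callers side by side:

* `mean_fraction`: $100 \cdot \overline{m_i}$ — no binarisation;
* `binomial_vs_spike` (default): per-site one-sided binomial test of
  $k \sim \mathrm{Bin}(t, \varepsilon)$, Benjamini–Hochberg at $q = 0.05$,
  reporting the percentage of sites called. This respects the spike-in that
  was sequenced for exactly this purpose.

The two callers differ most in sparsely methylated genomes, where many
sites carry low but real methylation; both are reported by the pipeline
rather than guessing which produced any particular published number.

## 2. Features, bootstrap, and high/low clustering

Feature means average $m_i$ over covered CpGs inside the feature, and are
undefined below 3 covered CpGs (`min_cpgs = 3`) — a variance guard, since a
1–2-CpG feature mean is dominated by single-site noise. Class summaries
resample *features* (not sites) with replacement, 1000 times, and report
percentile 2.5/97.5 bounds; the genome background is a plain mean over
background CpGs because there is no natural feature unit to resample.

**High/low clustering.** The clustering algorithm behind published
"proportion methylated" tables is typically unreported. We use deterministic
two-component k-means on logit-transformed values (clamped to
$[10^{-3}, 1 - 10^{-3}]$), initialised at the 10th/90th percentiles; the
larger-centre component is "high". The logit transform makes the bimodal
methylation distribution near-symmetric in each mode. A 1-D EM Gaussian
mixture is available (`method = "gmm"`) and agrees on well-separated data.
Because the algorithm is a substitution, published proportion columns are
treated as qualitative, not exact, targets; the acceptance check instead
verifies recovery of an implanted 75/25 Beta mixture to ±0.05.

**Metagene profiles.** Feature bodies are scaled to 20 bins
(site at offset $o$ of length $L$ → bin $\lfloor 20\,o/L \rfloor$, minus
strand reversed), flanks use 20 fixed 50-bp bins, and sites pool across
features per bin. Bin counts are emitted so empty bins are visible rather
than interpolated.

## 3. Nucleosome periodicity detector

For each separation $d \in [3, 500]$ bp, all same-feature site pairs at
exactly that separation are pooled across features and the Pearson
correlation between left- and right-site fractions computed. The series
$r(d)$ is detrended by OLS on $d$ (removing gradual decay of correlation
with distance), padded with 50 000 zeros, and Fourier transformed. The
nucleosome statistic is the summed amplitude of components with period in
the closed band [140, 200] bp; the dominant period is the in-band argmax.

Open choices, and what we chose:

* **Undefined distances** (fewer than `min_pairs = 20` pairs, or zero
  variance) are imputed as residual 0 before the FFT: zero-imputation adds
  no spectral energy, whereas interpolation would manufacture signal.
* **"Intensity"** is the amplitude modulus; `power = TRUE` switches to
  squared amplitude. The band statistic is monotone under either.
* **Pooling** is across all pairs of all features at a given $d$ (not a
  per-feature average): per-contig random phases cancel in the mean but not
  in the pooled correlation, which is exactly why the statistic works.
* **Significance.** `periodicity_null` builds a null from random circular
  shifts of the residual vector (re-padded per shift),
  $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n)$. Circular shifts
  preserve the autocorrelation structure of the series, so this null is
  conservative against genuinely periodic signals — it is calibrated on
  white noise (verified by test) but deliberately weak as a detector; the
  primary statistic remains the raw band intensity, as in the original
  procedure, with the empirical p as an aid.

Resolution note: with a 498-point series the intrinsic frequency resolution
is coarse; padding interpolates the spectrum so the in-band peak can be
read to a few bp. At the scale the acceptance tests run (≥500 exons of
600 bp, amplitude 0.2, coverage 50/strand) the dominant period lands within
±10 bp of the implanted repeat length in ≥18/20 seeded runs for
L ∈ {147, 160, 180}.

## 4. Brownian-motion ancestral states and PGLS

Under Brownian motion with rate $\sigma^2$, tip values are multivariate
normal with covariance $\sigma^2 C$, $C_{ij}$ the shared root-to-MRCA path
length. `asr_bm` implements the maximum-likelihood reconstruction by
Gaussian message passing: an upward pass combines child messages by
precision weighting (accumulating the contrast sum of squares $Q$, whence
$\hat\sigma^2 = Q/n$, or $Q/(n-1)$ for REML), and a downward pass supplies
each node with the information from the rest of the tree. The combined
estimate at a node equals the inverse-path-variance-weighted GLS root
estimate of the tree re-rooted at that node — the identity the test suite
checks against a dense-matrix oracle built from pairwise path lengths.
Node variance is $\hat\sigma^2 v$ with $v$ the combined message variance;
the 95% CI is $\pm 1.96\sqrt{\hat\sigma^2 v}$. As with any plug-in ML
variance, CIs are slightly anti-conservative on very small trees (the
estimator itself is exactly unbiased); this matches the behaviour of the
standard fast ML reconstruction tools.

`pgls` fits GLS with $V = \sigma^2 C$ via a Cholesky whitening, with exact
$t$-tests on $n - k$ degrees of freedom. It replaces a Bayesian phylogenetic
mixed model used for the same question (does a binary genomic character
predict methylation level?): same covariance structure, deterministic,
seconds instead of millions of MCMC iterations. Consequently published
posterior p-values are method-substituted, not exact targets; the package's
own guarantee is type-I calibration (verified: rejection rate within
[0.02, 0.09] at $\alpha = 0.05$ on 500 null simulations). Traits are
analysed on the percent scale by default, matching field practice.

## 5. Expression, orthogroups, promoters

FPKM is count/(kb × millions mapped). Group splits (top/bottom 20%) use a
rank rule with stable gene-id tie-breaks that partitions exactly at
$q = 0.5$. The coefficient of variation uses the sample (n−1) sd and is
undefined at zero mean. Orthogroup scores z-score methylation within each
species, average paralogs within species, then average across species —
the fixed-effect closed form of a balanced mixed model, substituted for an
unreported mixed-model specification. Housekeeping membership is always an
input list, never inferred.

CAGE CTSSs are clustered by the greedy 20-bp-gap rule per contig and
strand. The interquantile width takes the cumulative expression fraction
along positions as a step function and reports
$\mathrm{pos}(q_{0.9}) - \mathrm{pos}(q_{0.1})$, with "first position
reaching the fraction" as the quantile convention (no interpolation — the
data are integer positions). Width is invariant to uniform rescaling of
weights, so raw tags and TPM give identical widths within a library.
Cluster→gene assignment uses the cluster's peak CTSS, same strand, within
±500 bp of an annotated TSS (a convention; the window is a parameter).

Occupancy metagenes average a track over 200-bp windows spanning ±2 kb of
each TSS (minus-strand windows flipped). The confidence band recomputes the
per-window means on 100 random 90% subsamples of genes, loess-smooths each
resampled curve (span 0.3), and keeps the per-window min/max — a band of
extremes, as described for the original analysis, not a percentile band.

## 6. The synthetic world

The generator emulates exactly the statistical structure the analyses
assume, and nothing more:

* **Genome**: `n_contigs` contigs; genes (1–8 exons, lengths uniform in a
  configurable range), TEs and optional rRNA/tRNA placed without overlap,
  round-robin across contigs with randomised gaps (explicit error if the
  request cannot pack). CpG dyads are placed at `cpg_density` per bp with
  ≥2 bp spacing. No sequence is generated — only coordinates.
* **Methylome**: class means per feature class; a `meth_gene_fraction` of
  genes forms the methylated class (bimodal gene-body distribution), the
  rest sit at `exon_unmeth`. Inside methylated exons the phased cosine
  $p = \mathrm{clamp}(\mu + A\cos(2\pi(x-\phi_c)/L), 0, 1)$ is implanted
  with per-contig phase $\phi_c$ — a deliberately minimal generative model
  whose *correlation structure* matches nucleosome-phased methylation,
  rather than an explicit nucleosome-placement model. Promoter-silencing
  presets give a `silenced_fraction` of genes highly methylated upstream
  regions.
* **Counts**: per strand, totals Poisson(`coverage_mean`), methylated reads
  binomial with the non-conversion floor; the spike-in is a separate table
  on the reserved contig `"spike"` with $p = 0$ (no lambda-phage sequence
  model). The real coverage distribution of any particular library is
  unknown; Poisson is the configurable default.
* **Expression/CTSS/occupancy**: per-gene log-normal baselines; methylated
  genes are "housekeeping-like" — baselines truncated above the 30th
  percentile, low tissue spread (`cv_low = 0.1` vs `cv_high = 1.0`), broad
  CTSS clusters (40 bp vs 5 bp spans), and phased occupancy downstream of
  the TSS. The occupancy signal is a cosine of period L *plus a 0.4-amplitude
  offset*: a zero-mean cosine would cancel inside 200-bp windows, whereas
  real phased arrays show a net occupancy gain at window resolution.
* **Traits on trees**: child = parent + Normal(0, σ²·branch length), all
  internal truths retained for recovery tests.

What the generator does **not** emulate — and hence what a green test does
not establish: sequence composition and mappability artefacts, M-bias and
strand asymmetries, covariance between coverage and methylation, TE family
structure, isoform-level expression, and CAGE power-law tag normalisation.
Green tests establish that the *estimators* recover the *model* they
assume; they cannot certify behaviour on pathologies the model lacks.

Default parameter choices of record: coverage 30/strand (typical of a
modern WGBS study), non-conversion 0.005 (typical spike-in estimates),
nucleosome repeat length 160 bp, periodic amplitude 0.15 (0.2 in the
detector acceptance runs), 4 tissues, class means per preset as in
`sim_config`. These are fixed as the stated world; tests never tune them.

## 7. Numerical and convention notes

* Coordinates are 0-based half-open internally; GFF3 (1-based closed) and
  cytosine reports (1-based positions) convert at the I/O boundary. Site
  tables are keyed by the + strand cytosine of each dyad.
* Overlap is ≥1 shared bp and strand-blind. TEs are screened first;
  upstream regions are screened against the *pre-screen* TE set by default
  (the conservative reading; `upstream_against = "postscreen"` flips it).
* Pearson correlations are computed from accumulated sums; distances with
  near-zero variance (< 1e-12) are undefined rather than returning ±1.
* All generators derive their RNG streams from a single seed with fixed
  offsets, so stages can run in any order and reruns are byte-identical;
  the pipeline manifest records MD5 checksums of every output.
* Degenerate inputs have defined behaviour: all-identical clustering input
  warns and reports proportion 0; a paired test with identical values
  returns p = 1; an empty group in a contrast returns NA with a warning
  rather than an error, except where the contract specifies an error
  (empty spike-in, empty CTSS table, unmatched tips).

## 8. Known limitations

* Only the CpG context is handled (no CHG/CHH).
* The circular-shift significance aid for periodicity is conservative (see
  §3); raw band intensities are the comparable statistic across species.
* PGLS assumes strict Brownian covariance (no Pagel's λ or OU option).
* ASR confidence intervals use the plug-in ML σ²; on trees with < ~10 tips
  they under-cover somewhat, exactly as the standard tools do.
* The CTSS clustering implements the distance rule only; power-law
  normalisation to a reference distribution is out of scope, so TPMs are
  simple per-million ratios.
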