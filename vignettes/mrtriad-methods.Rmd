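---
title: "Methods: two-sample MR with literature triangulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with literature triangulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtriad)
```

## The model

Two-sample Mendelian randomization (2SMR) estimates the causal effect
$\theta$ of an exposure $X$ (here, typically a circulating metabolite) on
an outcome $Y$ (a disease or risk factor) from two independent GWAS. For
each instrument SNP $j$ we observe the SNP–exposure association
$\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$ and the SNP–outcome
association $\hat\beta_{Yj}$ with $\sigma_{Yj}$. Under the IV assumptions
(relevance, independence from confounders, and exclusion restriction —
no path to $Y$ except through $X$), each Wald ratio
$b_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ estimates $\theta$, with
first-order standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$. This SE
ignores the exposure-side sampling error (the NOME approximation); the
consequences are discussed under *Limitations*.

The estimators combine the ratios in different ways, trading efficiency
against robustness to exclusion-restriction violations (horizontal
pleiotropy, where a SNP affects $Y$ through some other pathway):

* **IVW** — inverse-variance-weighted mean of the $b_j$, equivalently
  the zero-intercept weighted regression of $\hat\beta_Y$ on
  $\hat\beta_X$ with weights $1/\sigma_{Yj}^2$. Efficient, but biased if
  average pleiotropy is nonzero.
* **MR-Egger** — the same regression with a free intercept, all pairs
  oriented so $\hat\beta_{Xj} > 0$ (the intercept is only identified
  under a fixed orientation). The slope is consistent under the InSIDE
  assumption (pleiotropic effects independent of instrument strength);
  the intercept estimates the average directional pleiotropic effect and
  is the package's pleiotropy test (t on $J-2$ df).
* **Weighted median** — the weighted 50% quantile of the ordered $b_j$
  using standardized cumulative weights $p_j = (\sum_{k\le j} w_k -
  w_j/2)/\sum_k w_k$ with linear interpolation at $p = 0.5$; consistent
  if instruments carrying half the weight are valid.
* **Weighted mode** — the argmax of a Gaussian kernel density over the
  $b_j$ (bandwidth: a configurable multiple of the Silverman rule,
  512-point grid over $[\min b - 3h, \max b + 3h]$); consistent if the
  largest group of instruments agreeing on a ratio is valid.

Median and mode SEs come from a parametric bootstrap (default 1000
resamples) that redraws $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from their
reported sampling distributions; the seed is mandatory, so every run is
reproducible.

### Random-effects IVW and its p-values

The default IVW is *multiplicative random effects*: the fixed-effect SE
$(\sum w_j \hat\beta_{Xj}^2)^{-1/2}$ is inflated by
$\max(1, \sqrt{Q/(J-1)})$, where $Q$ is Cochran's heterogeneity
statistic. Over-dispersion widens the interval; under-dispersion never
narrows it. The truncation at 1 makes random-effects p-values mildly
conservative under exact homogeneity (the p-value distribution has
slightly too little mass near 0 — our null simulations measure a 4–5%
rejection rate at $\alpha = 0.05$); the fixed-effect p-values are the
exactly calibrated ones in that regime. Both modes are exposed;
switching is one argument.

## Instrument selection

Instruments are chosen by (i) a genome-wide significance filter
(default $p < 5\times10^{-8}$, strict), (ii) exclusion of the MHC
region, chr6:26,000,000–34,000,000 inclusive on 1-based coordinates —
its extended LD defeats clumping — and (iii) greedy LD clumping at
$r^2 < 0.001$ within a 10 Mb window: SNPs are sorted by p-value (ties
broken lexicographically by rsID so the output is a deterministic,
order-invariant function of the input), the best remaining SNP is kept,
and everything correlated with it at $r^2 \ge$ threshold within the
window is removed with an explicit `clumped_by:` reason. The window
default is our choice (common practice; only the $r^2$ threshold is
standard), and it is configurable. Every removal is book-kept so kept +
removed always equals the input — silent loss is a bug by contract.

The LD reference is an abstract provider (pair table or labeled
matrix); pairs absent from it count as $r^2 = 0$ and are logged.
Genome build is carried as metadata only and never validated. Instruments
missing from the outcome GWAS may be replaced by their best LD proxy
($r^2 \ge 0.8$ by default), but only when the reference resolves the
allele orientation between proxy and original; an unphased proxy is
rejected outright, trading coverage for sign safety.

## Harmonization

The outcome effect must refer to the exposure's effect allele. For
non-palindromic SNPs this is label algebra: swapped labels negate
$\hat\beta_Y$ (and reflect the outcome EAF to $1-$EAF); alleles matching
only after strand complementation are complemented first. Palindromic
SNPs (A/T, C/G) are their own complements, so labels cannot reveal the
strand; three strategies are offered: (1) trust the labels (assume the
same strand), (2) infer strand from allele frequencies — the default,
with SNPs whose EAF on either side falls in $[0.42, 0.58]$ dropped as
ambiguous, and (3) drop all palindromic SNPs. The 0.08 ambiguity
half-window mirrors common practice; nothing in our sources fixes it.
Mode 2 is the default because it retains information where frequency is
decisive while refusing to guess near 0.5. By construction the mode-2
and mode-3 retained sets are subsets of mode 1's. Indels and
irreconcilable allele sets are flagged `dropped_incompatible` rather
than raising: a phenome-wide batch must not abort on one variant.

## Sensitivity analyses

* **Cochran's Q** on the ratio estimates with weights
  $(\sigma_{Yj}/|\hat\beta_{Xj}|)^{-2}$, $\chi^2_{J-1}$ under
  homogeneity. The weights match the IVW estimator (NOME-consistent).
* **Egger intercept** test (above).
* **Steiger directionality**: per SNP, the variance explained is
  compared between sides via $r = \sqrt{t^2/(t^2+n-2)}$ (t-statistic
  route, which works without EAF); the p-value is a two-sample z-test on
  Fisher-transformed $|r|$ with variance $1/(n_{exp}-3)+1/(n_{out}-3)$.
  A SNP is removed only when the direction is wrong *and* $p <$ 0.05:
  direction alone is noise for weak instruments. Whether filtering runs
  before estimation is a pipeline switch (`steiger = TRUE`), since our
  sources do not fix the order.
* **Leave-one-out** (IVW re-estimated without each SNP) and
  **single-SNP** (per-SNP Wald ratios plus method summaries) tables feed
  the leave-one-out and forest plots.

## The phenome-wide scan

`mr_scan()` runs the full pipeline per exposure × outcome pair with IVW
as the headline method (Wald ratio at a single instrument). Family-wise
control is Bonferroni over the whole grid with strict inequality —
$0.05/(825\times236) = 2.57\times10^{-7}$ for the motivating grid. Pairs
without usable instruments are recorded with a skip reason; result rows
plus skips always equal the grid size. The Miami table exports
$\mathrm{sign}(\hat\theta)\cdot(-\log_{10}p)$ with category order
indices and super-pathway keys; categories are free-form labels supplied
by the caller (no fixed taxonomy exists for them).

## Triangulation against literature triples

Subject–predicate–object triples mined from the literature are an
evidence stream independent of genetics. The overlap of {objects of
exposure-query triples} with {subjects of outcome-query triples}
proposes intermediates (glycine → homocysteine → coronary
arteriosclerosis is the canonical pattern). Matching is
case-insensitive exact equality after whitespace normalization, and
deliberately nothing more: stemming or ontology mapping would silently
change overlap sets. Enrichment, where counts are supplied, is a
one-sided Fisher exact test of the local 2×2 table against the global
background. The upstream services compute enrichment with unpublished
machinery, so *ranks*, not p-values, are the comparable output; the
ranking orders overlap terms by the better of their best per-side
p-values, ties broken by term.

## The synthetic-data generator

`simulate_sumstats()` draws, per SNP: EAF $\sim U(0.1, 0.9)$;
SNP–exposure effect $\gamma_j \sim N(0.08, 0.02^2)$ (effect alleles
oriented exposure-increasing, as mQTL instruments conventionally are;
at $n = 50{,}000$ this gives strongly genome-wide-significant
instruments, matching the metabolite-GWAS setting); pleiotropy
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ (zero by default);
SEs from the standardized-trait formula
$(2\,\mathrm{EAF}(1-\mathrm{EAF})\,n)^{-1/2}$; and observed effects
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$.
`reverse_causation = TRUE` swaps the generative roles to exercise the
Steiger filter. Effects are simulated directly on the
summary-statistic scale — no individual-level genotypes — and the two
samples are non-overlapping by construction, which is exactly the 2SMR
design assumption.

What the generator does *not* emulate: LD between instruments (LD
enters only through the separate block-structured
`simulate_ld()` used for clumping fixtures), sample overlap between the
two GWAS, allele-frequency differences between panels, population
stratification, and winner's-curse selection of instruments. A green
simulation test therefore establishes internal statistical correctness
of the estimators under the stated model, not robustness to those
real-data pathologies.

P-values are clamped at $10^{-300}$: very strong instruments underflow
the two-sided normal p to exactly 0, which the record invariant
$p \in (0,1]$ rightly rejects.

## Numerical choices

* Weighted regressions are solved by closed-form normal equations (two
  unknowns at most); the tests cross-check them against `lm()` to
  $10^{-10}$.
* Egger SEs use the multiplicative scaling $\max(1, \hat\sigma)$ on the
  weighted-regression residual SE, with t reference on $J-2$ df.
* Ties are broken lexicographically by rsID everywhere (clumping order,
  proxy choice, overlap ranking) so all outputs are deterministic.
* Degenerate inputs: empty harmonized sets make estimators raise a typed
  `insufficient instruments` error; batch paths (scan, report) catch it
  and record a reason instead.
* Bootstrap draws run under an isolated RNG state (`with_seed`), so
  library calls never perturb the caller's stream.

## Limitations

* The NOME approximation (ignoring $\sigma_{Xj}$ in ratio weights)
  biases MR-Egger toward the null when instrument strength is modest:
  the attenuation factor is roughly
  $\mathrm{var}(\gamma)/(\mathrm{var}(\gamma)+\bar\sigma_X^2)$. At the
  generator's defaults that is visible (~9% of the slope), which is why
  the Egger-unbiasedness property test simulates the
  strong/heterogeneous-instrument regime
  ($\gamma \sim N(0.15, 0.06^2)$) where the estimator's consistency
  conditions hold. IVW is essentially unaffected at these instrument
  strengths (measured bias $< 0.001$ at $\theta = 0.2$).
* Only 8 of the many published MR estimators are implemented (Wald,
  IVW fixed/random, Egger, weighted/simple median, weighted/simple
  mode); the method registry in `run_mr()` is the extension point.
* No multivariable MR, no outlier-correction (MR-PRESSO-style), no
  colocalization, no I² or Rucker model selection.
* The LD provider is a lookup contract: there is no on-the-fly $r^2$
  computation from genotype panels, and no multi-allelic proxy
  resolution.
* Fisher-exact enrichment is a transparent stand-in for the upstream
  literature services' unpublished scoring; compare ranks, not
  p-values.
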