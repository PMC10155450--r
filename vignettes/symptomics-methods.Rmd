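---
title: "Methods: narrative-to-correlation symptom screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: narrative-to-correlation symptom screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis model

`symptomics` operationalises a simple but complete measurement model for
free-text psychopathology data. Each patient narrative is reduced to the
*set* of canonical symptoms it mentions; presence/absence is the only
retained signal. The analysis dataset is therefore a binary patient ×
symptom matrix, and every association question is answered by the phi
coefficient — the Pearson product-moment correlation of two 0/1
indicators, computed exactly from the 2×2 contingency table:

$$\phi = \frac{n_{11}n_{00} - n_{10}n_{01}}
              {\sqrt{n_{1\cdot}\,n_{0\cdot}\,n_{\cdot 1}\,n_{\cdot 0}}}.$$

The screen fixes one *index symptom* (default: auditory hallucination) and
computes, for every other symptom: phi, a Fisher-z confidence interval, a
p-value, post-hoc power, and a Cohen effect-size band.

Assumptions worth stating explicitly:

* **Mention = report = presence.** A narrative that uses a symptom word at
  least once is treated as reporting that symptom; multiplicity is
  discarded at encoding. Negation is ignored by default — lay narratives
  report absent sleep as "couldn't sleep", and treating any mention as a
  report is the behaviour consistent with manual filtering practice. An
  optional negation window (`negation_window > 0`) is available and is a
  documented divergence.
* **The lexicon is the construct definition.** Whether "sad" and
  "sadness" are one symptom is a vocabulary decision, not an algorithmic
  one; the package applies no stemming beyond the explicit variant lists.
* **Associations are marginal.** Phi between symptom and index is not
  adjusted for other symptoms; this is a screen, not a structural model.

## Inferential machinery

* **Confidence intervals** use the Fisher z-transform:
  $z = \operatorname{atanh} r$, $\mathrm{SE} = 1/\sqrt{n-3}$, bounds
  $\tanh(z \mp z_{\alpha/2}\,\mathrm{SE})$. At $n \approx 10^4$ this
  reproduces printed two-decimal intervals for two-decimal $r$ inputs.
* **p-values** use the exact t reference
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df (two-sided) rather than the
  normal approximation; at small n this is the correct reference and at
  large n the two agree to many digits.
* **Post-hoc power** evaluates the two-sided $\rho = 0$ test at the
  observed effect through the Fisher-z normal approximation:
  $\Phi(|z_r|\sqrt{n-3} - z_{\alpha/2}) + \Phi(-|z_r|\sqrt{n-3} -
  z_{\alpha/2})$. At $r = 0$ this equals the test size exactly (enforced
  as a special case: the floating-point
  `pnorm(qnorm())` round-trip is otherwise off in the 17th digit). The
  default $\alpha = 0.05$ is the conventional choice and reproduces a
  printed power of 1 at $n \approx 10^4$ for $|r| \ge 0.10$.
* **Banding** follows Cohen's conventions with lower edges inclusive:
  negligible below 0.10, small in [0.10, 0.30), medium in [0.30, 0.50),
  large at and above 0.50, applied to $|r|$.
* **Independence scan**: a symptom counts as independent of the index when
  $|r| < 0.005$, i.e. when the coefficient would print as 0.00 at the
  two-decimal reporting precision. This is a *reporting* notion of
  independence; at $n = 10^4$ the sampling probability that a truly
  independent pair lands inside the tolerance is only ≈ 0.38, so the
  scan's recall on truly-zero pairs is limited by design.
* **Multiple testing**: the screen reports raw p-values by default,
  matching standard practice in exploratory symptom screens;
  Benjamini–Hochberg adjustment is available via
  `screen_config(adjust = "benjamini-hochberg")`.

## Cleaning rules and their order

`clean_matrix()` applies, in order: (1) merge variant columns into their
canonical by logical OR; (2) drop blacklisted non-symptom columns;
(3) drop rows reporting no symptom; (4) drop exact duplicate records,
keeping the first. Steps (1)–(2) never change the row count; the report's
arithmetic invariant `output = input - zero_rows - duplicates` is checked
on construction, and cleaning is idempotent.

Two deliberate choices:

* **Duplicates are detected on raw narrative text** when texts are
  available (else on pattern *and* patient id). Deduplicating on the
  binary row pattern alone would remove thousands of genuinely distinct
  patients who report the same symptom set — statistically destructive
  and clearly not what a narrative-level duplicate means.
* **The stratified co-occurrence report is computed before row cleaning**
  (the zero-symptom stratum is part of the description) but after column
  merging, the only ordering in which its total row matches the raw corpus
  size.

## The synthetic corpus generator

The generator exists so that every pipeline stage can be validated against
known ground truth. It uses the standard latent-threshold (Gaussian
copula) construction for correlated binary data: each symptom $j$ has a
latent standard normal $Z_j$ and is present when $Z_j$ exceeds the
upper-tail quantile of its prevalence $p_j$; a pairwise phi target is
converted to the latent correlation $\rho$ whose thresholded bivariate
normal reproduces it. The forward map is evaluated by adaptive quadrature
of the conditional-tail integral

$$P(Z_1 > q_1, Z_2 > q_2) = \int_{q_1}^{\infty}\varphi(x)\,
  \Phi\!\Big(\frac{\rho x - q_2}{\sqrt{1-\rho^2}}\Big)\,dx$$

(`rel.tol` 1e-11) and inverted by monotone root-finding (`uniroot`,
tolerance 1e-10 on $\rho$, giving the target phi back to well within
1e-6). Targets are validated against the Fréchet feasibility bounds of
their margins; a jointly infeasible target set (non-PSD latent matrix)
fails loudly, with eigenvalue clipping available only by explicit opt-in
(`nearest_psd = TRUE`), because silently repaired ground truth is no
longer ground truth. Eigenvalues above −1e-6 are treated as numerical
zeros.

Narrative rendering writes each present symptom as $1 +
\mathrm{Poisson}(\text{repeat\_mention\_rate})$ mentions, each a uniformly
chosen surface form, shuffled together with filler words. Filler is
required to be disjoint from every *token* of every surface form — a
stronger condition than form-level disjointness — which guarantees the
round-trip property: extraction plus encoding of a rendered corpus
reproduces the generating matrix exactly, for every seed. One integer seed
drives matrix sampling, rendering, and duplicate injection through
documented offset streams.

### The study-scale default profile

`default_profile()` emulates the statistical structure of a large
web-scraped narrative corpus: 10,933 records; index symptom at 5.7%
prevalence; ten correlates planted at phi 0.10–0.26; six symptoms planted
exactly independent of the index (dissociation, obsession, compulsion,
hypertension, nausea, weight loss); two common mood symptoms (depression
0.46, anxiety 0.41) plus background structure (depression–anxiety 0.25,
sadness–low mood 0.20, obsession–compulsion 0.30); one injected exact
duplicate narrative.

Two profile-level design decisions:

* **One-factor completion.** A star of ten phi targets on a rare hub is
  not jointly feasible with mutually independent correlates: the solved
  latent correlations have a sum of squares near 2, so the star's latent
  matrix is far from PSD. The profile therefore expresses the solved
  hub–correlate correlations as loadings on a single shared factor and
  adds the implied correlate–correlate phi values as explicit targets.
  This keeps every hub target exact, guarantees a PSD joint model, and is
  also the more realistic structure — hallucination-spectrum symptoms do
  co-occur with each other, not only with the index.
* **Calibrated zero-symptom share.** Marginal prevalences were calibrated
  once, by large-n Monte Carlo of the profile itself, so that the expected
  share of narratives mentioning no symptom is ≈ 6.4% (≈ 704 of 10,933,
  the scale a real corpus of this kind exhibits); the calibrated profile
  gives an expected ≈ 707 zero renders. These are fixed study conditions,
  not tuning knobs.

### What the generator does and does not emulate

It reproduces: corpus scale, marginal prevalences, pairwise co-occurrence
correlations, surface-form variation, repeated mentions, filler text,
zero-symptom narratives, and duplicate records. It does **not** attempt
realistic language (no grammar, no negation semantics, no discourse), any
dependence beyond pairwise (the factor completion is a modelling
convenience, not a claim), or heterogeneity across patients in verbosity
or style. Passing round-trip and recovery tests therefore validates the
*pipeline arithmetic* on corpora with known truth; it does not validate
lexicon coverage or extraction precision on real clinical text, which
depend on vocabulary quality the package cannot supply.

A related caveat on scale: for rare symptom pairs at $n \approx 10^4$ the
sampling standard error of $\hat\phi$ is ≈ 0.01–0.03 (the count in the
$n_{11}$ cell is only ~10²), so single-corpus screened values scatter
around their planted targets accordingly, and dropping zero-symptom rows
before screening additionally attenuates rare-pair phi by a further
~0.002–0.005. Tests that assert recovery therefore average over seeds
(mean absolute error < 0.01 over 20 corpora) rather than asserting
single-draw closeness.

## Problem sizes used by the test suite

The suite validates: phi against brute-force Pearson on 1,000 random 2×2
tables (tolerance 1e-12); planted-parameter recovery over 20 corpora of
n = 10,000; render→extract→encode round-trips over 10 seeds at n = 200;
the analytic power formula against a 100,000-replicate Monte-Carlo
estimate at (r = 0.20, n = 100); and the archetypal three-narrative
fixture end to end. The full suite runs in well under a minute on one
CPU; these sizes were chosen to put each stochastic assertion's Monte
Carlo error an order of magnitude below its tolerance.

## Known limitations

* Extraction is exact-match over normalized tokens: misspellings,
  metaphor, and paraphrase ("the voices came back" without a lexicon
  entry) are invisible. This mirrors manual-filtering practice but caps
  recall on real text.
* Lay symptom words are taken at face value; "depression" in a narrative
  is not a clinical diagnosis, and the screen inherits that semantics.
* Phi between rare symptoms is margin-bounded (Fréchet): with a 5.7%
  index symptom, observed phi cannot reach 1 against most symptoms, and
  small printed coefficients are partly a ceiling effect.
* The independence scan is a reporting-precision statement, not a test of
  independence; use the confidence intervals for inference.
* Post-hoc power at the observed effect is reported for descriptive
  completeness because screening practice expects the column; it is a
  deterministic transform of (r, n) and adds no evidence beyond them.
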