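---
title: "Methods: ancestry-stratified molecular profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-stratified molecular profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcancestry)
```

This vignette documents the statistical model behind each module, the
numerical conventions the implementation commits to, the reasoning behind the
choices the methods literature leaves open, and the limitations of the
synthetic-cohort approach.

## 1. Scientific setting

Tumor molecular profiles differ systematically between patients of African
and European genetic ancestry, and disentangling those differences requires
three ingredients that rarely live in one toolchain: (i) a genetic (rather
than self-reported) assignment of each patient to an ancestry group, (ii)
group comparisons of somatic alteration prevalence that behave sensibly at
the modest carrier counts of a single cohort, and (iii) expression analyses
that survive the assay-version batch structure typical of clinical
sequencing archives. `bcancestry` implements that pipeline end to end and
pairs it with a synthetic-cohort generator so every stage can be exercised,
calibrated, and regression-tested without patient-level data.

## 2. Genotype model and reference panels

A reference panel gives alternate-allele frequencies $f_{mk}$ for marker
$m = 1,\dots,M$ in population $k = 1,\dots,K$ (populations AFR, AMR, EAS,
EUR, SAS). A patient with admixture proportions $q$ on the $K$-simplex has
per-marker alternate-allele dosage

$$g_m \sim \mathrm{Binomial}(2,\; a_m), \qquad a_m = \sum_k q_k f_{mk}.$$

Synthetic panels are drawn from the Balding–Nichols model: an ancestral
frequency $f_m \sim U(0.05, 0.95)$ and population frequencies

$$f_{mk} \sim \mathrm{Beta}\!\left(f_m\tfrac{1-F_k}{F_k},\;
  (1-f_m)\tfrac{1-F_k}{F_k}\right),$$

so $F_k$ is the expected fixation index of population $k$ against the
ancestral pool. Frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ to keep
all log-likelihood terms finite. The test suite confirms the construction
against a Hudson-type ratio-of-averages $F_{ST}$ estimator. The bundled
fixture `aim_panel_synthetic.tsv` holds 654 markers over the five
populations — the size of a realistic ancestry-informative-marker (AIM)
panel — and the generator defaults (`sim_config()`) describe a cohort of
623 African-ancestry and 2,810 European-ancestry patients, matching the
scale of the metastatic breast-cancer setting the package models.

## 3. Supervised admixture EM

With the panel fixed (supervised estimation), the per-patient log-likelihood

$$\ell(q) = \sum_m \big[g_m \log a_m + (2 - g_m)\log(1 - a_m)\big]$$

is concave in $q$. The EM update, with $M'$ non-missing markers,

$$q_k \leftarrow \frac{1}{2M'} \sum_m q_k\left[
  \frac{g_m f_{mk}}{a_m} + \frac{(2-g_m)(1-f_{mk})}{1-a_m}\right],$$

starts from the uniform $q_k = 1/K$ and stops when the log-likelihood gain
drops below `tol` (default $10^{-8}$). Numerical conventions:

* **Monotonicity** of $\ell$ across iterations is an invariant of the EM
  construction and is asserted in the tests rather than assumed.
* **Iteration cap.** The default `max_iter = 20000` is deliberately
  generous: solutions near the simplex boundary approach a tight tolerance
  slowly, and each iteration is a single $M \times K$ sweep. A fit that
  hits the cap is reported with `converged = FALSE` instead of being
  silently accepted.
* **Identifiability.** When populations are (nearly) exchangeable —
  e.g. $F \to 0$ — $q$ is unidentifiable and the point estimate can land
  anywhere on a flat likelihood ridge. The meaningful guarantees, both
  tested, are that the fitted log-likelihood exceeds the uniform-$q$
  log-likelihood by a negligible per-marker amount and that estimates are
  exactly equivariant under relabelling of the panel's populations.
* **Oracle checks.** At $K = 2$ the EM optimum is compared against an
  exhaustive grid search of the likelihood at step $10^{-4}$.

Classification into analysis groups uses strict threshold rules on the
fitted proportions: African ancestry (AA) requires
$q_{\mathrm{AFR}} > 0.20$, $q_{\mathrm{AMR}} < 0.10$, and
$q_{\mathrm{AFR}} + q_{\mathrm{EUR}} > 0.70$; European ancestry (EA)
requires $q_{\mathrm{EUR}} > 0.80$ and $q_{\mathrm{AMR}} < 0.10$; everyone
else is excluded. Boundary values fail the strict inequalities by design.

## 4. Contingency statistics

Two-group comparisons of clinical characteristics and carrier prevalence
use Pearson's chi-squared test with the Yates continuity correction for
$2 \times 2$ tables (`two_by_two_chisq()`); the corrected convention is the
one that reproduces published two-group cohort statistics from their
printed counts, which the test suite verifies to two significant figures.
For $r \times c$ tables (`rxc_chisq()`) no correction is applied — the
correction is a $2 \times 2$ convention — and zero-margin rows or columns
are dropped with a warning. Degenerate tables return the convention
statistic 0 and $p = 1$, flagged rather than hidden.

The continuity correction is conservative at moderate counts: in null
simulations its type-I error sits at or below the nominal level while the
uncorrected test stays inside the binomial sampling band around 0.05. The
suite pins both behaviors rather than pretending the corrected test is
exactly calibrated.

Where a multiplicity adjustment is required but the method is not dictated,
Benjamini–Hochberg is used (`bh_adjust()`, delegating to
`stats::p.adjust`), and the choice is recorded in output metadata. The
tumor-grade comparison is genuinely ambiguous — neither high-vs-low
(unknown excluded) nor the full low/high/unknown table is canonical — so
`build_cohort_table()` reports both variants and pins neither.

## 5. Batch-aware differential expression

Counts are converted to $\log_2$ counts-per-million with a prior count of
0.5. Within each assay batch, a two-sample moderated t-statistic shrinks
the pooled per-gene variance $s_g^2$ (on $d$ degrees of freedom) toward a
prior fitted by the method of moments on $z_g = \log s_g^2$:

$$\mathrm{trigamma}(d_0/2) = \max\{0,\ \mathrm{var}(z) -
\mathrm{trigamma}(d/2)\},$$

$$\log s_0^2 = \bar z - \psi(d/2) + \log(d/2) + \psi(d_0/2) - \log(d_0/2),$$

with $\psi$ the digamma function and the trigamma inverted by Newton
iteration. When the spread of $z$ does not exceed what sampling alone
explains, $d_0 = \infty$ is returned and all variances collapse to $s_0^2$
(the last two terms of the location equation vanish in that limit; note
$s_0^2$ equals a common variance only as $d \to \infty$, since
$E[\log s^2] \ne \log \sigma^2$ at finite $d$). The moderated statistic
uses $\tilde s^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ on $d_0 + d$ degrees
of freedom (normal at $d_0 = \infty$), and $d_0 = 0$ recovers the ordinary
pooled t-test exactly. The fit is cross-checked in the test suite against
an established empirical-Bayes reference implementation; the package's own
code is the implementation.

### Weighted-Fisher meta-analysis

Per-batch two-sided p-values are combined with sample-size weights
$w_i = n_i/\sum_j n_j$. Each $p_i$ is converted to a one-sided value toward
a **fixed** reference direction (AA up):

$$p_i' = \begin{cases} p_i/2 & \text{batch effect positive}\\
1 - p_i/2 & \text{otherwise,}\end{cases}$$

then $T = \sum_i F^{-1}_{\Gamma(Kw_i,\,2)}(1 - p_i')$ is referred to
$\Gamma(K, 2)$, giving a one-sided meta p-value that is **exactly** uniform
under the null (each $p_i'$ is uniform; the gamma components add). The
reported two-sided value is $\min\{1,\ 2\min(p_{meta}, 1 - p_{meta})\}$. At
equal weights the components are exponentials and $T = -2\sum_i \log p_i'$,
the classical Fisher statistic.

The anchoring deserves emphasis: converting one-sided p-values toward a
direction *estimated from the same data* (e.g. the weighted-logFC sign)
makes each $p_i'$ non-uniform under the null and destroys the calibration —
in 50,000-replicate simulations the data-anchored variant shows a
Kolmogorov–Smirnov distance of about 0.07 from uniform, while the fixed
anchor used here is indistinguishable from uniform (KS distance about
0.002). The fixed-direction anchor is therefore a deliberate, tested
numerical decision, with the overall direction label reported separately as
the sign of the sample-size-weighted logFC.

`meta_de()` wires the pieces together for exactly two batches, averages
logFC with sample-size weights, requires sign concordance between batches
before a gene can be called, and applies a Bonferroni cutoff
$\alpha_{family}/G$ (0.01 over 10,000 genes gives $10^{-6}$). Monotonicity
of the combined evidence in each input p-value holds on the one-sided
branch and is tested there; it cannot hold globally for a two-sided
statistic, which folds at $p_{meta} = 1/2$.

## 6. Single-sample gene-set enrichment

For each sample, genes are ranked by expression (average ranks for ties)
and walked in decreasing order. For a set $S$ with weights
$w_i = r_i^{\alpha}$ at rank $r_i$:

$$ES(S) = \sum_{i=1}^{N}\left[
  \frac{\sum_{j \le i,\, j \in S} w_j}{\sum_{j \in S} w_j}
  - \frac{\#\{j \le i,\ j \notin S\}}{N - |S|}\right].$$

Conventions and their rationale:

* $\alpha = 0.25$ is the default, the established single-sample convention
  (milder than the $\alpha = 1$ of cohort-level enrichment scoring).
* Scores depend only on within-sample ranks, so they are invariant under
  any strictly increasing transform of one sample's values — tested, and
  the property end users should rely on when mixing normalizations.
* Normalization divides the whole score matrix by one global
  $\max - \min$ scalar, preserving every ordering and sign; per-sample
  normalizations were rejected because they break cross-sample
  comparability of the scores that the group test consumes.
* At $\alpha = 0$ the score of a set and of its complement are exact
  mirrors, a structural identity used as an oracle in the tests; a
  five-gene worked example is pinned to its enumerated value 2.513943.
* A set covering *all* genes has an undefined out-of-set ECDF and is an
  error, not a silent zero.

Group comparison of scores reuses the moderated t machinery across sets
with a Bonferroni cutoff $\alpha_{family}/\text{sets}$; the bundled
239-set collection gives $0.01/239 = 4.2 \times 10^{-5}$.

## 7. The synthetic-cohort generator

`sim_config()` centralizes the generator parameters; the defaults describe
the cohort the package models: 623 AA / 2,810 EA patients, a 654-marker
five-population AIM panel at $F = 0.15$ (a realistic continental-scale
differentiation), stage/subtype/grade composition matching a published
Table-1-style metastatic breast-cancer cohort (e.g. 83.31% of AA patients
stage IV, 22.95% TNBC), carrier prevalences per gene–group–subtype (e.g.
PIK3CA in HR+/HER2− disease: 34% AA vs 42% EA; KMT2C in TNBC: 23% vs 12%),
and negative-binomial expression with

$$\log_2 \mu_{gs} = b_g + \beta_g\,[\text{AA}] + \delta_g\,[\text{batch v2}]
 + \log_2(\text{libsize}_s/10^6), \qquad
 \mathrm{Var} = \mu + \phi_g \mu^2,$$

per-gene dispersions $\phi_g$ log-normal around 0.1, a planted effect
$\beta_g = \pm$`effect_size` in a `de_fraction` of genes recorded in a
truth registry, and a modest assay-version shift $\delta_g$. Every
generator function takes an explicit seed and is bitwise reproducible.

## 8. Decisions on open questions

* **Multiplicity method** unspecified upstream → Benjamini–Hochberg,
  recorded in metadata (gene-level prevalence scans); Bonferroni where a
  printed family cutoff exists (meta-DE, enrichment).
* **Grade comparison grouping** ambiguous → both variants reported,
  neither pinned (Section 4).
* **wFisher one-sided anchor** → fixed reference direction, because the
  data-driven alternative fails null calibration (Section 5).
* **Concordance filter** → sign agreement between batches is required
  *before* significance, so a discordant gene can never be significant
  regardless of its combined p-value.
* **EB prior at zero spread** → explicit $d_0 = \infty$ sentinel instead
  of a large finite cap, keeping the normal-reference limit exact.

## 9. Limitations

* Synthetic cohorts validate *software and statistics*, not biology: the
  generator's independence assumptions (mutations independent across genes
  given group and subtype; expression effects independent of mutation
  status) are simplifications, and effect sizes recovered from it say
  nothing about real effect sizes.
* The admixture model ignores linkage disequilibrium between markers —
  standard for AIM-scale panels, increasingly wrong for dense genotyping.
* Supervised estimation inherits any bias in the reference panel; the
  package never re-estimates panel frequencies.
* At AIM-panel marker counts, heavily admixed interior points of the
  simplex are information-limited: no estimator can recover them to the
  accuracy achievable for near-vertex (cohort-typical) compositions, which
  is why accuracy guarantees are stated for cohort-like mixtures.
* The meta-analysis supports exactly two assay batches, mirroring its
  target setting, and the continuity-corrected chi-squared is conservative
  at small counts (Section 4).

## 10. Worked example

```{r example, eval = FALSE}
set.seed(1)
clin <- simulate_clinical(60, 60, seed = 1)
cfg <- sim_config(seed = 2, n_AA = 60, n_EA = 60, G = 2000,
                  de_fraction = 0.05, libsize_range = c(1e6, 2e6))
sim <- simulate_counts(clin, cfg)
res <- meta_de(sim$counts, sim$samples)
glance(res)
autoplot(res)
```
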