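---
title: "Two-sample Mendelian randomization with mrkit: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The problem mrkit addresses

Observational associations between circulating cell counts (or any
heritable exposure) and disease are confounded and can run in either
causal direction. Two-sample Mendelian randomization (MR) sidesteps both
problems by using genetic variants as instrumental variables: because
alleles are assigned at conception, a variant that raises the exposure can
only associate with the outcome through a causal path — provided three
assumptions hold:

1. **Relevance** — the variant is robustly associated with the exposure;
2. **Independence** — the variant is not associated with confounders of the
   exposure–outcome relationship;
3. **Exclusion restriction** — the variant affects the outcome only through
   the exposure (no horizontal pleiotropy).

mrkit implements the complete summary-statistics workflow: reading and
validating GWAS association tables, selecting independent strong
instruments, harmonizing exposure and outcome effects onto a shared effect
allele, estimating the causal effect, and probing the third assumption
with a suite of sensitivity analyses. A synthetic two-sample generator with
known causal truth makes every stage testable at desk scale.

Only assumption 1 is directly enforceable from data (significance and
F-statistic screens). Assumptions 2 and 3 are addressed operationally: a
user-supplied exclusion list of confounder-associated variants
(`drop_listed()`), an outcome-overlap screen (`drop_outcome_associated()`),
and the pleiotropy diagnostics below. They remain assumptions, not
guarantees; the pipeline's role is to make their audit trail explicit.

## Notation and the data model

For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its estimated
per-allele effect on the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$)
its effect on the outcome, estimated in two non-overlapping samples and
harmonized to the same effect allele. For a binary outcome the
$\hat\beta_{Yj}$ are log-odds ratios. The working model is

$$\hat\beta_{Yj} \approx \beta\,\hat\beta_{Xj} + \alpha_j + \varepsilon_j,
\qquad \varepsilon_j \sim N(0, \sigma_{Yj}^2),$$

where $\beta$ is the causal effect of one SD of exposure on the outcome
log-odds and $\alpha_j$ is a direct (pleiotropic) effect, zero for a valid
instrument.

## Estimators

* **Wald ratio** (single instrument):
  $\hat\beta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order SE
  $\sigma_{Yj}/|\hat\beta_{Xj}|$. The exposure-side uncertainty is second
  order for strong instruments (the F > 10 screen upstream makes this the
  operative regime); `wald_ratio(second_order = TRUE)` adds it.
* **IVW**: weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $w_j = 1/\sigma_{Yj}^2$, i.e.
  $\hat\beta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$, fixed-effects SE $(\sum w_j \hat\beta_{Xj}^2)^{-1/2}$.
  Heterogeneity is Cochran's
  $Q = \sum_j w_j(\hat\beta_{Yj} - \hat\beta\hat\beta_{Xj})^2$ on $n-1$
  df. The **random-effects** variant (the primary estimator here) is the
  multiplicative-overdispersion model: the SE is inflated by
  $\max\{1, \sqrt{Q/(n-1)}\}$, which leaves the point estimate unchanged
  and never reports less uncertainty than the fixed-effects fit.
* **Weighted median**: order the Wald ratios; with normalized first-order
  ratio weights $w'_j \propto \hat\beta_{Xj}^2/\sigma_{Yj}^2$, linearly
  interpolate the ratio at cumulative weight $1/2$ (using
  $s_j = \sum_{i\le j} w'_i - w'_j/2$). Consistent when instruments
  carrying at least half the weight are valid. The SE comes from a
  parametric bootstrap: $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ are
  resampled from normal distributions with their reported SEs and the
  median recomputed; the seed is a mandatory argument so results are
  reproducible by construction.
* **MR-Egger**: the same weighted regression with a free intercept, after
  orienting every instrument so $\hat\beta_{Xj} \ge 0$ (negating both
  betas of any instrument pointing the other way — a relabeling of the
  effect allele, under which all estimators here are invariant). A nonzero
  intercept estimates the mean directional pleiotropic effect; the slope
  is a causal estimate that remains consistent under the InSIDE assumption
  (instrument strength independent of direct effects). Both SEs carry the
  $\max\{1,\sqrt{Q'/(n-2)}\}$ overdispersion factor.
* **Radial IVW**: regress $\hat\beta_j\sqrt{w_j}$ on $\sqrt{w_j}$ through
  the origin with ratio weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.
  The slope is algebraically the IVW estimate; its per-SNP squared
  residual $q_j = w_j(\hat\beta_j - \hat\beta)^2$ decomposes $Q$ exactly.
  An instrument is flagged as a pleiotropic outlier when $q_j$ exceeds the
  upper $\alpha$ tail of $\chi^2_1$ ($\alpha = 0.05$ by default, no
  multiplicity correction — pass `outlier_alpha = 0.05/n` for a
  Bonferroni screen). Flagged instruments are removed and the IVW rerun.
* **Leave-one-out**: the random-effects IVW refit $n$ times, each
  excluding one instrument, to expose single-variant influence.

With one surviving instrument the pipeline reports the Wald ratio alone;
with two, IVW plus Q; from three, the full suite (the weighted median and
Egger are undefined below three).

## Instrument selection parameters

`selection_config()` holds the four screens, applied in order:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5e-9 | exposure significance (strict `<`). The tightened default suits very large single-trait GWASs where genome-wide 5e-8 yields thousands of hits; for modest GWASs (e.g. a few thousand flow-cytometry profiles) use 5e-8. |
| `clump_r2`, `clump_window_kb` | 0.001, 1000 | greedy LD clumping: repeatedly keep the smallest-p remaining SNP, discard same-chromosome SNPs within the window (inclusive, center-to-center kb) with $r^2 \ge$ threshold. A relaxed 0.1/500 pairing is conventional for small GWASs. |
| `f_min` | 10 | per-SNP F statistic $(\hat\beta/\sigma)^2$ must exceed this (weak-instrument screen). |
| `outcome_p_exclude` | 1e-5 | instruments whose outcome association is already suggestive are removed as potentially pleiotropic; `0` disables the screen. |

Clumping ties on p-value are broken by (chromosome, position, snp_id)
ascending, so results are identical across platforms. Duplicate rsIDs are
resolved at parse time keeping the smallest p. Instruments absent from the
outcome table are dropped, not proxied: no LD-proxy search is performed,
so results do not depend on a proxy panel.

## Harmonization

Exposure and outcome effects must refer to the same allele before any
ratio is meaningful. For each shared SNP the allele encodings are
compared; swapped encodings negate the outcome beta (and flip its
frequency), and strand-complement encodings (A/G vs T/C) are resolved
deterministically for non-palindromic SNPs — these arise routinely between
consortia and carry no ambiguity. Allele sets that match under neither
reading are dropped as incompatible.

Palindromic SNPs (A/T, C/G) are the genuinely ambiguous case: the allele
letters are identical on both strands, so only the allele frequency can
identify the orientation. The package drops palindromes whose exposure EAF
lies strictly inside the symmetric window (0.42, 0.58) — near 0.5 the
frequency carries no strand information — and orients the remainder by
frequency agreement with the outcome study when its EAF is available. A
one-sided reading of an "EAF > 0.42" rule would discard every common-allele
palindrome while keeping its mirror image, an asymmetry with no
statistical rationale, so the symmetric window is the default; the
conservative alternative of dropping all palindromes is available as
`harmonize_config(drop_all_palindromic = TRUE)`. Palindromes with missing
exposure EAF are always dropped: their ambiguity cannot be assessed.

The harmonization report accounts for every input SNP exactly once
(kept / flipped / dropped with reason), which the tests assert, and two
invariances pin the semantics down: harmonizing an already-harmonized pair
is a no-op, and re-encoding the outcome file (swap alleles, negate betas,
flip EAFs) changes neither the harmonized table nor any downstream
estimate.

## The synthetic two-sample generator

`simulate_pair()` draws true per-SNP exposure effects
$\gamma_j \sim |N(0, \texttt{gamma\_sd}^2)|$ once and treats them as fixed
truth, then samples the two studies independently:
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_X^2)$ and
$\hat\beta_{Yj} \sim N(\beta\gamma_j + \alpha_j, \sigma_Y^2)$. Direct
effects $\alpha_j$ are zero (`none`), centered (`balanced`, which
satisfies InSIDE because $\alpha_j$ is drawn independently of $\gamma_j$),
or shifted (`directional`, adding `pleiotropy_mean`). Effect alleles are
oriented to the exposure-increasing allele — hence the half-normal
$\gamma_j$ — which is what makes a *directional* mean direct effect well
defined: reorienting an allele flips $\gamma_j$ and $\alpha_j$ together,
so a mean pleiotropic effect is only meaningful in a fixed orientation,
and this is the orientation MR-Egger estimates in.

Defaults were chosen once to emulate the regime of a consortium-scale
quantitative exposure GWAS read against a large case–control outcome GWAS:
`se_exposure = 0.002` (the per-allele SE of a trait in SD units at
$n \approx 5.6\times10^5$ and typical MAF, $\sigma \approx
1/\sqrt{2f(1-f)n}$), `se_outcome = 0.003` (log-odds SE at the effective
size of a study with tens of thousands of cases and an order of magnitude
more controls), and `gamma_sd = 0.02`, putting per-allele effects in the
range reported for blood-cell-count loci and the mean instrument F near
100. EAFs are uniform on (0.05, 0.95); a configurable fraction of SNPs
(default 10%) receives palindromic alleles. LD is encoded directly as a
block-diagonal $r^2$ matrix — clumping consumes only $r^2$, so no
genotype-level simulation is needed — with block members placed 10 kb
apart (inside any realistic clumping window) and unlinked SNPs given zero
$r^2$.

What the generator deliberately does not emulate: winner's curse beyond
what selection-on-noisy-estimates naturally induces (the $\gamma_j$ are
fixed truth), sample overlap between the two studies, InSIDE violations
(correlated pleiotropy), allele-frequency differences between studies, and
population stratification. Passing calibration therefore demonstrates that
the estimators and pipeline are correct under the model MR assumes — not
that real consortium data satisfy that model.

`calibration_study()` runs the full pipeline per replicate — selection,
harmonization, estimation — with per-replicate substream seeds drawn from
one master seed, so replicates are independent yet individually
reproducible. The packaged studies use 1000 replicates of 50-SNP panels
(the analysis script uses 500), sizes at which the Monte-Carlo SE of a
rejection rate is under 0.01 and each study completes in about half a
minute on one core. Of the 50 candidates roughly 30 survive selection at
5e-8 under the default effect-size distribution; the calibration tables
report the realized mean instrument count. The directional-pleiotropy
study disables the outcome-overlap screen: with pleiotropic effects of
0.02 against an outcome SE of 0.003, that screen removes precisely the
planted pleiotropic instruments, and nothing would remain for the Egger
intercept to measure — in real analyses the screen is a feature; in this
calibration it would empty the measurand.

## Numerical and reporting choices

* p-values are computed as $2\Phi(-|z|)$ and floored at the smallest
  positive double; input p-values of exactly 0 are floored likewise (with
  a log note) so downstream log/threshold operations are safe.
* All threshold comparisons are strict (`<`), matching the conventional
  statement of each rule.
* Serialized tables are tab-separated with `NA` for missing and
  floating-point fields written with 17 significant digits, so
  write-then-read is lossless; gzip is handled transparently.
* 95% CIs are normal-based on the log-odds scale and exponentiated for
  odds ratios; report tables round half-to-even (2 decimals for ORs, 4 for
  p-values by default).
* Significance tiers are exhaustive and mutually exclusive:
  `bonferroni_significant` iff $p < 0.05/m$, `nominal` iff
  $0.05/m \le p < 0.05$, else `null`. The divisor $m$ is explicit
  configuration (`bonferroni_m`, default 6): when several exposure
  families are analyzed, the divisor is per family and should be set to
  the family size rather than the global test count.
* `run_mr()` never mutates its inputs; every stage logs its drop counts
  and reasons (enable with `options(mrkit.verbose = TRUE)`), and all
  stochastic steps take explicit seeds, so identical configurations
  produce byte-identical reports.

## Worked example

```{r example}
sim <- simulate_pair(sim_config(n_snp = 60, beta_causal = 0.06, seed = 7,
                                prop_palindromic = 0.15,
                                ld_blocks = list(c(5, 0.9))))
run <- run_mr(list(monocyte_count = sim$exposure), sim$outcome, sim$ld,
              selection = selection_config(p_threshold = 5e-8),
              outcome_label = "t2d", n_boot = 1000, seed = 42)
writeLines(render_forest_table(run$rows))
```

The true odds ratio here is $e^{0.06} = 1.062$ per SD of exposure; the
IVW row is the primary estimate, the weighted median and Egger slope are
sensitivity estimates, and the `outlier_removed` row reruns IVW after
radial outlier exclusion.

## Known limitations

* The F statistic is the single-SNP $(\hat\beta/\sigma)^2$ approximation;
  no $R^2$/sample-size form is computed.
* Random effects are multiplicative only; an additive (DerSimonian–Laird
  style) model is not provided.
* No MR-PRESSO, mode-based, multivariable, or contamination-mixture
  estimators; no proxy-SNP substitution; no strand inference from LD.
* The weighted-median bootstrap is parametric-normal; with very weak
  instruments (near-zero $\hat\beta_{Xj}$) resampled ratios can be heavy
  tailed, which the median tolerates but which inflates the bootstrap SE —
  the upstream F screen keeps the pipeline out of that regime.
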