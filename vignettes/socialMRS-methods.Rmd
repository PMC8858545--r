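---
title: "socialMRS: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{socialMRS: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialMRS)
```

# Scope

`socialMRS` analyzes cohorts in which each mouse contributes (a)
three-chamber social behavior scores and (b) ¹H-MRS metabolite
quantifications with per-measurement Cramér–Rao lower bounds (CRLB, %SD)
from two brain voxels, prefrontal cortex (PFC) and hippocampus (HPC). The
pipeline computes preference indices, quality-filters and derives metabolite
features, screens features against behavior with a permutation-calibrated
Pearson correlation, compares genotypes, and evaluates single-feature
biomarkers with binormal ROC curves. MR acquisition and full spectral
quantification are out of scope: the package consumes already-quantified
tables, and its toy spectral fitter exists to generate mechanistically
plausible CRLB values, not to compete with production quantification
software.

# The generative model behind the synthetic cohorts

Every downstream stage is validated on simulated cohorts with known truth.
The generator (`cohortSpec()`, `simulateCohort()`) uses a single
**latent sociability score** per animal,

$$s_i \sim \mathcal{N}(\mu_{g(i)},\, 1),$$

with genotype means $\mu_{WT} = 2$, $\mu_{KO} = 0$ by default. One latent
variable drives both sides of the analysis:

- **Behavior.** The preference index is
  $PI_i = \alpha_{sess} + \beta_{sess}\, s_i + \varepsilon_i$, with
  $\varepsilon_i \sim \mathcal{N}(0, 0.15^2)$, clipped to $[-1, 1]$ by
  construction: the index is realized through a time allocation,
  `explorationTimesFromPI()`, which splits a uniformly drawn total
  exploration time (80–160 s) so the PI identity holds exactly. Defaults:
  preference session $\alpha = 0$, $\beta = 0.3$ (wild types average
  $PI \approx 0.6$, knockouts $\approx 0$); recognition session
  $\alpha = 0.2$, $\beta = 0.05$ (a weak, genotype-insensitive signal).
- **Metabolites.** Each (region, metabolite) concentration is
  $c = \text{baseline} + \delta\,[g = KO] + \kappa\, s + \mathcal{N}(0,
  \sigma^2)$, truncated at zero. CRLB %SD is drawn independently from a
  shifted gamma, $\text{CRLB} = 3 + \Gamma(2, \text{scale}_m)$ with
  $\text{scale}_m = \max(1, 25 / (\text{mean}_m + 1))$, so low-abundance
  metabolites (Scyllo, NAAG, PCh, ...) regularly exceed the 50% filter
  threshold while abundant ones rarely do — the quality-control path is
  always exercised.

This latent-variable structure was chosen over a direct bivariate-normal
(PI, metabolite) model because one mechanism must produce *both* the
genotype difference in the feature *and* its correlation with behavior, the
joint pattern the analysis is designed to detect. Ratios are never generated
directly: the generator shifts component metabolites (knockouts: Glu down,
GABA up in PFC), and the pipeline must derive Glu/GABA itself.

**Default effect sizes.** No public per-animal concentration table exists
for this design, so baselines are typical rodent-brain values at high field
in arbitrary units (NAA 8.5, Glu 10, Tau 8, Ins 5.5, Cr = PCr 4, Gln 3,
GABA 2.5, ... down to Scyllo 0.2) with ~8–12% CV, all config-overridable.
The planted signal — knockout shifts Glu −0.2, GABA +0.12, Cr and PCr −0.3
in PFC; Glu +0.5 and Gln +0.4 in HPC; latent coupling 0.7 on PFC Glu and
0.12 on PFC Cr/PCr — was sized once, analytically, so the generative
(delta-method) AUC of the prefrontal Glu/GABA ratio is ≈ 0.84 at the
default 9 + 11 group sizes, the regime the biomarker evaluation targets:

```{r}
generativeAUC(cohortSpec(), "Glu/GABA", "PFC", positive = "WT")
```

`generativeAUC()` treats ratios as approximately Gaussian via the
first-order delta method; raw metabolites and sums are exactly Gaussian
under the model, so for them the closed form is exact.

**What the simulations do not emulate.** Real MRS data have correlated
quantification errors across metabolites (overlapping resonances), CRLB
values that depend on the concentration itself, voxel-composition and
shimming differences between animals, and non-Gaussian behavioral scores.
Passing the recovery and calibration tests therefore demonstrates that the
*statistical machinery* is correct and calibrated under its stated
assumptions — not that those assumptions hold in any particular scanner's
output.

# Feature construction

- **CRLB filter** (`applyCrlbFilter()`): retain iff CRLB %SD ≤ 50. The
  boundary is inclusive: a measurement at exactly 50% is kept. Filtered
  cells become missing — never zero, never imputed — and every removal is
  logged with its reason.
- **Inclusion rule** (`metaboliteInclusion()`): the default `per_group`
  mode requires at least `minN = 5` surviving animals in *each* genotype
  group. The convention "more than 5 individuals overall" is ambiguous when
  a group of exactly 5 appears in published per-metabolite counts; the
  per-group ≥ 5 reading reproduces those counts, and the literal pooled
  `total` mode (count strictly > `minN`) is available as a switch. Neither
  is asserted to be the original intent.
- **Derived features** (`buildFeatureTable()`): tCr = Cr + PCr,
  Glx = Gln + Glu, and the ratios Glu/GABA, GABA/Glu, NAA/tCr, PCr/tCr. A
  derived cell is missing iff any component is missing; denominators must
  be strictly positive (a zero denominator yields a logged missing cell,
  never an infinity). A derived feature is *included* iff all its
  components are included. Concentration units are treated as opaque
  throughout; no unit conversion is attempted.

All downstream statistics use pairwise-complete observations, so the
effective n varies per feature — by design, mirroring per-metabolite
inclusion counts in real studies.

# The correlation screen

For each included feature and behavior index, the screen computes Pearson's
*r* and a permutation p-value: the empirical null is built by re-pairing the
two vectors B times (default B = 5000), and

$$Pr = \frac{1 + \#\{b: |r_b| \ge |r_{obs}|\}}{B + 1}.$$

Conventions, each deliberate:

- **Sidedness.** Two-sided on $|r|$ by default, because both positive and
  negative correlations are of interest in a volcano screen; one-sided
  modes are available.
- **Add-one rule.** The +1 in numerator and denominator keeps the p-value
  valid at finite B and never exactly zero. The exhaustive mode (n ≤ 9)
  enumerates all $n!$ permutations and divides the count — which includes
  the identity permutation — by $n!$, so it is also never zero.
- **Tiers.** q95 iff Pr < 0.05, q975 iff Pr < 0.025 — the two quantile
  levels marked on the volcano plot. No across-feature multiplicity
  correction is applied by default: the permutation p is reported as is,
  per feature. (A Benjamini–Hochberg column can be added by the user from
  `screen_results.csv`; it is beyond the default analysis.)
- **RNG discipline.** Each (region, feature, index) combination gets its own
  RNG stream derived by hashing the key with the master seed, so results do
  not depend on the order in which features are screened, and adding a
  feature never changes another feature's p-value. Whether the original
  analysis shared one permutation set across features is unknowable from
  the outside; per-feature streams are the cleaner default and are
  documented here.
- **Performance.** The permutation core is compiled (Rcpp), using R's own
  RNG so `set.seed()` governs it; a calibration run of 1000 null screens at
  B = 2000 takes ~1 s.

Group comparisons default to Welch's t (Satterthwaite df); Student's t with
pooled variance is provided because small-sample MRS studies sometimes
report it for selected metabolites. Both are thin, validated wrappers over
`stats::t.test`; two constant, equal groups return p = 1 by convention with
a message. The three-chamber session itself is analyzed with an ordinary
two-way (genotype × target) ANOVA with interaction — each animal contributes
one value per target side, treated as independent observations, matching the
between-cell contrast layout customary for this assay rather than a
repeated-measures model — followed by within-genotype Sidak-adjusted
contrasts ($p_{adj} = 1 - (1-p)^k$) using the ANOVA error mean square. The
implementation reports the degrees of freedom it computes and never forces
a published df value.

# Biomarker evaluation

`fitSimpleLogistic()` fits class membership on one feature by IRLS
(`stats::glm`, tolerance 1e-8, ≤ 100 iterations). Training is deliberately
in-sample — with ~20 animals a held-out split would be noise — and every
report carries a note to that effect. Complete separation is detected and
flagged rather than silently returning a huge slope.

`binormalRoc()` fits $\mathcal{N}(\mu_0, \sigma_0)$, $\mathcal{N}(\mu_1,
\sigma_1)$ by sample moments; AUC $= \Phi\!\big((\mu_1 - \mu_0)/
\sqrt{\sigma_0^2 + \sigma_1^2}\big)$. Conventions:

- **Orientation.** Higher score = more positive. The AUC is *not* forced
  above 0.5; a feature that scores lower in the positive class yields
  AUC < 0.5 unless `autoFlip = TRUE`. This keeps label semantics honest.
- **Positive class.** Required, explicit, echoed in every output row. With
  asymmetric groups (9 vs 11) sensitivity and specificity swap meaning with
  the class convention, so no silent default is defensible.
- **CI.** Hanley–McNeil standard error at 95% by default; a seeded
  percentile bootstrap (2000 resamples) as the alternative. The interval is
  clipped to [0, 1].
- **Cutoff.** Youden's J maximized analytically on the binormal curve (the
  stationarity condition reduces to a quadratic; the equal-variance case
  gives the midpoint of the means). Both model-based and empirical
  sensitivity/specificity at the cutoff are reported, as percentages. A
  degenerate ROC (identical class distributions) is flagged, with J = 0.

# The toy spectral quantifier

`synthesizeSpectrum()` renders metabolite basis lineshapes (Lorentzian or
Gaussian peak lists) on a decreasing ppm grid, adds a polynomial baseline
and iid Gaussian noise. `fitSpectrum()` estimates concentrations by
non-negative least squares — concentrations are physical — with an
unconstrained baseline (its columns are split into positive and negative
parts so the augmented problem remains an NNLS, solved by
`pracma::lsqnonneg`). The covariance on the active set is
$\sigma^2 (G^\top G)^{-1}$ and CRLB %SD $= 100\,\sqrt{\mathrm{var}} /
\hat{c}$, infinite for estimates pinned at zero. When $\sigma$ is not
supplied it is estimated from a signal-free window (default 9–10 ppm) after
linear detrending. Rank-deficient (collinear) bases are rejected with the
offending metabolites named. Baseline degree defaults to 2; splines were
rejected as needless flexibility for a toy.

Numerically: noiseless spectra are recovered to machine precision, CRLB
scales linearly in $\sigma$, and residuals are orthogonal to the active
design columns — all asserted in the test suite.

# Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at sizes chosen to give
tight Monte-Carlo error at desk scale: permutation calibration over 1000
null replicates (n = 20, B = 2000); exhaustive-vs-sampled agreement at
n = 7 (5040 permutations both ways); empirical-vs-closed-form AUC at
10⁵ samples per class; planted-signal recovery over 200 replicate 9 + 11
cohorts and null calibration over 500, both with B = 999 per feature
(tier decisions at the 0.05 level are insensitive to B beyond ~10³, and the
add-one rule makes the null rejection rate exactly 49/1000 there); CRLB
noise scaling over 100 seeds. The user-facing default stays B = 5000.

# Known limitations

- The binormal ROC assumes within-class normality; with n = 9 + 11 the
  moment estimates are noisy, and the Hanley–McNeil interval is itself an
  approximation. The bootstrap option quantifies this but cannot fix it.
- The delta-method "generative AUC" for ratio features is first-order; for
  very noisy denominators (CV ≳ 20%) it drifts from the exact value.
- In-sample logistic training overstates discriminative performance by
  construction; the package reproduces that choice for fidelity and labels
  it, but offers no cross-validation.
- The permutation screen calibrates each feature's p-value marginally; the
  family of features remains uncorrected by default.
- Zero-exploration animals have no defined preference index and are
  excluded with a log entry; no convention for scoring them is imposed.
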