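---
title: "Models and methods behind aortaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aortaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

This vignette is the package's own account of its science: the models
each stage fits, the assumptions they make, the tunable parameters and
why their defaults are what they are, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## 1. Haemodynamic metrics from cine velocity maps

The raw input is a `cine_flow` object: a time-ordered stack of 2D
through-plane velocity maps (m/s) over a fixed lumen mask with known
pixel spacing (mm). From it, `flow_metrics()` derives

* `CSA` (mm²) — masked pixel count × pixel area;
* `D` (m) — the equivalent-circle diameter `2*sqrt(CSA/pi)`. We compute
  `D` from the traced area rather than treating it as an independent
  caliper measurement because the area is reproducible from the mask,
  while a manual diameter depends on operator and measurement angle.
  A caller who has an independent diameter can pass it straight to
  `reynolds()`;
* `U_pm` (m/s) — the maximum over frames of the *spatial mean* velocity
  within the mask;
* `U_max` (m/s) — the maximum over frames and pixels;
* `Re_pm = rho*U_pm*D/mu` and `Re_max = rho*U_max*D/mu`.

Both Reynolds numbers carry the density factor `rho`; a definition of
`Re_pm` without it would not be dimensionless, so the package uses the
general form consistently for both metrics.

Conventions worth stating:

* **Negative (regurgitant) velocities** enter the spatial mean as-signed,
  because that is what a phase-contrast acquisition reports; the frame
  maximum is the signed maximum by default, with
  `max_by_magnitude = TRUE` available when jets of either sign matter.
* **Ties across frames** are broken toward the earliest frame, and pixel
  ties row-major, so results are deterministic.
* **Units** are enforced at the container boundary: a `cine_flow`
  declared in cm/s is converted to m/s on construction, never downstream.
  Mixing the two units silently would inflate Re a hundredfold.
* **Venc**: velocities beyond the declared encoding limit raise a
  warning, not an error — aliasing is not modelled, and real data would
  need unwrapping upstream.
* Fluid constants default to `rho = 1050` kg/m³ and `mu = 3e-3` N·s/m²,
  the standard values for blood; both are exposed in `fluid_constants()`
  since individual variation in viscosity is a known limitation of any
  fixed-constant Reynolds estimate.
* The turbulence classification threshold (`Re_pm > 4000`, the
  straight-pipe transition value) is a reporting convention only and is
  exposed in `run_config()`.

## 2. The synthetic cohort

The generator exists so that every downstream stage can be exercised
with known ground truth. It is calibrated, not a reconstruction of any
real recruitment history.

**Pedigrees** (`simulate_pedigrees()`): each family is three
generations — an optional grandparent couple (probability 0.3), a parent
couple (one lineal, one married-in founder), and a sibship of at least
three, with the size drawn from a truncated Poisson offset
(`3 + Poisson(0.7)`). One sibling per family is the proband and is
always phenotyped and hypertensive, mimicking ascertainment through a
hypertension clinic without a liability-threshold model — downstream
analysis only ever adjusts for hypertension as a binary covariate, so a
fuller ascertainment model would add parameters the pipeline cannot see.
Role-specific phenotyping probabilities (grandparent 0.10, parent 0.30,
sib 0.55) put the expected phenotyped count of a 108-family cohort at
about 341. A `genotyped` flag (rate 0.90) reproduces the fact that some
imaged subjects lack genotypes, so SNP-based fits run on a subset.

**Genotypes** (`simulate_genotypes()`): founders draw two independent
Bernoulli(p) allele copies (Hardy–Weinberg proportions); non-founders
inherit one allele from each parent uniformly at random per SNP — plain
gene dropping. SNPs are independent: linkage disequilibrium is off by
default because none of the estimators tested here (kinship, GRM,
single-component REML) requires LD to have the properties we verify.
Missingness is completely at random at a configurable rate.

**Covariates** (`simulate_covariates()`): BMI ~ N(25.88, 3.77²),
systolic BP ~ N(139.71, 21.83²), 49% male, hypertension prevalence
calibrated to about 39% among phenotyped members once probands are
forced positive (non-proband rate 0.107 under the default structure).
Ages descend through the pedigree: founder parents around 70, each child
the parental midpoint minus N(26, 4) years, clipped to 19–73. The
resulting phenotyped-cohort mean is about 47 years. Covariates are
mutually independent by design — the generator matches marginal moments,
not the covariance structure of real clinical data (SBP is *not* higher
in hypertensives here, for example).

**Traits** (`simulate_trait()`): `y = X*beta + g + e` with
`g ~ MVN(0, 2*Phi*sigma2_g)` drawn per family block (kinship mode) or a
rescaled sum of 100 causal-SNP effects (causal mode), and iid Gaussian
environment. `trait_spec()` enforces `h2 = sigma2_g/(sigma2_g+sigma2_e)`
exactly. Causal mode standardises the genetic score to variance
`sigma2_g` in the generated cohort, so the realised heritability equals
the target by construction.

**Velocity phantoms** (`simulate_flow_series()`): a disc mask, a radial
profile `v(r) = v_c * (1 - (r/R)^q)`, a smooth cardiac waveform
(Gaussian systolic pulse over a 5% diastolic baseline) and iid pixel
noise. The profile exponent default `q = 2.62` is chosen so the
spatial-mean to centreline ratio `q/(q+2)` matches the observed
`U_pm/U_max ~ 0.57` of adult aortic flow — blunter than Poiseuille
(`q = 2`), as expected for a pulsatile entrance flow. Cohort defaults
(radius 15.5 mm on a 64×64 grid of 1.25 mm pixels, peak centreline
velocity 0.79 m/s, noise 5 mm/s) give cohort means near U_pm 0.45 m/s,
U_max 0.79 m/s, D 0.031 m, CSA 755 mm². The disc is centred on a pixel
so the profile apex is sampled exactly. The phantom does *not* emulate
aliasing, eddy currents, partial-volume effects at the wall, breathing
motion or segmentation error; passing tests therefore validate the
estimators' arithmetic and statistics, not robustness to real-world
imaging artefacts.

In the end-to-end pipeline, the heritable quantities are the latent
lumen radius and peak centreline velocity (each with the configured h²
plus covariate effects on sex, age, BMI and hypertension); the six
reported traits inherit heritability through the measurement chain, so
their recovered h² is close to, but not exactly, the latent target —
which is precisely how real traits behave relative to their generative
physiology.

## 3. Covariate adjustment

`stepwise_select()` is bidirectional stepwise linear regression: enter
the most significant candidate while its partial p < 0.05, then drop any
included covariate whose partial p has risen to ≥ 0.05, iterating to a
fixed point. Both thresholds are exposed; classical stepwise software
defaults to removal at 0.10, and since the original procedure's settings
are not recoverable, we default to the symmetric 0.05/0.05 (matching the
stated inclusion criterion) and let the caller choose otherwise. The
quadratic age term is computed from centred age by default to curb its
collinearity with the linear term; aliased candidates are dropped with a
warning.

`adjust_standardize()` standardises the model residuals to mean 0,
variance 1, and flags |z| > 3 as excluded. The order is fit →
standardise → exclude, with *no* refit after exclusion (refitting is
available behind `refit = TRUE` but changes the estimand slightly and is
off by default). On clean Gaussian data the 3-SD rule removes about
0.27% of subjects, which is why per-trait sample sizes shrink modestly
down the pipeline.

## 4. Genotype QC

Filters run in a fixed, logged order: SNP call rate → MAF → exact HWE →
sample call rate → heterozygosity window → Mendelian check; the order
matters (MAF is computed on the individuals still present, HWE on
founders) and is part of the contract. Thresholds default to the
familiar PLINK settings (call rates 0.95, MAF 0.05 final / 0.01 initial,
HWE 1e-8), run as two back-to-back stages mirroring a pre- and
post-imputation workflow (imputation itself is out of scope). Boundary
conventions follow PLINK: strict `<` removes, so a SNP exactly at the
MAF threshold and an individual exactly on the heterozygosity window
edge are retained.

The HWE test is the exact conditional test: given the allele counts, the
p-value sums the probabilities of all heterozygote counts no more
probable than the observed one, computed in log space from the
hypergeometric-type distribution. The mid-p variant exists but is off by
default, because the plain exact test is the one an enumeration oracle
reproduces exactly. HWE is tested in founders only by default — related
individuals violate the independence assumption and inflate rejection —
with a flag to use all samples.

The heterozygosity window is cohort-specific; when unset, mean ± 3 SD of
the observed distribution is used. Mendelian checking flags trio and duo
genotype configurations impossible under biallelic inheritance, blanks
them, and iterates until no new error appears — an approximation to a
full multigenerational check that converges because blanking only
removes information.

## 5. Pedigree heritability (maximum likelihood)

`kinship_matrix()` implements the standard recursion over a
topologically sorted pedigree; `2*Phi` is the additive relationship
matrix. `fit_polygenic()` maximises the likelihood of
`y ~ MVN(mu*1, 2*Phi*sigma2_g + I*sigma2_e)` per family block and
contrasts it with the environment-only null.

Numerically, the mean and the total variance are profiled out in closed
form (GLS mean, then the weighted residual mean square), reducing the
optimisation to one dimension in `h2` over [0, 1]: a 101-point grid
followed by local refinement to tolerance 1e-8. We chose this over a 2-D
quasi-Newton search in a transformed parameter space because the profile
is exact, the boundary `h2 = 0` is reachable without limits of
transformed parameters, and a dense grid cannot be trapped by a local
optimum. Each family's `2*Phi` block is eigendecomposed once, making
every likelihood evaluation O(n).

Because the null pins `sigma2_g` to the boundary of its parameter space,
the likelihood-ratio statistic is referred to the 50:50 mixture of a
point mass at zero and chi-squared(1) by default; the plain chi-squared(1)
p-value (conservative, exactly twice the mixture p) is always reported
alongside, since which convention legacy variance-components software
applied is ambiguous. Standard errors for `h2` come from the observed
information of the profile likelihood in `(sigma2_g, sigma2_e)` via the
delta method. A cohort of unrelateds makes the two components
non-identifiable (the covariance depends only on their sum); this is
detected from the spread of the relationship eigenvalues and flagged
rather than silently reported.

## 6. SNP heritability (AI-REML) and association

`compute_grm()` uses the GCTA estimator: standardised cross-products off
the diagonal and the `1 + ...` corrected diagonal, with allele
frequencies estimated from the sample and missing dosages handled by
pairwise-complete SNP counts rather than imputation (QC caps missingness
at 5%, so the difference is small). Monomorphic SNPs are a hard error:
they indicate the QC stage was bypassed.

`ai_reml()` fits `V = A*sigma2_g + I*sigma2_e` by restricted maximum
likelihood: an EM-REML first step, then average-information updates with
an EM fallback whenever an AI step would leave the parameter space or
reduce the restricted likelihood — so the likelihood trace is
non-decreasing by construction (and asserted in tests). Because EM
crawls when the optimum sits near the `h2 = 1` boundary, a final
profile-likelihood polish (1-D search over the variance ratio with the
total variance profiled) is applied and accepted only uphill. The AI
matrix at convergence provides the sampling covariance of the variance
components and, by the delta method, the standard error of `h2`. A ridge
of 1e-8 stabilises factorisation; the single spectral decomposition of
`A` serves every iteration. The p-value is again the boundary-mixture
LRT against `sigma2_g = 0`.

`mlma_scan()` estimates the variance components once under the null and
holds them fixed for every SNP (the standard mixed-model-association
economy), then computes each SNP's generalised-least-squares effect and
Wald chi-squared. Missing dosages are mean-imputed for the scan only;
zero-variance SNPs are skipped with a warning. The genomic-control
factor `lambda_GC = median(chisq)/0.4549` is attached to the result; on
null cohorts it sits in [0.95, 1.05]. Leave-one-chromosome-out variants
and multi-component GREML are out of scope.

## 7. File formats

Binary PLINK (bed/bim/fam) is read and written bit-exactly in the
SNP-major convention (magic bytes 0x6C 0x1B, mode 0x01, two-bit codes
packed little-endian, `ceiling(n/4)` bytes per SNP); GCTA GRM binaries
are the lower triangle in single precision plus pair counts and an id
list. Cines travel as one delimited matrix per frame with a JSON sidecar
holding grid shape, pixel spacing, frame interval and the declared
velocity unit. Coordinates are 1-based throughout. Metric tables carry a
units header row. All pipeline outputs are written atomically (write to
a temporary name, then rename) so a failed run leaves no partial files,
and every run directory includes a manifest with the seed and full
configuration.

## 8. Problem sizes in the test suite

The suite verifies the estimators at the sizes where their properties
are provable in reasonable time, chosen as a deliberate design point:
kinship against 100,000 gene-dropping replicates; ML and REML optima
against dense 200×200 grid searches on cohorts of up to 30 individuals;
parameter recovery on 200 pedigree-based and 100 SNP-based replicate
cohorts of 108 families at 2,000 SNPs; null test size on 500 replicates;
and association calibration at 20,000 SNPs. Heritability standard errors
at this cohort size are around 11 percentage points, which is why
single-cohort estimates scatter visibly around the simulated truth while
replicate averages recover it within a couple of points.

## 9. Known limitations

* The phantom's simplifications (Section 2) mean image-processing
  robustness is untested by construction.
* Covariates are independent of each other and of the genetic values;
  confounding between covariates and polygenic signal is not simulated.
* Gene dropping without LD understates the realised-relationship
  variance seen with real genomes; GRM-based estimates on real data
  carry additional variability the tests do not exhibit.
* The two-stage QC runs back-to-back without an intervening imputation
  step, so the initial MAF stage is exercised but has little to do on
  simulated panels.
* Heritability estimates are population-specific by nature; nothing in
  the package corrects for ascertainment beyond the hypertension
  covariate.
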