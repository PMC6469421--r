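---
title: "Multi-kernel GBLUP with hyperspectral relationship matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel GBLUP with hyperspectral relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem

Wheat breeding programs evaluate thousands of candidate lines for grain
yield (GY) under several managed treatments — irrigation and planting
regimes that emulate target environments — across successive breeding
cycles. Two facts make prediction hard: genotype-by-environment interaction
(G×E) reorders lines between treatments, and measuring yield everywhere is
expensive. Genomic selection predicts unphenotyped lines from genome-wide
markers or pedigrees; aerial high-throughput phenotyping measures canopy
reflectance at dozens of narrow wavelength bands for every plot in minutes.
specBLUP implements a multi-kernel GBLUP framework that combines the two:
markers or pedigree model the genetic main effect across environments, and
hyperspectral reflectance — collected in the very trial being predicted —
models the environment-specific deviations.

# Stage one: plot-level mixed models

Within each *site-year* (one treatment in one cycle), plots follow an
α-lattice: incomplete blocks nested in replicates nested in trials. The
plot-level model for any trait is

    y = mu + genotype + trial + rep(trial) + block(rep) + error,

with all design terms as independent scalar-variance random effects.
Genotype enters fixed for BLUEs (the training responses of stage two) and
random for BLUPs (the validation responses) via `fitTraitBlues()`. For
days to heading (DTHD) and maturity, recorded on one replicate only, the
replicate and block terms are dropped. A numeric lodging covariate is added
only when lodging was actually observed in the site-year, and a DTHD
covariate produces the phenology-corrected validation BLUPs. Broad-sense
heritability on an entry-mean basis is `heritability()`:
H² = σ²_g / (σ²_g + σ²_e / nreps), with nreps = 3 by default.

Per-band reflectance BLUEs use the same model for a single phenotyping
date, and add a random time-point effect (with trial/rep/block re-nested
within time-point) when a developmental stage or all dates are combined
(`fitBandBlues()`). Time-points are classified by `classifyTimePoints()`
from the realized phenology: a date is VEG while under half the plots have
headed, HEAD until all have headed, and GF (grain fill) until all have
matured.

**Numerical strategy for the band models.** All 62 bands share one field
design. Fitting the genotype-fixed model per band is needlessly expensive
(hundreds of dense fixed-effect columns), so the package estimates each
band's variance components by REML under the genotype-random form of the
same model — a fast refit across bands — and then solves the genotype-fixed
mixed-model equations sparsely at those variances. The two-step is exact
given the variances, reduces to per-line means when the design variances
vanish, and absorbs pure date offsets; both properties are covered by
tests. Plot-level REML fits are delegated to `lme4`; the restricted
likelihood at the returned variances is checked in tests never to fall
below its value at the generating truth.

# Stage two: kernels

Three families of relationship matrices serve as covariance kernels over
genotypes (or site-year × genotype records):

* **G** (`genomicRelationship()`): VanRaden's genomic relationship,
  G = ZZ′ / (2 Σ p(1−p)), with Z the marker dosages centered at twice the
  post-QC observed allele frequency. Marker QC (`qcMarkers()`) removes
  markers with more than 70% missing data, then markers with minor allele
  frequency below 0.05, and mean-imputes the rest — the standard GBS
  pipeline defaults.
* **A** (`pedigreeRelationship()`): the numerator relationship (twice the
  coefficient of parentage) by the tabular method on an explicit two-column
  pedigree. Founder diagonals are 1 + F; `inbredFounders = TRUE` sets F = 1
  for fully inbred lines, the realistic convention for inbred wheat, but
  the default leaves F = 0 since coefficient-of-parentage conventions vary.
* **H** (`spectralRelationship()`): H = SS′/nbands, where S holds the
  per-band BLUEs of one site-year, column-centered and scaled to unit
  sample standard deviation (n−1; configurable to n, which only rescales H
  globally). Constant bands are dropped with the divisor adjusted, so with
  all bands retained trace(H) = n−1 and H·1 = 0. H is built within a
  site-year: it is a phenotypic similarity in the environment being
  predicted, which is exactly why it can carry G×E signal.

`expandKernel()` lifts kernels to the record level: `main` is Z_g K Z_g′;
`gxe` is the Hadamard product (Z_g K Z_g′) ∘ (Z_E Z_E′), which zeroes all
cross-site-year covariances; `block_h` assembles per-site-year H blocks
into a block-diagonal record kernel.

# Stage three: multi-kernel GBLUP

`assembleModel()` builds the record-level model
y = μ + E_i + Σ_m u_m + ε from a model name: single-kernel genetic (G, A),
single-kernel spectral (H.VEG, H.HEAD, H.GF, H.ALL), genetic main plus
genetic G×E (G+G_GxE, A+A_GxE), or genetic main plus spectral G×E
(G+H.x_GxE, A+H.x_GxE). Site-year fixed effects use drop-first coding with
an intercept (predictions are invariant to this choice) and are omitted for
single-site-year fits.

`fitGblup()` offers two engines over the identical model:

* **Gibbs** (default): each kernel term is carried as the eigendecomposition
  of its record-level covariance (eigenvalues below 1e-10 truncated — the
  H blocks are rank-deficient since nbands ≪ n). Rotated into the
  eigenbasis, the effect coefficients have independent Gaussian full
  conditionals, so the sampler is exact blocked Gibbs. Variance components
  get scaled-inverse-chi-square full conditionals; the default prior gives
  every variance term, residual included, an equal share of the training
  phenotypic variance with 5 prior degrees of freedom — the common default
  convention of Bayesian GBLUP software. Missing responses (the records to
  predict) are imputed from their conditional each sweep; predictions are
  posterior means of the systematic part. Defaults are 10,000 iterations,
  2,000 burn-in, thinning 5, and an explicit seed; batteries use shorter,
  logged settings (below).
* **EM-REML**: expectation-maximization on the observed records in the same
  eigenbasis; predictions solve Henderson's mixed-model equations at the
  converged variances. Convergence is declared when the maximum relative
  variance change falls below 1e-6; components are floored just above zero
  (boundary estimates are reported, not errors). With all variances frozen
  via `varFixed` the fit is a single direct MME solve, which the tests
  compare to an independent dense Henderson solve at 1e-8.

The two engines agree: on single-kernel data their predictions correlate
above 0.99 (tested over 10 seeds at n = 200).

# Evaluation

`makePartitions()` implements the three train-test schemes: within
site-year (random 80% training), within cycle across managed treatments
(four treatments complete plus 20% of the focal treatment), and across
cycles within treatment (three cycles complete plus 20% of the focal
cycle). Training fractions use floor(p·n). Partitions are deterministic
given (scheme, focal unit, replicate, master seed) and are reused across
every model in a battery, so model comparisons share identical splits.
Check lines, which recur across cycles, stay in training and are never
drawn into a test set (configurable). Accuracy is the Pearson correlation
between predictions and the GY BLUPs of the test records, reported for
both validation variants: uncorrected and DTHD-corrected BLUPs. Models are
trained on uncorrected BLUEs in both variants (the correction applies to
the validation response); a corrected-training mode would be a one-line
change in `prepareBundle()` but is not the default. Undefined correlations
are recorded as missing and excluded from means with a count, never set to
zero; model/unit cells whose spectral stage is unavailable are reported
absent with the reason.

# The synthetic study generator

`simConfig()` / `makeScenario()` / `simulateDataset()` generate complete
studies with known truth. Defaults mirror a large multi-environment
program: 4 cycles × 5 treatments, 1,092 lines per cycle in full-sib
families of two, α-lattice trials of ~28 lines with 3 replicates and 6
blocks per replicate, 8,519 markers on inbred-derived lines. Yield
variances default to σ²_g = 0.2 (t/ha)², σ²_e = 0.15 (entry-mean H² = 0.8,
inside the 0.58–0.94 range typical of such trials), treatment means from
6.0 (optimal) down to 2.0 t/ha (severe drought), and moderately correlated
G×E (correlation 0.5, σ²_gE = 0.08). G×E deviations are *genetic*: drawn
with the marker-kinship covariance across lines (Kronecker with the
treatment correlation), which is the generative model the Hadamard
interaction kernel assumes. Phenology gives each line a genetic
days-to-heading deviation (sd 4 d) independent of the yield markers;
`gyDthdSlope` couples yield to earliness as under terminal stress.

Reflectance at each time-point is a date offset plus stage-dependent
loadings on the standardized breeding value, G×E deviation and heading
deviation, times smooth wavelength profiles (red-edge-centered for the
genetic signal, attenuated below ~500 nm where real sensors are noisy),
plus squared-exponential band-correlated noise (length-scale 8 bands).
Later stages load more heavily on yield signal, matching the observation
that grain-fill reflectance correlates most with yield. Phenotyping dates
are placed from the realized heading-date distribution so a configured
number of time-points falls in each stage.

Scenarios: `strong_gxe` raises σ²_gE to 0.25 with treatment correlation
0.45 and strong spectral G×E loadings, calibrated so the study sits in the
regime the framework targets — spectral-only accuracy comparable to
genomic-only, genetic G×E modeling helping, and spectral G×E modeling
helping most. `phenology_confounded` couples yield strongly to earliness
and loads the spectra on phenology, so DTHD-correcting the validation
BLUPs lowers reflectance-model accuracy while leaving marker/pedigree
models untouched. `missing_stage` drops all vegetative flights from one
cycle, reproducing the coverage bookkeeping a real unbalanced campaign
requires.

What the generator does **not** emulate: spatial field trend beyond the
block structure, radiative-transfer physics of canopy reflectance,
lodging (generated as zero; the covariate path is exercised by its
omission logic), epistasis or dominance, and marker-linked phenology.
Passing tests therefore demonstrate correctness of the machinery and
qualitative reproduction of the headline orderings, not quantitative
accuracy on any real dataset.

# Problem sizes and runtime choices

The test suite and acceptance script use reduced but structurally complete
studies chosen to keep a full run on one CPU within minutes: 2 cycles × 3
treatments × 300 lines with 1,000 markers and 4 flights per site-year for
the battery; 4 site-years × 300 genotypes for variance recovery; 39 trials
× 3 replicates × 6 blocks for the plot-level REML recovery. Batteries run
the Gibbs sampler at 1,000–1,500 iterations with 250–400 burn-in, which
the agreement tests show is ample for posterior-mean predictions at these
sizes.

# Known limitations

* The spectral kernel needs the test lines phenotyped by the camera in the
  focal site-year; it cannot predict lines absent from the flights.
* EM-REML converges slowly when a variance sits near zero; the Gibbs
  engine is the default for batteries.
* Stage classification uses the site-year's predominant stage, not
  per-plot phenology, mirroring common practice.
* The checks-in-training default assumes check plots are identified; with
  unflagged checks recurring across cycles, across-cycle accuracies can be
  optimistic.
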