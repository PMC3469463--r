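---
title: "Family history and SNP panels as risk predictors under the liability threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family history and SNP panels as risk predictors under the liability threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famliab)
```

## The model and its assumptions

`famliab` works entirely inside the additive liability threshold model. An
individual's liability to disease is a unit-variance, zero-mean normal
variable `l = g + e`: an additive genetic component with variance `h²` (the
heritability of liability) and an independent environmental component with
variance `1 − h²`. Disease occurs — at some point in the individual's
lifetime — exactly when `l ≥ T = Φ⁻¹(1 − f)`, where `f` is the lifetime
morbid risk. The model therefore excludes, by construction:

* non-additive genetic effects (dominance, epistasis) and
  gene–environment interaction;
* major loci of large effect, whose presence makes the genetic liability
  distribution non-normal;
* age-of-onset structure: `f` is a lifetime quantity, so a "pattern of
  disease occurrence" refers to whole lifetimes, which tends to make
  family-history accuracy estimates optimistic relative to a snapshot of a
  real pedigree;
* recall error — family histories are taken as complete and correct.

Within a family, genetic components are jointly normal with covariance
`h²A`, where `A` is the additive relationship matrix computed from the
pedigree by the standard tabular recursion (`relationship_matrix()`).
Optionally a single environmental component common to *all* family members
adds a constant `c²` to every covariance entry. This rank-one construction
deliberately overstates environmental sharing between distant relatives; it
is intended as an upper bound on what shared environment could contribute,
not as a realistic sharing model.

## Tunable parameters

| Parameter | Meaning | Units / range | Default |
|---|---|---|---|
| `f` | lifetime morbid risk | probability in (0,1) | — |
| `h2` | heritability of liability | fraction of liability variance | — |
| `c2` | shared-environment variance | fraction, `h2 + c2 ≤ 1` | 0 |
| `pi` | heritability explained by SNPs | fraction of `h2` | 0 |
| `K` | grid size, combined model | cells | 200 |
| `abseps` | MVN tolerance (large pedigrees) | absolute probability | 1e-6 |
| `max_n` | pattern-enumeration cap | individuals | 16 |
| `alpha` | significance threshold | p-value | 5e-8 |
| `r2_max` | LD independence threshold | r² | 0.005 |

The pattern-enumeration cap exists because family-history evaluation costs
one MVN integral per disease-status pattern, i.e. `2^n` integrals; 16
members is where a single evaluation stops being an interactive desk
computation. The genome-wide significance default `5e-8` is the canonical
threshold for European-ancestry GWAS; `r2_max = 0.005` keeps selected
associations approximately independent so their liability-scale variances
can be summed.

## Numerical choices

**MVN rectangle probabilities.** For pedigrees of up to 6 members the
package evaluates pattern probabilities with the deterministic Miwa lattice
rule (512 grid points, absolute accuracy around 1e-9). This accuracy is
what lets the calibration identities — pattern probabilities summing to 1,
every member's marginal risk equalling `f`, the control-weighted mean
likelihood ratio equalling 1 — hold to 1e-5 in the tests: with a
quasi-Monte-Carlo rule at tolerance 1e-6, the likelihood-ratio identity
(which divides by `f`) visibly inherits the integration error. Above 6
members the Miwa rule's cost grows too quickly and the Genz–Bretz
quasi-Monte-Carlo algorithm takes over, run under a fixed local RNG seed
(the caller's RNG state is saved and restored) so that repeated calls are
bit-identical; it is also the automatic fallback for singular covariance
matrices, which the lattice rule cannot factorize. The affected region is
the closed set `l ≥ T`; the boundary has measure zero, so this choice is
cosmetic but fixed.

**Degenerate patterns.** Relative patterns with probability below 1e-12
keep a defined conditional risk of `f` (with a warning), so classifier
bookkeeping stays total; items of probability zero cannot affect any
metric.

**Ties.** Classifier items whose risks agree within 1e-12 are merged before
ROC construction. Under the trapezoid rule a tie is a single line segment,
so merging changes no metric; it does make the trio's complete and
restricted models produce identical structures, which is the correct
analytic statement (exchangeable parents make the affected-parent count a
sufficient statistic there).

**Operating points.** The ROC vertices are the realizable deterministic
threshold rules; sensitivities between vertices are attained by
randomizing between the two adjacent rules. At metric time the package uses
deterministic linear interpolation — no RNG is consulted — which equals the
expectation of the randomized rule.

**Combined-model grid.** The distribution of the index's measured genetic
liability `g ~ N(0, v)` is discretized into `K` equal-probability cells.
Each cell is represented by its conditional mean,
`g_k = √v · K · (φ(z_{k−1}) − φ(z_k))`, with weight `1/K`. Mid-quantile
node placement (`g_k = √v · Φ⁻¹((k−½)/K)`) was evaluated and rejected: at
`K = 200` it leaves a mean-risk error of about 1.2e-4 and an AUC
discretization error of about 3e-3 on a single-individual pedigree, where
the closed form is available for comparison; conditional-mean nodes reduce
these to 4e-6 and 4e-4. Convergence in `K` is verified in the tests by
doubling the grid. With `pi = 0` the combined classifier short-circuits to
the complete family-history classifier, making the degenerate limit exact.

**Root-finding.** The equivalent-π inversion and the likelihood-ratio tail
solver use bracketed root-finding (monotone objectives); LR brackets start
at ±12 standard deviations of `g` and expand on failure, returning an empty
tail when a target ratio is unattainable.

**Winner's-curse correction.** The observed z-score of a reported
association is modeled as `N(μ, 1)` truncated to `|z| ≥ c`, with
`c = Φ⁻¹(1 − α/2)`; the corrected effect solves the truncated-mean identity
for `μ`. This is a conditional point estimate: it strictly shrinks
borderline effects toward zero and is odd-symmetric, and the tests verify
it reduces aggregate bias in a truncated-reporting simulation. Missing
standard errors are back-computed from the two-sided p-value.

**Per-SNP variance.** Genotype frequencies are Hardy–Weinberg; allelic
odds are multiplicative across genotype classes (odds `1, R, R²` relative
to the reference homozygote), and the baseline odds are solved so that the
genotype-risk mixture reproduces `f`. Each genotype class shifts the
liability threshold; the between-class variance `V` is mapped to the
unit-variance liability scale as `V/(1+V)` and per-SNP contributions are
summed across the (approximately independent) selected list before
dividing by `h²`. Whether to rescale jointly rather than per SNP is a
convention; the per-SNP convention used here is validated against a
genotype-level simulation oracle in the test suite.

## The simulator: what it does and does not emulate

`simulate_families()` forward-simulates the exact generative model above:
jointly normal genetic vectors via a symmetric eigenfactorization (with
eigenvalue clipping at −1e-10 for the rank-one shared-environment term), a
single shared environmental draw per family, i.i.d. residuals, and a
measured genetic component constructed to have variance `v` and covariance
`v` with the index's genetic value. One `set.seed()` call per invocation
with fully vectorized draws makes output bit-identical under a fixed seed;
per-replicate substreams were considered and dropped because no consumer
needs subset reproducibility.

Because the simulator *is* the model, agreement between analytic results
and simulation demonstrates internal correctness — that the integration,
classifier construction, and closed forms implement the stated
distributions — and nothing more. It cannot reveal how real family data
deviate from the model: no ascertainment bias, no age structure, no
misreported histories, no major-gene families, no population
stratification. Conclusions about real cohorts inherit all of the model
assumptions listed above.

The test suite validates every analytic surface against the simulator at
fixed seeds: pattern probabilities and family-history AUCs on a grid of
`f ∈ {0.05, 0.2} × h² ∈ {0.3, 0.8}` over a trio and a five-member nuclear
family at one million replicates per cell, SNP-model AUCs and
likelihood-ratio tail fractions at the corresponding closed forms, and
per-SNP variance at one million simulated genotypes. These problem sizes
keep each Monte-Carlo standard error small enough for 3-standard-error
equivalence bands to be meaningful while the whole suite stays in the
minutes range.

## Design choices on genuinely open points

* **Restricted-model conditioning.** The restricted classifier's class
  risks are computed from the full pedigree's pattern distribution
  (equivalence classes of complete patterns), not from a reduced
  first-degree-only pedigree. The two differ whenever more distant
  relatives correlate with first-degree counts; conditioning on the full
  distribution is what "summarizing the family history" means
  operationally.
* **First-degree identification** is derived from pedigree links (parents,
  full siblings, children of the index) rather than accepted as a user
  list, removing a class of input errors.
* **Sex-limited diseases** are handled by removing individuals of the
  non-applicable sex — the exact marginalization property of the
  multivariate normal — with unknown-sex individuals conservatively
  retained. If the index's own sex is non-applicable, the caller is
  instructed to flip all sexes (`flip_sexes()`), matching how a pedigree
  drawn for one sex is reused for the other.
* **Test pedigrees.** The package ships its own documented structures
  (`ped_trio()`, `ped_nuclear()`, `ped_three_generation()`). Published
  analyses of this kind often use particular extended families whose exact
  composition is not recoverable; results that depend on pedigree shape
  (family-history AUCs in particular) are therefore validated by
  properties and simulation, not by comparison to any specific published
  pedigree's numbers.
* **Inbreeding** is supported by the relationship-matrix recursion
  (diagonal entries above 1) but flagged with a warning, since the
  liability model's unit-variance convention assumes outbred families.

## Known limitations

Beyond the model-level exclusions above: the combined model conditions only
on the *index's* measured genotype (relatives' genotypes are out of scope,
though the conditioning code is written against an index-column vector so
the extension is localized); pattern enumeration is exponential in family
size, so very large pedigrees need the restricted model or trimming; and
the equivalent-π scale is only defined up to the SNP-model normal
approximation for case/control distributions of measured liability, which
is exact in the small-`v` limit and accurate to a few times 1e-4 in AUC at
the parameter ranges exercised here.
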