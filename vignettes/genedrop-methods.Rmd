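---
title: "Gene-drop neutrality testing for MHC haplotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-drop neutrality testing for MHC haplotypes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
drift null and how it is simulated, the trajectory statistics and their
empirical tests, the MHC diversity and association layers, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## 1. The question and the null model

In a closed, pedigreed population, MHC haplotype frequencies change from year
to year through two confounded processes: selection and drift. In a small
population drift alone produces conspicuous trajectories, so "frequency went
up" is not evidence of selection. The gene-drop builds the drift-only
reference distribution *conditional on the observed pedigree*: it holds
demography fixed — who bred with whom, how many offspring, who lived how
long — and re-randomises only Mendelian inheritance. Any systematic
difference between the observed trajectory and the drop distribution must
then come from the one ingredient not conditioned on: which haplotypes the
actual individuals carried, i.e. selection on (or linked to) the haplotypes
themselves.

A replicate proceeds in pedigree (topological) order:

1. **Founder cohorts** (default birth years 1989–1992) keep their observed
   diplotypes verbatim.
2. A founder-cohort individual *without* an observed diplotype receives each
   allele independently: a Mendelian draw (each of the parent's two assigned
   haplotypes with probability 1/2) when that parent is known, otherwise a
   draw from the observed haplotype frequencies of its own birth cohort.
3. **Simulated cohorts** (default 1993–2012) are assigned the same way for
   every individual — an observed diplotype of a post-founder individual is
   deliberately never copied, because those genotypes are the data being
   tested.
4. Individuals born *before* the founder window keep observed diplotypes if
   genotyped, otherwise both alleles are drawn from the earliest cohort with
   genotyped individuals. They matter only as parents of founder-cohort
   animals.

Standing-population frequencies for year $y$ count both haplotype copies of
every individual alive in $y$. The life interval is inclusive at both ends
(an animal dying in $y$ was part of year $y$'s population); an individual
with unknown death year is counted only in its birth year unless a
`FINAL_YEAR` (last seen) column extends it — we prefer under-counting to
fabricating presence, and the column makes the choice overridable.

Cohort frequencies used for unknown-parent draws are the *observed* ones,
computed once and held fixed across replicates; a cohort with no genotyped
individuals borrows the nearest cohort with data (earlier preferred on ties),
and the borrowing is reported on the result object. Mutation, recombination
within the haplotype block, and immigration are deliberately absent: on a
20-year horizon haplotypes are transmitted intact.

### Which individuals to count

`frequency_individuals = "genotyped_only"` (the default) computes simulated
frequencies over exactly the individuals that enter the observed
frequencies — those with an observed diplotype. Observed and null
trajectories then share population composition, so the test compares like
with like. The `"all"` option uses every individual alive in a year (all
carry simulated diplotypes). The difference is small when genotyping is
reasonably complete; the default removes it entirely.

### What the drop conserves (and what it does not)

Conditional on one realized pedigree, the expectation of a simulated
individual's haplotype dosage is a *pedigree-weighted* mixture of
founder-cohort genotypes — each founder weighted by its realized genetic
contribution — plus cohort-frequency atoms where parents are unknown. This
expectation is computable exactly by linear propagation
(`genedrop_expectation()`): an observed individual contributes its genotype;
a Mendelian allele contributes half the parent's expected dosage; an
unknown-parent allele contributes the cohort frequency vector. The Monte
Carlo engine is validated against this oracle (replicate means agree within
Monte-Carlo error).

The pedigree-weighted expectation is *not* the equal-weighted founder-cohort
frequency. Realized reproductive success varies enormously (many juveniles
die; a few males sire much of a cohort), so even the drop's *expected*
final-year frequency sits a drift-sized distance — roughly one per-replicate
standard deviation — from the founder-cohort frequency. "Drift preserves
expectation" is true over the joint randomness of demography and
inheritance, not conditional on one pedigree. This is why the neutrality test
compares the observed statistic with the simulated *distribution* (which has
the pedigree-weighting baked into both sides) rather than with the founder
frequency; the validation suite checks expectation conservation against the
exact oracle and checks the founder frequency only at the drift-envelope
(per-replicate SD) scale.

## 2. Trajectory statistics and empirical tests

Over the simulated years (default 1993–2012), each haplotype yields:

* **slope**: the ordinary least-squares slope of standing frequency on
  calendar year. Calendar years, not indices, so gaps are handled honestly;
  years with undefined frequencies (no counted individuals) are dropped
  pairwise, never interpolated. Unweighted, even though yearly sample sizes
  differ — the same statistic is applied to observed and null trajectories,
  so the test remains valid regardless.
* **cumulative change**: the sum of absolute consecutive-year frequency
  differences, starting at the first simulated year. It is bounded below by
  the absolute net change, with equality exactly for monotone trajectories.

Empirical tails use the raw counting estimator $p_{upper} = \#\{null \ge
obs\}/n$, $p_{lower} = \#\{null \le obs\}/n$, with ties counted in both tails
(so $p_{lower} + p_{upper} = 1 + ties/n$ exactly). The rule is conservative
and matches a "top or bottom 2.5%" tail definition with a closed boundary
($\le \alpha$ flags). A $(k+1)/(n+1)$ bias-corrected variant is available; it
never returns an exact zero. A raw tail of zero is stored as 0 but printed as
"< 1/n", since it only means "more extreme than every null value".

Classification applies four one-tailed rules at $\alpha = 0.025$ per tail:
upper-tail slope → positive directional selection; lower-tail slope →
negative directional; upper-tail cumulative change → fluctuating selection;
lower-tail cumulative change → balancing selection (a frequency held
unusually close to equilibrium). The four rules are reported jointly — labels
can co-occur (a strongly rising haplotype often accumulates unusual total
change as well) — and a haplotype flagged by none is "consistent with
drift". With eight haplotypes and four rules, occasional nominal flags under
neutrality are expected by construction; the type-I calibration below
quantifies this.

## 3. MHC diversity and association layers

**Divergence** is the amino-acid p-distance between an individual's two
haplotype sequences on the user-supplied concatenated alignment: the
proportion of compared positions that differ, excluding positions where
either sequence has a gap (pairwise deletion — the standard p-distance
convention). Comparison is case-insensitive and `X` is an ordinary,
mismatching residue. No alignment is performed internally; whichever loci the
user concatenates (all expressed class IIa loci, or antigen-binding sites
only) defines the measure. **Heterozygosity** is the indicator that the two
haplotype labels differ; **dosage** codes 0/1/2 copies per haplotype, each
row summing to 2.

For association, haplotype dosages enter a design matrix relative to a
reference haplotype (default H), giving $K-1 = 7$ haplotype degrees of
freedom. The **Wald test** $W = b^\top V^{-1} b \sim \chi^2_{df}$ uses the
posterior mean and posterior covariance of the haplotype coefficients from an
external mixed-model ("animal model") fit; the MCMC engine itself is out of
scope here, because the reusable computation is the post-processing. When $V$
is numerically singular, a Moore–Penrose pseudo-inverse is used with a
warning. **Haplotype-versus-rest contrasts** $c_i = b_i - \text{mean}_{j \ne
i}(b_j)$ are computed per posterior draw with the reference effect included
at zero; a haplotype is flagged when the equal-tailed 95% credible interval
of $c_i$ excludes zero. Contrasts are invariant to the choice of reference
(tested to $10^{-10}$) and are meant to be read only after a significant Wald
test, mirroring the sequential procedure. Interval exclusion was chosen as
the flagging rule because credible-interval overlap with zero is the
significance convention used throughout this literature.

The **fixed-effects fitters** (`fit_glm()`) cover the error families matched
to each fitness measure: probit for binary survival, log-link Poisson for
life span and breeding counts, zero-inflated Poisson for lifetime breeding
success of all individuals born (the excess zeros are the many animals that
never bred), and ordinal probit for female annual breeding success (0–3
offspring). They are maximum-likelihood fits with covariance from the inverse
observed information, fitted by IRLS (`stats::glm.fit`), `MASS::polr`, or —
for the zero-inflated Poisson — a BFGS optimisation of the likelihood with a
logit-scale inflation intercept shared across individuals. These fitters
deliberately omit random effects (pedigree, year, individual): they exist to
validate the post-processing machinery on synthetic data with known
coefficients, not to replace animal models on real data, where relatedness
confounding matters.

## 4. The synthetic-data generator

`simulate_population()` is a forward individual-based simulation emulating
the study design the analysis assumes:

| Parameter | Default | Why |
|---|---|---|
| cohorts | 24 (1989–2012) | multi-decade study with overlapping generations |
| founders | 220, ages 0–6 from the survivorship curve | stable-ish age structure at the start |
| haplotypes | 8, rarest at 3% | realistic allele-frequency spectrum with one rare haplotype |
| juvenile survival | 0.50 | severe first-winter mortality |
| adult survival | 0.80 / year, death certain at age 12 | short-lived ungulate |
| female litter | 0–3, mean ≈ 0.97 | females capped at three offspring per year |
| male skew | gamma(shape 0.4) siring weights | polygyny; male annual breeding success ranges to ~20+ |
| genotyping missingness | 0.28 | roughly the genotyped fraction of such studies |

Founders receive Hardy–Weinberg diplotypes at the configured frequencies
(the neutral default in the absence of information about founder
composition). Offspring inherit one haplotype from each parent. Selection
enters as per-copy multiplicative factors on juvenile survival probability
(clamped to [0, 1]) and/or on male siring weight — simple, documented
mechanisms sufficient for calibration and power experiments, not claims
about the real biology. Fitness records follow the six standard definitions
(total fitness = lifetime breeding success of all individuals born; juvenile
survival to age 1; adult annual survival; adult life span; adult annual and
lifetime breeding success), with final-year records censored to `NA` rather
than guessed. The generated amino-acid alignment gives each haplotype ~12%
divergence from a common base sequence, with the rare haplotype most
divergent (~30%).

What the generator does *not* emulate: density dependence and population
crashes, spatial structure, inbreeding depression, age- or condition-
dependent selection, genotyping error (missingness is random, not
quality-driven), and parentage error (the recorded pedigree is the true
one). Passing tests therefore demonstrate the *statistical machinery* —
calibration of the empirical tests given a correct pedigree, power under a
known selection mechanism, unbiasedness of the engine — not robustness to
the data pathologies of real field studies.

## 5. Numerical choices

* **RNG.** All replicates of a run are generated by one stream seeded from
  the configuration, with the drop vectorised across replicates (one pass
  down the pedigree assigns all replicates at once). Identical
  configuration ⇒ bit-identical results. Vectorisation was chosen over
  per-replicate child streams for speed in R (two orders of magnitude); the
  cost is that results are reproducible per (seed, n_sim) pair rather than
  per replicate index.
* **Tie-breaks.** Topological order breaks ties by (birth year, id), so
  processing order — and hence the RNG stream — is deterministic.
* **Degenerate inputs.** Years with no counted individuals propagate as
  `NA` (flagged, never silently zero) and are dropped pairwise by the
  statistics; slope needs ≥ 2 defined years, cumulative change ≥ 1 defined
  consecutive pair; `n_sim = 1` yields degenerate but well-defined tails in
  {0, 1}; an empty null distribution is an error.
* **Wald.** Sub-covariance inversion falls back to the pseudo-inverse with a
  warning; the statistic is invariant to label order and to joint rescaling
  $b \to cb, V \to c^2 V$.
* **Zero-inflated Poisson.** Started from the plain Poisson fit plus an
  excess-zero moment estimate for the inflation intercept; a fixed inflation
  of 0 reduces exactly to the Poisson fit. Possible probit separation is
  detected via runaway coefficients and reported.

## 6. Validation design and problem sizes

The validation experiments (run by the test suite and `scripts/acceptance.R`)
use these designs, chosen to make Monte-Carlo error small relative to the
effects tested while keeping each experiment in the seconds-to-minutes
range:

* **Mendelian exactness**: an 11-individual pedigree covering every
  assignment rule, 10&nbsp;000 replicates, every diplotype probability
  compared with exact recursive enumeration within 3 binomial SE.
* **Expectation conservation**: a default population (~2400 pedigree
  members), 2000 replicates, replicate-mean final-year frequencies against
  the exact propagation oracle (3 SE of the mean), and against
  founder-cohort frequencies at the drift-envelope scale (3 per-replicate
  SD) — see §1 for why the envelope is the right scale there.
* **Type-I error**: 200 neutral populations (~1400–1700 individuals, 20
  cohorts), gene-drop test at 500 replicates each; the per-tail slope
  rejection rate is required to sit inside the exact binomial 99% interval
  around 0.025. (With the raw tail estimator and 500 replicates the
  attainable rate under perfect calibration is 13/501 ≈ 0.026.)
* **Power**: juvenile viability selection s = 0.5 on a haplotype starting at
  5%, 100 replicate populations; the directional-positive flag is required
  in more than half (measured: ~0.8–0.9).
* **Fitter calibration**: per family, 100 fits at n = 2000; every
  coefficient within 3 SE of its generating value in ≥ 95% of fits; the
  zero-inflated Poisson is additionally cross-checked against an independent
  implementation (glmmTMB) on one dataset.

## 7. Known limitations

* The standing population is reconstructed from birth/death/last-seen years;
  a field census could differ (e.g. emigrants, missed animals). This is a
  declared approximation of the data model, not of the method.
* Observed cohort frequencies are treated as fixed sampling distributions
  for unknown-parent alleles; resampling them per replicate would add a
  small extra layer of uncertainty that this implementation (like the
  analysis it follows) omits.
* The empirical p-values inherit the granularity of `n_sim`; with 5000
  replicates the smallest nonzero raw tail is 0.0002.
* The association layer post-processes externally fitted posteriors; it does
  not itself control for relatedness or inbreeding, and its fixed-effects
  fitters must not be substituted for animal models on real data.
* Classification treats the four tail rules independently; no multiplicity
  correction across haplotypes or rules is applied, matching the
  per-haplotype 2.5%-tail convention rather than a family-wise error rate.
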