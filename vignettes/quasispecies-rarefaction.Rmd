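---
title: "Rarefaction of viral quasispecies: with or without replacement"
author: "qsrare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rarefaction of viral quasispecies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrare)
```

## The problem

Amplicon deep sequencing of a viral quasispecies yields, per sample and
amplicon, a table of haplotypes with integer read counts. Diversity
comparisons between samples are confounded by library size: several widely
used indices, above all the number of haplotypes, grow with sequencing
depth. Rarefaction — repeated random subsampling of every sample down to a
common library size — removes that confound, but it can be performed under
two schemes that behave very differently when rare haplotypes matter:

* **without replacement** (the classical definition): a subsample of
  $m$ reads is a uniform random $m$-subset of the $N$ reads, so the count
  vector is a multivariate hypergeometric draw;
* **with replacement**: $m$ independent draws with probabilities
  $c_i/N$, a multinomial draw — computationally convenient, but each
  replicated draw displaces an unseen rare haplotype.

`qsrare` implements both schemes on a common container
(`HaplotypeTable`), the closed-form theory that predicts their behaviour,
the diversity indices the comparison is about, and deterministic
generators for five benchmark quasispecies structures that span the
relevant compositional extremes.

## Model and closed forms

With $n$ items and $n$ independent draws with replacement (a bootstrap
cycle), a given item is seen with probability $1-(1-1/n)^n \to 1-1/e
\approx 0.6321$. Subsampling a fraction $f$ with replacement, the seen
probability is $1-(1-1/n)^{fn} \to 1-e^{-f}$, always below the exact
fraction $f$ that a without-replacement subsample retains
(`pSeenBootstrap()`, `pSeenFraction()`).

For a full count vector the two expectations of observed richness are

$$E_{\mathrm{wo}}[H_m] = \sum_i \left[1 -
\binom{N-c_i}{m}\Big/\binom{N}{m}\right], \qquad
E_{\mathrm{w}}[H_m] = \sum_i \left[1 - (1-c_i/N)^m\right],$$

implemented in `expectedRichnessWithout()` (the rarefaction equation,
evaluated with log-space binomial coefficients so $N=10^7$ is exact to
double precision) and `expectedRichnessWith()`. For a *flat* quasispecies
(all counts equal to $k$) these collapse to the printed special cases
$n - n\binom{nk-k}{m}/\binom{nk}{m}$ and $n[1-(1-1/n)^{nkf}]$; the ratio
of the two (`richnessRatio()`) measures the accuracy of with-replacement
subsampling and tends to 1 as $k$ grows. The per-haplotype seen
probability for the flat case is exposed separately as `flatPSeen()`:
the with-replacement richness expectation is $n$ times it. We return the
*count* from `expectedRichnessWith()` because only counts make the
ratio against the rarefaction expectation dimensionally meaningful
(it is then bounded by 1).

Diversity is summarized by Hill numbers
$^qD(p) = (\sum_i p_i^q)^{1/(1-q)}$ with the limits $^0D = H$,
$^1D = e^{\mathrm{Shannon}}$, $^2D = 1/(1-\mathrm{GiniSimpson})$,
$^\infty D = 1/\max_i p_i$ (`hillNumber()`, `diversityProfile()`), plus
the read-fraction statistics specific to quasispecies work: the singleton
read fraction, the rare haplotype load `fractionBetween(x, 0, 0.01)`, and
the replicated-singletons statistic `over1BelowTop()` (reads in
over-one-read haplotypes outside the top $K$).

## Benchmark structures

The five generators are deterministic and parameterized at the sizes used
throughout the package's tests:

| generator | default composition |
|---|---|
| `allSingletons(n)` | $n = 10^4$ reads, all singletons ($H=N$) |
| `singleDominant(N, f)` | $N = 10^5$; master at $f \in [0.1, 0.9]$, rest singletons |
| `prominentHaplotypes()` | counts 49231, 24615, 12308, 6154, 3077, 1538 + 3077 singletons ($N=10^5$, $H=3083$) |
| `noRareHaplotypes()` | $N=10^5$: master 90% + 10 minors at 1% (no singletons) |
| `flatQuasispecies(n, k)` | $n$ haplotypes at exactly $k$ reads |

`noRareHaplotypes()` needs a library size that the composition itself
does not pin down; we use $N=10^5$ for consistency with the other
$10^5$-read structures. Non-integral $N\cdot$frequency combinations are
resolved by largest-remainder apportionment so counts always sum to $N$
exactly.

These are idealized compositions: real quasispecies have continuous
abundance spectra, sequencing-error singletons, and haplotype identity
that depends on upstream read processing. Tests passing on these
structures demonstrate the samplers and estimators, not the upstream
pipeline; in particular nothing here addresses haplotype calling or
denoising, and sequences carried in from FASTA are never interpreted.

## Numerical and design choices

* **Sampler algorithm.** The without-replacement draw is generated as
  sequential conditional hypergeometric draws over haplotypes — memory
  $O(H)$, never materializing an $N$-read vector. Haplotypes with one
  read are exchangeable, so the singleton block is drawn as a uniform
  subset of singleton ids in a single C-level call; the tests verify
  both paths against exhaustive enumeration of all $\binom{N}{m}$
  subsets on small tables (chi-square over $10^5$ draws).
* **Subsample size.** $m = \mathrm{round}(N f)$ with R's round-half-even;
  this only matters on knife-edge fractions.
* **Summaries.** Median and IQR use R's interpolated type-7 quantiles and
  SD the $n-1$ denominator, matching the environment the reference
  simulations were run in.
* **Seeding.** `repeatedSubsample(seed = s)` derives one independent
  substream per cycle from the master seed, so results are reproducible
  and cycle-order-independent. `rarefyGroup()` reuses the same master
  seed for every sample, so identical tables always yield identical
  summaries. The resampling cycle count defaults to $B = 500$
  everywhere.
* **Frequency bands.** `fractionBetween()` uses $[\ell, u)$: a haplotype
  sitting exactly at a 1% threshold is *not* below it (so the rare
  haplotype load of the no-rare structure is 0). The sole exception is
  $u = 1$, inclusive, so the full band $(0,1]$ covers all reads.
  Ranking ties in `over1BelowTop()` break by count descending then id
  ascending, making outputs deterministic.
* **Expected columns.** Reported "exact" richness values are the
  $\sum_i$ hypergeometric expectations without ad-hoc rounding; on the
  single-dominant structures this includes the $\approx 1$ contribution
  of the master, e.g. $5001.0$ at $f=0.5$ for Q.90.10. For the
  all-singletons structure the with-replacement formula gives
  $951.67$ at $f=0.1$; reference tabulations that print $952.1$ there
  appear to carry a simulation mean rather than the formula value, and we
  make no attempt to force agreement.

## Sensitivity of indices to sample size

`sensitivityRank()` quantifies index sensitivity as the relative absolute
bias of the $B$-cycle median against the full-sample value, averaged over
subsampling fractions. On structures rich in rare haplotypes the ordering
is

richness > Shannon entropy > Gini–Simpson > master frequency,

mirroring the decreasing weight of rare haplotypes as the Hill order
grows. Two caveats that the metric itself imposes:

* The Gini–Simpson sensitivity is a plug-in bias of order $1/m$ while
  the master frequency's median is essentially unbiased; both medians
  carry Monte-Carlo noise of order $1/\sqrt{mB}$, so resolving that last
  gap requires $B \gg m$. The ordering test therefore runs the balanced
  single-dominant (Q.50.50) *structure* at library size 1000 with
  $B = 2000$ cycles, where the separation is decisive; at $N = 10^5$ and
  practical $B$ the two smallest sensitivities are indistinguishable
  from zero — which is itself the practical message: those indices do
  not need rarefaction.
* On an all-singletons table the full-sample master frequency is $1/N$,
  and any with-replacement resample inflates it several-fold, so under a
  *relative*-bias metric the master frequency ranks first there; the
  invariably large signal is the richness collapse (the $1-1/e$ loss).

## Problem sizes used by the test suite

The packaged tests reproduce the benchmark tables at their native sizes —
$N = 10^4$ (all-singletons), $N = 10^5$ (single-dominant grid over nine
master frequencies and four fractions, prominent, no-rare), $B = 500$
cycles — and verify the samplers against exhaustive enumeration on
$N \le 12$ tables. Stochastic medians are compared to closed-form
expectations within $4 \times 1.2533\,\sigma/\sqrt{B}$ (the asymptotic
standard error of a median) plus the discreteness step of the statistic's
grid; where a printed-precision band is wider, the band applies.

## Limitations

* Rarefaction here is size-based; coverage-based standardization and
  richness extrapolation beyond the observed $N$ (unseen-species
  estimators) are out of scope.
* Incidence-type indices that need sequence alignments (polymorphic
  sites, mutation frequencies) are not computed, since the model
  deliberately ignores sequence content.
* Variances and confidence intervals for rarefied richness are not
  provided; the repeated-resampling summaries (IQR, SD over cycles) are
  the intended uncertainty measure.
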