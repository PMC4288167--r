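---
title: "Modelling and inferring transcription factor occupancy with tfocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and inferring transcription factor occupancy with tfocc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfocc)
```

## The model

A site-specific transcription factor (TF) competes for a genome's worth of
potential binding positions. In the statistical-thermodynamics picture, every
length-m window j of the genome is a binding slot with statistical weight
proportional to its sequence affinity and chromatin accessibility, and the
probability that a particular slot is occupied in a nucleus carrying N bound
molecules is

$$
P_j \;=\; \frac{N\,a_j\,e^{w_j/\lambda}}
  {N\,a_j\,e^{w_j/\lambda} \;+\; L\,n\,\big\langle a_i\,e^{w_i/\lambda}\big\rangle_i},
$$

where

* $w_j$ is the PWM (position weight matrix) log-odds score of window j,
* $a_j \in [0,1]$ is the probability that the chromatin at j is open,
* $\lambda > 0$ rescales the binding energy: $\lambda > 1$ flattens the
  difference between strong and weak sites (a less specific factor),
  $\lambda < 1$ sharpens it,
* $N$ is the number of TF molecules bound to the DNA (an ensemble average
  over nuclei, so it is treated as a positive real),
* $L\,n$ counts the competing site slots across the $n$ genome copies of a
  nucleus (ploidy; default 2), and
* $\langle\cdot\rangle_i$ is the arithmetic mean weight over all slots —
  the per-slot partition function that every site competes against.

The model deliberately ignores steric hindrance between neighbouring sites,
TF–TF cooperativity and competition between different factors; its point is
that PWM affinity, accessibility, abundance and specificity already explain
the bulk of a genomic binding profile.

### Score and weight conventions

PWMs are built from count matrices with a pseudo-count (default 1) that is
split across the four bases in proportion to the background frequencies
before normalising, so all scores are finite. Scores and information content
are reported in bits (log2). Inside the model, however, the Boltzmann weight
of a site is the *likelihood ratio* raised to $1/\lambda$:

$$ e^{w_j/\lambda} \equiv \left(\frac{f_j}{b_j}\right)^{1/\lambda}
   = \exp\!\big(w_j^{\mathrm{bits}} \ln 2 / \lambda\big). $$

This form does not depend on the base the score matrix happens to be printed
in, and it makes $\lambda$ a dimensionless energy scaling in units of
$k_\mathrm{B}T$. Any other convention is absorbed by a rescaling of
$\lambda$, so the convention must simply be stated — this is it.

### The genomic average and masked sequence

Both strands are scanned; a plus and a minus site at the same start are
distinct slots. Windows containing non-ACGT characters are masked: they are
excluded from the site table but still counted in the slot total, because
unmapped sequence still occupies physical genome length. With this
convention the identity $\sum_j P_j \to N$ holds exactly in the
low-abundance limit (the test suite checks it on 10-kb toys and on the full
benchmark), which is the internal consistency the formula's denominator is
supposed to provide. The average is computed once per $(\lambda,
\text{accessibility})$ pair and cached; cached and fresh computations are
asserted identical in the tests.

### The reporting threshold

Only sites whose score clears a relative threshold are *reported* (and
turned into profile signal): ChIP is a population average, and individual
weak sites, occupied in few cells each, contribute no identifiable peaks.
Two threshold modes exist:

* `offset_from_min` (default): $w_j \ge \min_i w_i + f\,(\max_i w_i -
  \min_i w_i)$ with $f = 0.7$;
* `absolute_range`: $w_j \ge f\,(\max_i w_i - \min_i w_i)$, the range used
  as an absolute cut-off.

The second form is the literal transcription of the usual verbal rule
("higher than 70% of the difference between the strongest and weakest
site"), but for any realistic log-odds matrix the minimum score is strongly
negative and the literal threshold exceeds the maximum score, selecting
nothing — the package's own unit tests demonstrate this on a four-score toy.
`offset_from_min` is therefore the default; the literal mode is retained for
comparability. Crucially, the threshold only chooses which sites are
*reported*: the partition-function average in the denominator is always
taken over every scorable window, so the normalisation does not depend on
the reporting choice.

## From occupancy to a ChIP-like profile

A bound site is recovered on sheared DNA fragments, so its footprint in a
coverage profile is the site occupancy spread by the fragment-length
distribution. Fragment lengths are normal with mean 200 bp and sd 200 bp
(truncated at 1 bp and discretised); a fragment of length $\ell$ covering
the site is placed uniformly among the $\ell$ possible placements, giving a
triangular per-length kernel $\max(0, \ell - |d|)/\ell$. The closed-form
mixture kernel has total mass exactly $E[\ell]$, so profile mass equals
$\sum_j P_j \cdot E[\ell]$ away from region edges (asserted to $10^{-6}$
relative in the tests); a Monte-Carlo sampling mode cross-checks the closed
form. Profiles are then smoothed with a 250-bp centred moving average whose
window shrinks at the region ends (a constant profile is a fixed point and
no negative values can appear). Whether the original profile-generation
recipe smoothed with a moving average, a Gaussian or a spline is not
something we can settle; the moving average is the documented choice and the
smoothing width matters far more than its shape at these scales.

The simulated *observed* profile adds Gaussian noise truncated at zero, with
sd expressed as a fraction (default 0.1) of the noiseless profile's maximum.

## Inference of N and lambda

Two complementary metrics compare a model profile to an observation over the
analysed region:

* **Pearson correlation** $\rho$ — shape only; invariant to affine rescaling
  of either profile.
* **Mean squared error over 1-kb bins** — amplitude-aware by default.

The grid search evaluates both over $N \in \{1, 10, 100, 500, 1000, 2000,
5000, 10^4, 2\times10^4, 5\times10^4, 10^5, 10^6\}$ and $\lambda \in \{0.25,
0.5, \dots, 5\}$, recomputing the genomic average only once per $\lambda$.
The optimum is the minimum-MSE cell inside the intersection of the top-12%
correlation band and the bottom-12% MSE band (ties break towards smaller
$N$, then smaller $\lambda$; an empty intersection falls back to the global
MSE minimum and is flagged). The division of labour is the heart of the
method: correlation constrains $\lambda$ but is nearly flat in $N$, while
the MSE constrains $N$ — the acceptance tests verify on noiseless benchmarks
that at the true $\lambda$ the set of N values inside the correlation band
strictly contains the set inside the MSE band.

### Why the MSE is not normalised per profile by default

"Normalised MSE" admits several readings. Dividing each profile by its own
mean (or maximum) makes the MSE scale-invariant — convenient for raw ChIP
units, but it erases exactly the amplitude information that identifies $N$:
below saturation every occupancy is proportional to $N$, so a
self-normalised profile does not change with $N$ at all, and the MSE surface
flattens along the $N$ axis. The package therefore compares profiles on the
model's occupancy scale by default (`normalization = "none"`), which
presumes the observation has been brought to that scale; the `"mean"` and
`"max"` modes are provided, tested, and appropriate when only the shape is
trusted. For observations in arbitrary units the practical recipe is to fit
with `"mean"` first and treat the reported $N$ as an order of magnitude.

### Fitting under truncated noise

The synthetic observation model clips negative noise at zero. Clipping is
not mean-zero: it adds a positive floor wherever the clean signal is small,
compressing the observed peak-to-valley dynamic range. Comparing the *clean*
model profile against such data systematically biases $\lambda$ upward (a
flatter model imitates the filled-in valleys). `grid_search` therefore
passes predictions through the censored-observation mean

$$ E\big[\max(0, p + \varepsilon)\big]
   = p\,\Phi(p/\sigma) + \sigma\,\phi(p/\sigma), $$

with $\sigma$ estimated from bases of inaccessible chromatin at least 2 kb
from any accessible base — there the model predicts exactly zero, so the
observed mean is $\sigma\,\phi(0)$. When no such bases exist, or with
`noise_model = "none"`, $\sigma = 0$ and the correction is the identity, so
noiseless fitting is exact. The 2-kb margin keeps fragment-kernel leakage
(reach $\approx$ 1.4 kb) out of the noise estimate.

Metrics are computed over the analysed loci — by default the 1-kb bins
containing at least one accessible base — rather than genome-wide, mirroring
per-locus profile comparisons; `metric_domain = "all"` switches to the whole
region.

## The synthetic benchmark

`make_fixture()` draws, from a single seed: an i.i.d. random genome (200 kb,
GC 0.5), a block-structured binary accessibility track (geometric block
lengths, mean 1 kb, 15% accessible — emulating the block structure of
thresholded DNase accessibility calls), 50 planted motif instances (words
sampled from the PWM's own frequency model within a strength-quantile
window, default the top 70%, placed non-overlapping on random strands), and
a forward-simulated observed profile at $N^* = 5000$, $\lambda^* = 1.5$ with
noise at 10% of the profile peak. Every artefact is byte-reproducible from
the spec.

Two generator choices deserve their rationale:

* **The default motif** is a 10-bp, ~5.8-bit matrix (one dominant base at
  frequency ~0.68 per column). A moderate motif keeps the genomic partition
  function dominated by the many background windows rather than by the
  handful of planted sites. That is the regime the analytical model assumes
  on real genomes — megabases of near-neighbour sites form the competition
  term — and it is what makes the low-abundance limit
  $\sum_j P_j \approx N$ meaningful on a desk-scale 200-kb genome. A very
  sharp motif on so short a genome would concentrate the partition function
  on a few sites, a small-system artefact rather than a property of the
  model.
* **Site placement** is independent of accessibility by default (the
  partition function then reflects background sequence), with
  `sites_in_accessible = TRUE` for recovery benchmarks — a site planted in
  closed chromatin has $a_j = 0$ and is unrecoverable by construction, so
  forcing sites into open chromatin is a precondition of parameter
  recovery, not a convenience.

What the generator does *not* emulate: mappability artefacts, GC bias,
PCR duplicates, read-level sampling noise (the noise is additive Gaussian on
the smoothed profile, not Poisson on reads), copy-number variation,
cooperative or competitive binding, and the correlated structure of real
DNase signal. Passing the benchmark therefore shows that the estimator
inverts its own generative model under realistic signal-to-noise — not that
any particular biological dataset satisfies that model.

## Numerical choices and problem sizes

* Coordinates are 1-based and closed internally (the R/Bioconductor
  convention); BED input/output converts at the boundary.
* Coverage is accumulated site-by-site (profiles are linear in the site
  occupancies), smoothing uses a cumulative-sum moving average, and binning
  uses grouped means; a full 240-cell grid search on the 200-kb benchmark
  takes on the order of ten seconds.
* The test suite runs its recovery study at the benchmark scale (20 fixtures
  of 200 kb) and its oracle equivalences on 3–10-kb toys; these sizes were
  chosen so the whole suite completes in a few minutes while keeping the
  low-N sum and recovery checks statistically meaningful.
* Degenerate inputs fail loudly: an all-inaccessible genome (undefined
  model), a zero-variance observed profile, an empty filtered site set, a
  zero-count column with zero pseudo-count, and tracks that disagree with
  the sequence length are all errors, not warnings.
* Zero-variance profiles inside a grid cell yield `NA` metrics for that cell
  only; band selection ignores `NA` cells.

## Worked example

```{r example, eval = FALSE}
library(tfocc)

# a reproducible benchmark with known truth
fx <- make_fixture(synthetic_spec(seed = 1, sites_in_accessible = TRUE))
fx

# fit N and lambda from the noisy observed profile
fit <- fit_occupancy(fx$observed, model = fx$model)
coef(fit)
summary(fit)

# predict the profile a nucleus with one tenth the abundance would show
low <- predict(fit, N = coef(fit)[["N"]] / 10)

# region-level quality of fit, 20-kb tiles
regions <- genome_wide_regions(fx$observed, fitted(fit), fx$accessibility)
ks_two_sample(regions$rho[regions$passes_background],
              regions$rho[!regions$passes_background])
```

## Limitations

* $N$ is identifiable only through saturation and amplitude; for data in
  arbitrary units fitted with self-normalising metrics, treat it as an
  order-of-magnitude estimate.
* $\lambda$ estimates depend on the stated weight convention; comparing
  $\lambda$ across tools requires converting conventions first.
* The read-density-to-accessibility map is a documented logistic stand-in
  (monotone in log-density, 0.5 at the chosen midpoint); its two parameters
  are exposed rather than hidden.
* The model predicts zero signal in closed chromatin; observed peaks inside
  inaccessible regions are, from the model's point of view, evidence against
  the accessibility track or the profile, and will depress the fit quality
  metrics rather than be explained.
```
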