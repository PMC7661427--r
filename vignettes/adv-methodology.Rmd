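---
title: "Reference subsamples and admissible dissimilarity values for length-frequency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference subsamples and admissible dissimilarity values for length-frequency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(advlfd)
```

## The problem

Length-frequency distributions (LFDs) — counts of fish per 1-cm length
class, raised from measured subsamples to whole catches — are a key input to
stock assessment. Sampling programmes routinely ask whether a *smaller*
sample would have carried the same information: could fewer trips, hauls or
measured fish have been recorded without distorting the shape of the LFD?

`advlfd` answers that question with a distribution-free, shape-based
criterion. Rather than testing means or running goodness-of-fit tests (which
react to differences that may be biologically irrelevant, and miss ones that
matter), it asks whether a reduced sample preserves the *modal structure* of
the original: the same number of robust modes (cohort peaks) and antimodes
(gaps between cohorts), in nearly the same places, with comparably
pronounced amplitudes.

## Robust critical points

On a 1-cm grid a class is a **mode** when its neighbours have lower counts
and an **antimode** when they have higher counts; for runs of equal counts
the first (smallest) class represents the run. Two boundary decisions are
deliberate:

* the grid is padded with zeros for mode detection, so a boundary class can
  carry a mode (the largest length class often does);
* antimodes are interior-only — with zero padding every boundary would be a
  spurious minimum.

Raw 1-cm extrema are noisy. A mode is **robust** under a smoothing
bandwidth $\Delta$ (rebinning into $[k\Delta, (k+1)\Delta)$ bins anchored at
the bin origin, fixed at 0) when its class falls inside a bin that is itself
a mode of the smoothed histogram, and it is the dominating (highest-count)
1-cm mode inside that bin; ties go to the smallest class. Antimodes are
treated symmetrically with minimal counts. Modes whose count is at or below
1% of the largest 1-cm mode count are discarded as noise; no such filter is
applied to antimodes. If a smoothed mode bin contains no 1-cm mode (possible
with plateaus) it contributes nothing — no synthetic points are invented.
Robust modes and antimodes need not alternate after filtering; the merged
sequence is stored as computed.

`local_extrema()` and `robust_critical_points()` implement this;
`delta = 5` cm is the default, appropriate for species reaching over a
metre. All critical-point work is confined to the **important length
classes** $l^I$ (an inclusive class interval, `important_range()`): tails
that carry little information for the application at hand can be excluded.

## The penalized dissimilarity

Let $F$ and $G$ be the empirical CDFs of the original sample and a
subsample over $l^I$ (cumulative class counts divided by the total inside
the range). The base distance is the Minkowski distance of order $p$,

$$L_p(F,G) = \Big(\sum_{j \in I} |F(l_j) - G(l_j)|^p\Big)^{1/p},$$

with $p = 1$ (the Manhattan / 1-Wasserstein distance, the area between the
step CDFs) used throughout. Both CDFs are evaluated on the union of the two
class grids inside $l^I$, cumulative values carried forward over classes
where a sample has no mass.

Similarity is then three conditions on the robust critical points of the
two samples:

1. equal numbers of robust modes, and of robust antimodes;
2. pairing modes with modes and antimodes with antimodes in ascending
   order, every location shift is at most $\varepsilon$ cm;
3. for consecutive pairs $(v_{i-1}, v_i)$ of the merged critical sequence,
   the amplitude difference in the subsample is at least $\theta$ times the
   original one.

The penalized distance adds one term per violated condition:

$$D = L_1(F,G) + c_1\,\mathbb 1\{\text{counts differ}\}
 + c_2 \sum_i \max(0, |v_i - V_i| - \varepsilon)
 + c_3 \sum_{i\ge 2} \max\Big(0,\ \theta - \tfrac{|g(v_i)-g(v_{i-1})|}{|f(V_i)-f(V_{i-1})|}\Big),$$

where the shift and amplitude sums apply only when the counts match. The
defaults $c_1 = 10$, $c_2 = 2$, $c_3 = 1$ impose a hierarchy: losing or
gaining a cohort peak is penalized hardest, a shifted peak less, a flattened
amplitude least. $D = 0$ exactly when the subsample equals the original on
$l^I$, and $D = L_1$ exactly when all three conditions hold.

**Amplitude conventions.** Two readings of "amplitude" are defensible and
both are implemented. The default, `amplitude_mode = "pointwise"`, takes
amplitudes as the raised counts at the robust critical classes, so the
ratio compares count differences between consecutive peaks and gaps. The
alternative, `"cdf_mass"`, takes the amplitude of the $i$-th consecutive
pair as the class mass between $v_{i-1}$ and $v_i$ (the backward CDF
increment scaled by the total), so the ratio compares interval masses. The
pointwise reading matches how stopping behaviour is naturally described
(amplitude ratio between a mode and the neighbouring antimode) and is the
package default; the mass reading is available for sensitivity analysis.
Consecutive pairs whose *original* amplitude difference is zero have an
undefined ratio; they are skipped with a warning rather than treated as an
infinite ratio.

## The reference subsample and the ADV

The admissibility threshold comes from a deterministic thinning algorithm
(`reference_subsample()`):

1. compute the robust critical points of the original once; they stay fixed;
2. each iteration removes one measurement from *every* class in $l^I$ whose
   count still exceeds its floor (classes outside $l^I$ are never touched);
3. recompute the candidate's robust critical points and test conditions
   (1)–(3) against the original; accept and repeat while they hold;
4. on the first violation, the previous subsample is the **reference
   subsample**; if nothing can be thinned, the algorithm stops at the floor.

The stopping reason reported is the first violated condition
(`mode_count_changed`, `shift_exceeded`, `amplitude_ratio`) or
`all_classes_at_floor`. When a violation is ultimately caused by a frozen
class (a floor stops one class while its neighbours keep shrinking until an
antimode relocates), the reported reason is still the violated condition —
the trace records sizes and per-condition status per iteration.

The **ADV** (admissible dissimilarity value) is $D$ between the original
and the reference subsample; all penalties vanish by construction, so it
equals the plain $L_1$ distance. Any candidate subsample with
$D \le \mathrm{ADV}$ is *admissible* — no further from the original than
the minimal still-representative subsample.

Because every iteration decrements all thinnable classes simultaneously,
the candidate after $i$ accepted iterations is simply
$\max(n_j - i, \gamma_j)$ per class. Two consequences are exploited
throughout:

* with no floors binding, the subsample size after $i$ iterations is
  exactly $n - i \cdot |I|$;
* the candidate path does not depend on $(\theta, \varepsilon)$ — those
  parameters only select the stopping step. Grid studies therefore share
  one path per replicate across all $(\theta, \varepsilon)$ cells, which
  also makes the monotone trends exact per replicate: reference size is
  non-decreasing and ADV non-increasing in $\theta$; ADV is non-decreasing
  in $\varepsilon$.

**The floor $\gamma$** (`gamma_spec()`) encodes managerial minimums per
class: a fixed count (`absolute`), a fraction of the class count
(`fraction`, smallest integer at or above the share), the adaptive rule
"20% of the class, sparse classes with fewer than 5 fish frozen"
(`adaptive`), or nothing (`zero`). Fraction floors use the smallest integer
not below the share, so a class always retains *more than* the stated
proportion of its measurements. No ordering between $\gamma$ and $\theta$
is imposed — one is a count, the other a ratio, and they act on different
parts of the algorithm.

## Worked toy example

```{r}
x <- lfd(c(`1` = 5, `2` = 1, `3` = 5, `4` = 1, `5` = 5))
p <- adv_params(delta = 1, theta = 1, epsilon = 0)
rr <- reference_subsample(x, p)
rr
rr$trace
```

One iteration is accepted (counts `[4,0,4,0,4]`, every amplitude difference
still 4/4 of the original); the second iteration would leave `[3,0,3,0,3]`
with amplitude ratios 3/4 < 1, so it is rejected and the algorithm stops
with reason `amplitude_ratio`. The ADV is the area between the CDFs,
$2/17 \approx 0.1176$.

## Hierarchical scenarios

Observer data are clustered: fish within hauls within trips, with raised
counts per class (`raising_factor` = whole catch weight over measured
weight). `apply_scenario()` evaluates effort reductions by dropping whole
trips, hauls below a catch-weight threshold, hauls in a daily time window
(wrap-around intervals like 21:00–03:00 supported), and/or a random
fraction of measured individuals per haul (without replacement, replicated;
the median $D$ is reported, as medians resist the occasional extreme
replicate). Raised counts are rounded to integers once, after aggregation
over all records per class — the iterative algorithm removes whole
measurements, so integer counts are required, and per-record rounding would
accumulate error.

Mean length is summarized with a nested random-effects model
(`mean_length_varcomp()`): length = $\mu$ + trip + haul + residual, with
independent components. The estimator is method-of-moments nested ANOVA for
the unbalanced two-fold design (Searle's coefficients); it is closed-form,
reproducible, and coincides with REML on balanced designs with interior
estimates — the test suite cross-checks it against `lme4` on such a design.
Negative moment estimates are truncated to zero with a warning. The
standard error of the grand mean combines the components with the squared
design counts. Unraised lengths are used: the model describes measurement
clustering, not raised populations.

## Synthetic data

Two generators make every stage testable without any data download:

* `simulate_mixture()` draws from a normal mixture — by default the
  three-cohort configuration $\tfrac14 N(40, sd) + \tfrac12 N(70, sd) +
  \tfrac14 N(100, sd)$ with $n = 2000$ — rounds to the nearest cm and
  redraws values below 1 cm. Rounding *is* the 1-cm binning of the field's
  data format; redrawing (rather than truncating or clamping) keeps the
  mixture weights intact.
* `synthetic_hierarchical_data()` emulates observer records: three trips of
  eight hauls of 27 fish by default (about 650 measurements, a realistic
  quarter of sampling for one metier), lengths = mixture draw + trip effect
  + haul effect (defaults 2 and 3 cm standard deviations, mild intra-haul
  correlation), haul times uniform over the day, catch weights uniform on
  0.5–6 tonnes so that catch-weight thresholds at 1.5 and 3 tonnes split
  the hauls, and raising factors implied by a cubic length-weight relation.

What the generators do *not* emulate: gear selectivity curves, spatial
structure, correlated trip/haul effects, measurement error beyond rounding,
and species-specific length-weight allometry. Passing tests on synthetic
data therefore demonstrate the algorithmic properties (determinism,
stopping behaviour, monotone trends, recovery of known variance
components), not field realism.

## The simulation studies

`grid_study()` maps mean reference size and mean ADV over
$\theta \in \{0.30, 0.35, \ldots, 0.95\}$, $\varepsilon \in \{0,1,2,3\}$
and mixture spreads $sd \in \{5, 7, 10\}$ with $\gamma = 5$, $\Delta = 5$
and all classes important. With well-separated cohorts ($sd = 5$) the
$\varepsilon$ curves nearly coincide — location shifts are not what stops
the thinning — while at $sd = 7$ they separate clearly.

`bootstrap_comparison()` contrasts the deterministic reference with naive
random subsampling: per replicate and cell, bootstrap subsamples of the
cell's mean reference size are drawn from the original draw (without
replacement by default — these are subsamples of a finite sample; a
with-replacement switch exists), their penalized $D$ to the original is
averaged, and the fraction of replicates whose reference CDF sits entirely
inside the pointwise 95% bootstrap CDF band is recorded. Random subsamples
of the reference size are *not* reliably admissible — their mean $D$ far
exceeds the ADV — and the band coverage collapses as $\theta$ grows past
about 0.8, because stricter amplitude preservation forces larger reference
sizes whose tight without-replacement bands no longer contain the
deterministically thinned CDF.

`contrast_datasets()` reproduces the two-dataset demonstration: a
two-cohort sample ($\tfrac12 N(50,5) + \tfrac12 N(60,5)$, $n = 1000$) is
scored against the three-cohort original; $D$ exceeds the ADV at every
$(\theta, \varepsilon)$ cell, while a second draw of the same configuration
scores far lower.

Replicate counts are configurable and default to 100; the package's test
suite and acceptance script run the grid and bootstrap studies at 100
replicates and 100 bootstrap draws per cell, sizes chosen so the complete
suite runs in minutes on a single core while keeping Monte Carlo error on
grand means within a few percent.

## Numerical notes and degenerate inputs

* Counts are integers throughout; raised counts are rounded half away from
  zero (the market-sampling convention), once per class after aggregation.
* An empty length vector gives an empty LFD (total 0); CDFs and critical
  points require positive mass inside $l^I$ and fail loudly otherwise.
* Equal-count runs: first class wins, for modes and antimodes alike.
* A subsample whose support extends beyond the original's inside $l^I$ is
  aligned on the union grid; missing classes carry their cumulative value
  forward.
* The reference algorithm is fully deterministic: identical inputs give
  bit-identical results, including the iteration trace.

## Limitations

* The approach presumes a modal LFD. Near-uniform or platykurtic samples
  (large $sd$) still yield a reference subsample, but weak modes make the
  result fragile — for such stocks a method not relying on modal structure
  is preferable.
* Scalar $\theta$ and $\varepsilon$ apply one tolerance to all critical
  points; per-point vectors are a natural extension not implemented here.
* Amplitude *rank* changes (a secondary peak overtaking the primary) are
  not penalized.
* The records dialect is a minimal CSV; no direct database connectivity.
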