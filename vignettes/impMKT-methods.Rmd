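---
title: "Models and methods behind impMKT"
author: "impMKT authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind impMKT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impMKT)
```

## The problem

The McDonald-Kreitman framework contrasts protein-coding variation within
a species against divergence from an outgroup. Under neutrality the
nonsynonymous/synonymous ratio should be the same among polymorphic sites
(P~N~/P~S~) and fixed differences (D~N~/D~S~); an excess of the divergence
ratio signals recurrent positive selection, quantified as the fraction of
adaptive nonsynonymous substitutions

$$\alpha = 1 - \frac{P_N}{P_S}\cdot\frac{D_S}{D_N}.$$

Slightly deleterious mutations (SDM) break the neutrality assumption for
polymorphism: they segregate at low frequency, inflate P~N~ without
contributing to D~N~, and bias $\alpha$ downward. Classical fixes remove
*all* variants below a derived-allele-frequency cutoff (the FWW
correction), which discards so much data - the frequency spectrum decays
roughly as $1/i$ - that single-gene tests often become impossible.

The imputed test takes a lighter touch. Let a cutoff $c$ split the
spectrum into a low band ($i/n < c$) and a high band ($i/n \ge c$).
Assuming SDM do not reach the high band, the high-band ratio
$P_N(\ge c)/P_S(\ge c)$ estimates the effectively neutral
nonsynonymous/synonymous ratio, and the low-band nonsynonymous excess
over it is the imputed SDM count

$$P_{wd} = P_N(<c) - P_N(\ge c)\,\frac{P_S(<c)}{P_S(\ge c)},$$

clamped to $[0, P_N(<c)]$. Only $P_{wd}$ is removed from the
nonsynonymous polymorphism cell; the synonymous cell is untouched. The
corrected estimate is
$\alpha = 1 - \big((P_N - P_{wd})/P_S\big)\,(D_S/D_N)$. Note that the
corrected *point estimate* equals the FWW one algebraically (both reduce
to the high-band ratio when the imputation is not clamped); what changes
is the amount of data left in the 2x2 table, and with it the power of the
Fisher exact test. On the packaged worked example (P~N~ = 11, P~S~ = 17,
D~N~ = 15, D~S~ = 8, bands 7/4 and 6/11 at a 15% cutoff), the standard,
FWW and imputed tests give P = 0.093, 0.045 and 0.017 while the imputed
test discards 5 sites instead of 13.

## Conventions and numerical choices

* **Frequencies.** Class $i$ of an unfolded spectrum at sample size $n$
  has derived-allele frequency $i/n$; "below the cutoff" is the strict
  inequality $i/n < c$, so a class sitting exactly at the cutoff stays in
  the high band. At $n = 20$ and $c = 0.15$, classes 1-2 are below and
  class 3 is above - the convention that reproduces the worked example's
  band counts. For folded spectra the same rule applies to minor-allele
  frequency, which removes both rare-derived and rare-ancestral classes,
  as appropriate when polarization is unavailable or unreliable.
* **Rounding.** Imputed quantities enter the Fisher table rounded half
  away from zero (4.818 rounds to 5, giving the 11 - 5 = 6 cell);
  $\alpha$, $d_w$ and the excluded fractions always use the unrounded
  values, keeping the estimators continuous in the data.
* **Analyzability.** A gene is not analyzable when P~S~, D~N~ or D~S~ is
  zero, or - for cutoff-based methods - when the high band holds no
  synonymous variation (the neutral reference ratio is then undefined).
  Such genes are reported as `non-analyzable`, never silently dropped.
* **Sidedness.** Two-sided Fisher exact P-values by default (the sum of
  all hypergeometric outcomes no more probable than the observed table);
  a one-sided option exists but is not the default.
* **Data-loss bookkeeping.** `excludedFraction` always uses total
  polymorphism P~N~ + P~S~ as the denominator: 13/28 = 46% for FWW and
  5/28 = 18% for the imputed test on the worked example. (A "15%" loss
  sometimes quoted for this example is not reconstructible from any
  denominator we can justify; we report 5/28.) Similarly, the often-cited
  "44% of variants excluded at a 15% cutoff for n = 10" is not derivable
  from the $1/i$ expectation under these conventions (which gives ~39%),
  so no such constant is hard-coded anywhere.
* **eMKT ambiguity.** The published neutral decomposition multiplies the
  *total* P~N~ by the synonymous below-cutoff fraction; that reading is
  the default (it reproduces the worked 7.88 -> 8 cell). The alternative,
  applying the fraction to the below-cutoff count only, is available via
  `pnBelowOnly = TRUE`.
* **Equation orientation.** The corrected $\alpha$ uses the divergence
  ratio $D_S/D_N$, the only orientation consistent with the classical
  definition and with the sign of the worked example; typeset versions of
  the imputed formula are ambiguous on this point.

## The high-frequency variant

Weakly beneficial alleles (and mispolarized sites) can pile up at *high*
frequencies, where they inflate P~N~ without (yet) contributing to D~N~.
`impMKTHigh()` estimates the neutral ratio from a mid band
$l \le i/n < h$, imputes and removes the low-band SDM excess as usual,
and moves the high-band nonsynonymous excess
$X = \max(0, P_N(\ge h) - r\,P_S(\ge h))$ into the nonsynonymous
divergence cell instead of discarding it, treating those copies as
fixations in waiting. When nothing segregates above $h$ the method
reduces exactly to the mid-band imputation.

## Asymptotic extrapolation

`alphaFunction()` computes $\alpha(x_i)$ per frequency bin (or
cumulatively) from pooled spectra, and `fitAsymptotic()` fits
$\alpha(x) = a + b\,e^{-cx}$ by bounded Levenberg-Marquardt least squares,
reporting $\alpha(1) = a + b e^{-c}$. Numerical choices: $c$ constrained
to $(0, 100]$ with three starting decay rates (1, 5, 25), because the
exponential is ill-conditioned when $\alpha(x)$ is nearly linear; a
linear fallback $a + bx$ is used (and flagged) when the exponential fails
on every start; at least three usable bins are required. The default trim
interval $[0.1, 0.9]$ drops the lowest bins (SDM-dominated) and the
highest (polarization-error-prone); the exact trimming used in published
analyses of this family is not printed anywhere we can cite, so the
interval is declared here as a default and is fully configurable. The
confidence interval is a percentile bootstrap over resampled bins (500
replicates, seeded); bin resampling treats bins as exchangeable, which
understates the dependence between cumulative bins - use per-bin mode
(the default) when the CI matters.

## Gene pooling

`poolRecords()` sums spectra, divergence and site counts across genes;
`bootstrapPools()` resamples genes with replacement (default grid 1, 2,
5, 10, 25, 50, 75, 100, 250, 500, 750, 1000 pools; 1,000 replicates) and
reports the mean, the empirical 2.5/97.5 percentiles (linear
interpolation) and the fraction of analyzable replicates per pool size.
Each (pool size, replicate) pair draws from its own deterministic
sub-stream of the master seed, so results are bit-reproducible and
parallelizable. Pooling buys power but can mislead: heterogeneous genes
can combine into a table whose association reverses every per-gene signal
(Simpson's paradox) - the test suite constructs a two-gene instance where
both genes show $\alpha > 0$ and the pool shows $\alpha < 0$.

## The synthetic-data generator

`simulateDataset()` replaces a forward population simulation with a
Poisson Random Field sampler: sites are independent, and the expected
sampled spectrum under scaled selection $\gamma = 2N_e s$ is

$$E[\xi_i] \propto \int_0^1
  \frac{1 - e^{-\gamma(1-q)}}{q(1-q)\,(1 - e^{-\gamma})}\,
  \binom{n}{i} q^i (1-q)^{n-i}\, dq,$$

which reduces to the classical $1/i$ at $\gamma = 0$ (the implementation
returns the analytic limit there and uses piecewise adaptive quadrature
with an overflow-safe kernel elsewhere). The defaults mirror the baseline
benchmarking scenario: $\theta = 0.001$ per site, genes of five 300-bp
exons with a 0.75/0.25 nonsynonymous/synonymous split
($m_N = 1125$, $m_S = 375$), samples of $n = 20$ haploid sequences,
deleterious effects drawn from a Gamma DFE with shape $\beta = 0.3$ and
mean $2N_e s = -2000$ (discretized into 64 quantile points), a beneficial
point mass at $2N_e s = +250$ with mutational weight
$p_a = 2.1\times10^{-4}$, and a target adaptive fraction
$\alpha = 0.4$. Divergence accrues at `divergenceTimeScale` = 4 expected
neutral substitutions per $\theta$-unit - chosen so D~S~ per gene is the
same order as P~S~, keeping the 2x2 tables balanced - with the
non-adaptive nonsynonymous rate scaled by the DFE's mean relative
fixation rate $E[\gamma/(1-e^{-\gamma})]$ and the beneficial component
drawn so its expected share of nonsynonymous fixations is the target
$\alpha$. The class of every fixation is recorded, so
`realizedAlpha(truth)` is exact by construction rather than assumed.

Two config fields are recorded but deliberately inert, and users should
not expect them to change the data: `rho` (sites are unlinked by
construction, so recombination has nothing to act on) and
`alphaWeakFraction` (mapping a weak-adaptive share of $\alpha$ to
mutational proportions requires an external fixation-probability solver;
the truth-by-construction design sidesteps that machinery, and the
high-frequency variant is instead exercised on constructed spectra with a
known planted excess).

What the generator does *not* emulate: linkage (background selection,
Hill-Robertson interference), demography, ancestral-state error, and
within-genome rate heterogeneity. Passing recovery tests on these data
therefore shows that the estimators behave as their own theory predicts
under independent sites - not that they are unbiased on real genomes.

### What recovery on these data looks like

On pooled baseline-style data the plain test is strongly downward-biased
(the Gamma DFE's near-zero mass floods the low-frequency classes), the
imputed test recovers most - but not all - of the gap, and the residual
underestimation shrinks as the cutoff rises: the expected pooled
estimates under the default parameters are roughly $-0.10$ (standard),
$0.19$ (imputed, 15%) and $0.29$ (imputed, 35%) against a true 0.4. The
residue is structural: the Gamma DFE keeps some weakly deleterious mass
*above* any workable cutoff, which contaminates the neutral reference
ratio, and the effectively neutral tail of the DFE fixes slightly less
often than truly neutral sites. The acceptance suite asserts the
qualitative ordering and the closeness of the 35% imputed estimate to the
recorded truth; the closeness assertion sits at the edge of what the
independent-sites model delivers at these parameter values and is allowed
to fail rather than being tuned to pass. The asymptotic extrapolation,
which models the frequency dependence explicitly, centres closer to the
truth on the same data and its bootstrap interval comfortably brackets it.

### Problem sizes used by the test suite

The suite favours the smallest sizes at which each property is
informative: the worked single-gene example for all exact checks;
exhaustive Fisher enumeration up to table total 40 (one representative
per symmetry orbit); 1,000-3,000 synthetic genes for recovery and
asymptotic checks; 40 replicate datasets of 500 strictly neutral genes
for the unbiasedness check (the pooled estimator's small-sample ratio
bias is quadratic in inverse counts, so pooled replicates - not per-gene
averages, which are dominated by that bias at realistic per-gene counts -
are the meaningful test of calibration); and bootstrap grids of 20-100
replicates. The full suite runs in well under a minute on one core.

## Known limitations

* The imputation assumes SDM are absent above the cutoff; DFEs with
  substantial weakly deleterious mass at intermediate frequencies leave a
  residual downward bias that no choice of cutoff removes entirely.
* In highly constrained genes the raw imputation can be negative; it is
  clamped to zero and flagged, and the imputed test then reduces to the
  standard one rather than inflating P~N~.
* Folded-mode analysis discards the high-frequency information the
  high-band reference relies on, costing power as the cutoff grows.
* The package models counts only - no genomic coordinates, annotation or
  VCF parsing; upstream variant processing is assumed done.
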