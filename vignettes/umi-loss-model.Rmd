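---
title: "Counting molecules with UMIs: the amplification model behind umicountr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules with UMIs: the amplification model behind umicountr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why raw UMI counts are biased

Unique molecular identifiers (UMIs) let a sequencing experiment count
molecules instead of reads: every original molecule is tagged before PCR, and
after sequencing reads are grouped by tag, so each distinct UMI should equal
one original molecule. Two effects break this equality:

* **Lost molecules.** A molecule whose family of PCR copies attracts zero
  reads is invisible; one whose UMI attracts fewer reads than the
  error-correction threshold `T` is deliberately discarded. Both deflate the
  count.
* **Phantom UMIs.** PCR chimeras, sequencing errors and index misassignment
  create UMIs with no molecule of origin. Because these artifacts arise late
  in the reaction or at random, they carry characteristically few reads, and
  inflate the count.

`umicountr` filters the phantoms with the read-count threshold and then
scales the surviving count back up by the estimated fraction of true
molecules lost to the same filter. Everything hinges on a mechanistic model
of how many reads a true molecule attracts.

## The model

**Amplification.** PCR is a Galton–Watson branching process: in every cycle
each molecule of a family is duplicated independently with probability `E`,
the reaction's *efficiency*. Family sizes follow
`M_0 = 1, M_i = M_{i-1} + Binom(M_{i-1}, E)`, with mean `(1+E)^i` and
variance `((1-E)/(1+E)) (1+E)^i ((1+E)^i - 1)`. The *normalized family size*
`F = lim M_i / (1+E)^i` has mean 1 and variance `(1-E)/(1+E)`; its
distribution no longer depends on the cycle count, which is why the cycle
count is not a model parameter. The distribution of `F` has no closed form;
`build_density_table()` pre-computes its density `f(x; E)` on a grid by
Monte-Carlo simulation of the branching process, and `fsd_density()`
interpolates it.

**Sequencing.** Sequencing is Poisson sampling: given `F`, the read count of
a UMI is `C | F ~ Poisson(F * D)`, where `D` is the mean number of reads per
molecule (the *depth*). Marginally `P(C = k)` is the mixture integral of the
Poisson pmf over `f(x; E)`, evaluated with the midpoint rule on the density
grid (`umi_read_pmf()`); its moments are `E(C) = D` and
`V(C) = D + D^2 (1-E)/(1+E)`. At `E = 1` the model is exactly Poisson — the
extra `D^2`-term is the contribution of PCR stochasticity, and ignoring it
(as a plain Poisson model does) under-estimates the loss whenever `E < 1`
(`poisson_loss_baseline()` quantifies this).

**Loss and correction.** The loss is `loss = P(C < T)`: the probability that
a true molecule is unsequenced or filtered. Given `n_obs` surviving UMIs,
the corrected count is `n_obs / (1 - loss)` (`correct_count()`).

**Estimation.** Only UMIs with `C >= T` are observable, so `E` and `D` are
fitted by the method of moments on the *censored* distribution: find `(E, D)`
whose censored mean and variance (`umi_censored_moments()`) equal the sample
mean and variance of the observed reads-per-UMI (`fit_readcount_model()`).
At `T = 0` the fit is closed-form: `D = m`, `E = (1 - v')/(1 + v')` with
`v' = (v - m)/m^2` clipped to `[0, 1]`.

**Shrinkage.** Per-gene fits are noisy when a gene has few UMIs. The final
loss estimate is the James–Stein-type combination
`loss_shr = lambda * loss_raw + (1 - lambda) * loss_all` with
`lambda = s / (s + u / n_obs)`, where `s` is the between-gene variance of the
true loss and `u` the proportionality constant of the raw estimator's
variance (`~ u / n_obs`). Both are fitted by weighted least squares on the
squared deviations of the raw losses from their mean, with weights
`w(n) = n / (1 + n/100)` that saturate at 100 so that moderately observed
genes — the ones shrinkage actually helps — dominate the fit
(`fit_shrinkage_prior()`). Genes with fewer than two surviving UMIs (or a
failed fit) take the library-wide loss directly (`lambda = 0`) and are
excluded from the prior regression.

## Parameters that matter

| Parameter | Meaning | Units | Default / range |
|---|---|---|---|
| `efficiency` (E) | per-cycle duplication probability | — | estimated; grid (0, 1] |
| `depth` (D) | mean reads per molecule | reads | estimated; search `[1e-4, 1e6]` |
| `threshold` (T) | minimum reads for a UMI to be kept | reads | user choice; see `threshold_scan()` |
| `umis_per_molecule` | UMIs arising per original template | — | 1 (2 for both-strand labelling) |

The threshold is deliberately not chosen automatically: the practice this
package supports is to inspect `threshold_scan()` / `autoplot()` output and
pick the lowest `T` at which the observed reads-per-UMI histogram matches the
model prediction above `T` while the bins below `T` are over-abundant
(phantom territory). For phantom-free data the corrected total is insensitive
to this choice (verified in the test-suite at a relative spread below 2%).

## Numerical choices

* **Density grid.** Efficiencies 0.02–1.00 in steps of 0.02 by default (no
  extrapolation below the grid: convergence of the limit is pathologically
  slow as `E -> 0` and the variance formula is discontinuous at `E = 0`, so
  zero efficiency is rejected). Sizes use bins of width 0.01 up to `x = 2`
  *centred on multiples of 0.01*, so that `x = 1` — the entire mass of `F`
  at `E = 1` — is a bin midpoint and the midpoint rule reproduces Poisson
  formulas exactly in the degenerate limit; beyond `x = 2` bin widths grow
  geometrically (factor 1.08) to the support end at `x = 50`.
* **Convergence of the limit.** Families are simulated until
  `(1+E)^i >= 1e4` (at most 2000 cycles); the residual variance deficit of
  the rescaled size is then at most `1e-4` relative.
* **Common random numbers.** All efficiency columns of a table are driven by
  the same per-cycle uniforms (binomial draws by inverse transform), so
  interpolated functionals vary smoothly in `E` rather than carrying
  independent Monte-Carlo noise per column; this keeps censored-moment
  inversion well-posed between grid nodes.
* **Interpolation.** Linear in `x` (the 0.01 bins already resolve the
  structure) and linear in `E` between columns, clipped at 0; the
  interpolated distribution at off-grid efficiencies is validated against
  fresh branching-process draws at a Kolmogorov–Smirnov distance below 0.01.
* **Censored moments without cancellation.** Heavy censoring makes the
  textbook rewrite `E(C) - sum_{k<T} k P(C=k)` cancel catastrophically;
  instead the censored moments integrate closed-form Poisson partial
  expectations (`lambda Q(T-1, lambda)` etc.) per grid point, which remain
  accurate even when the loss approaches 1.
* **Moment inversion.** For fixed `E` the censored mean is strictly
  increasing in `D`, solved by bracketed root-finding; the outer search on
  the censored-variance residual first scans the grid nodes (where the
  residual is monotone), returns an exact node root when one exists, and
  otherwise runs Brent inside the single bracketing interval — under deep
  censoring the residual can wiggle between nodes because the far tail rests
  on few Monte-Carlo draws. Moment pairs outside the attainable region are
  clamped to the nearest domain boundary and flagged (`at_boundary`;
  under-dispersed data clamp at `E = 1`, exactly the `v'` clipping of the
  closed form).
* **Probabilities** are clamped to `[0, 1)`; a fit whose survival
  probability falls below `1e-12` is treated as a numerical loss of 1 and
  refused.

## The simulator, and what passing tests do and do not show

`simulate_umi_library()` generates data from the model itself: per gene,
`n_true` molecules each receive a family size from the pre-computed `F`
distribution (inverse-CDF sampling on the density grid, validated against
direct branching-process simulation) and a read count
`Poisson(F * D)`; zero-read UMIs are dropped. Phantoms are injected at a
configurable rate with `1 + Geometric` read counts of mean 1.5 — a
deliberate artifact convention mimicking their empirically low read counts,
*not* a mechanistic chimera model. A `phantom` column retains the ground
truth for evaluation.

Because the simulator shares the package's own generative assumptions,
passing recovery tests demonstrates internal consistency — estimation,
censoring, loss correction and shrinkage invert the stated model — but not
robustness to what real libraries add: UMI sequence errors and barcode
collisions (handled upstream by UMI-grouping tools and out of scope here),
efficiency drift across cycles and plateau effects, fragment-length-dependent
efficiency (supported only implicitly, by using any feature column as the
grouping variable), and phantom read-count distributions unlike the assumed
geometric shape.

Two further caveats surfaced by the tier-design simulations are worth
stating plainly. First, the library-wide loss comes from fitting one `(E, D)`
pair to the *pooled* reads-per-UMI distribution; when efficiencies vary
widely between genes, the pooled mixture is over-dispersed relative to any
single-parameter model, so the library-wide loss over-states the average
gene's loss, and genes shrunk mostly to it inherit that bias. With average
losses around 10% the effect is negligible; in simulations pushed to average
losses around 40% it reaches several percentage points on weakly expressed
genes. Second, `n_obs / (1 - loss_hat)` is a plug-in ratio: by Jensen's
inequality its expectation slightly exceeds the truth when `loss_hat` is
noisy, visible only for genes with very few UMIs at high loss.

## Problem sizes used by the tests

The shipped test-suite and the acceptance script rebuild a reduced density
table (efficiency grid 0.05–1.00 in steps of 0.05, `1e5` draws per column)
and simulate libraries of `1e5` UMIs for recovery checks, 210 genes over
seven abundance tiers (10–10 000 molecules, 30 genes each, `E ~ U(0.25, 0.8)`,
`D = 6`, `T = 5`) for end-to-end accuracy, 2000 genes for the shrinkage
regression, and a 150-gene library rescaled to a mean depth of one read per
molecule (`T = 2`, the lowest threshold that still filters single-read
phantoms) for the low-depth regime. These sizes are the package's choice of a
desk-scale experiment; production tables default to a 0.02 grid at `1e6`
draws per column.
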