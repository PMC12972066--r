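---
title: "Methods: burst statistics for trapped single-molecule FRET"
author: "fretburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst statistics for trapped single-molecule FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(fretburst)
```

## The measurement and the data model

A trapped-molecule smFRET experiment holds one fluorescently labeled
molecule in a confocal detection volume for hundreds of milliseconds while
photons are counted in a donor and an acceptor channel. The raw data for
this package is a *burst*: a contiguous stretch of elevated two-channel
fluorescence from one trapping event, binned at 1 ms, together with one
constant pair of background rates per burst (backgrounds drift between
trapping events, so they are estimated per burst, not globally).

The conformational readout is the proximity ratio

$$\mathrm{PR} = \frac{I_A}{I_D + I_A},$$

with $I_D$, $I_A$ the *background-corrected* intensities, computed either
per bin (bin-wise PR) or from the full-burst sums (burst-wise PR). PR is an
uncorrected FRET indicator: no gamma correction or distance conversion is
attempted, because every comparison in this package is between distributions
of PR, or between PR statistics and their matched photon-level null models,
where instrument factors cancel.

Two conventions matter downstream and are fixed here once:

* **Invalid bins.** Background correction can push a bin's total corrected
  intensity to zero or below. Such bins carry no usable FRET information;
  their PR is undefined (`NA`) and they are excluded pairwise from every
  statistic. They are never clamped, because clamping piles probability mass
  at 0 and 1 and biases the PR distributions.
* **Filtering.** Bursts shorter than 100 ms are removed (strict: a burst of
  exactly 100 ms is kept), then bursts whose mean corrected total intensity
  exceeds 40 counts/ms are removed as likely aggregates. The intensity rule
  is applied to *corrected* totals: single-molecule intensities are reported
  background-corrected (20–30 counts/ms), while raw totals would sit at
  50–70 counts/ms and the 40-counts/ms rule would remove everything.

## The synthetic world

`simulate_burst_ensemble()` generates ground-truth-labeled data with the
statistical structure the estimators assume, so that every stage of the
analysis is testable without instrument data. Defaults are fixed to the
experimental regime they emulate:

| parameter | default | why |
|---|---|---|
| brightness | 25 counts/ms total signal | reported single-molecule range 20–30 |
| background donor / acceptor | 12 / 22 counts/ms | reported ranges 10–15 and 20–25 |
| durations | Exp(mean 350 ms) truncated to [100, 2000] ms | typical observations 0.1–1 s, maximum ~2 s; the truncated exponential is a choice, not a fit — no empirical duration distribution is published |
| states | PR 0.4 and 0.8, $k_{12}=k_{21}=5\,\mathrm{s^{-1}}$ | two well-separated states with a 100-ms relaxation time, inside the window the method can resolve |

Emission is the minimal shot-noise model: the latent conformational state
follows a continuous-time two-state Markov chain; each 1-ms bin's true PR is
the occupancy-weighted average of the state PRs (sub-bin dynamics average
within the bin); the signal photon count per bin is Poisson with the
brightness as mean, split donor/acceptor binomially at the true PR; and
independent Poisson background photons are added per channel. Dye
photophysics (blinking, spectral fluctuations), the microsecond excitation
modulation of the trap, and polarization effects are deliberately absent —
so a green test establishes that an estimator behaves correctly under
shot-noise statistics, not that real data are free of photophysical
artifacts.

## Photon re-coloring nulls

The central inferential device is re-simulation of the *experimental*
photons under a chosen ground truth (`recolor_bursts()`): per bin the total
raw photon count is kept exactly, a constant expected background total
$b = b_D + b_A$ (rounded, capped at the bin total) is re-colored binomially
at $b_A/(b_D+b_A)$, and the remaining photons are re-colored binomially at
the scenario's PR:

* **static homogeneity** — one shared PR, the grand mean of all valid
  bin-wise PRs: all PR scatter is shot noise;
* **static heterogeneity** — each burst keeps its own burst-wise PR:
  between-molecule spread is real, within-burst dynamics are absent.

Because bin totals, burst count and durations are preserved, the null
carries exactly the experiment's shot-noise structure. Choices the source
description leaves open, fixed here: the per-bin background total is
allocated deterministically (rounded expectation) rather than drawn;
scenario PRs are clamped to $[0,1]$ before the binomial draws (corrected-
intensity PRs can leave the unit interval through noise); if a burst has
zero stored background but nonzero counts, all photons are treated as signal
and a message is emitted.

## The four analyses

**Variance profile** (`variance_profile()`). Per burst, the sample
($n-1$) SD of the bin-wise PRs; bursts grouped by burst-wise PR into 51
intervals centered at $0.00, 0.02, \dots, 1.00$; group means reported only
where a group holds strictly more than 20 bursts. Assignment is to the
nearest center, with exact midpoints going to the lower center
(deterministic tie-break; the boundary assignment is not specified in the
source description). Bursts with burst-wise PR outside $[-0.01, 1.01]$ are
excluded rather than clamped. Within-burst dynamics show up as group means
above the matched static-heterogeneity null.

**Burst-edge-aware correlations** (`intensity_correlation()`,
`pr_autocorrelation()`). Finite bursts make the standard autocorrelation
estimator invalid; the segmented estimator restricts every sum at lag
$\tau$ to bursts longer than $\tau$ and to start times $t$ with $t+\tau$
inside the same burst. For intensities,

$$G^{X\times Y}(\tau)=\frac{\left(\sum_{k:T_k>\tau}\sum_{t=0}^{T_k-\tau-1}
X_k(t)\,Y_k(t+\tau)\right)\sum_{k:T_k>\tau}(T_k-\tau)}
{\left(\sum\sum X_k(t)\right)\left(\sum\sum Y_k(t+\tau)\right)}-1 .$$

For PR, the default normalization is the per-lag Pearson coefficient of the
paired samples $\{PR(t), PR(t+\tau)\}$, with means and SDs over exactly the
contributing pairs — guaranteeing $g(0)=1$ and $|g|\le 1$. A second mode
normalizes the lagged covariance about the single grand-mean PR by its
lag-0 value; both are exposed because the source presents both forms, and
the per-lag mode is the canonical one here. A pair contributes only when
both bins are valid. The lag grid is every integer millisecond (no
multi-tau binning), to 300 ms by default.

For a two-state exchange the PR autocorrelation decays as
$\exp(-(k_{12}+k_{21})\tau)$; `fit_relaxation_time()` recovers
$1/(k_{12}+k_{21})$ by log-linear fitting. (The alternative reading that
the curve loses 50% at the relaxation time is inconsistent with the
exponential form — the loss at $\tau_r$ is $1/e$ — and is not asserted
anywhere.)

*Known estimator artifact.* On a finite heterogeneous ensemble the
estimator is not exactly flat in $\tau$ even for truly static molecules:
as $\tau$ grows, long bursts contribute proportionally more pairs, so the
effective molecule weighting drifts with lag. On 350-burst synthetic
ensembles this drift is ~3% of the curve level over 1–100 ms and grows
beyond 100 ms where rare long bursts dominate; the acceptance checks
therefore test flatness as drift small relative to level, not as exact
horizontality, and curves beyond ~100 ms should be read with care.

**Recurrence analysis** (`recurrence_curves()`,
`conditional_pr_histograms()`). The median bin-wise PR over all bursts
splits bins into high-FRET (strictly above) and low-FRET (strictly below)
regions; ties stay unlabeled. For each delay $\tau$ the conditional
probabilities $p(\mathrm{HF}(t)\mid \mathrm{HF}(t-\tau))$ and
$p(\mathrm{HF}(t)\mid \mathrm{LF}(t-\tau))$ are computed over all pairs
inside the same burst. Long-lived states keep the two curves separated out
to long delays; fast exchange (or the homogeneity null) collapses both to
the unconditional 50%. The burst-length condition is $\omega_i \ge \tau$ as
printed in the source equations (a burst with exactly $\tau$ bins
contributes no pairs, so the distinction from the strict inequality used in
the intensity correlations is vacuous); this per-equation fidelity is
intentional.

**Diffusion** (`msd_curve()`, `estimate_D()`). Two-dimensional MSD with
overlapping windows and a least-squares line (with intercept) over lags
1–10 by default; $D = \text{slope}/4$. The source does not state its fit
window or whether displacements overlapped; overlapping windows and the
1–10 range are the standard choices. Trajectory reconstruction from trap
electrode voltages is out of scope — the input is a position trajectory.

## Bootstrap

All confidence intervals are burst-level nonparametric bootstrap
(`bootstrap_ci()`): bursts (never bins) resampled with replacement, 200
replicates by default, percentile bounds using the canonical
$(B+1)\alpha$ order-statistic rule (R quantile type 6; the default type-7
interpolation gives systematically narrower intervals). Data-derived
references — the recurrence median, the homogeneity grand-mean PR — are
recomputed inside each replicate, treating them as part of the estimator.
Resampling happens after filtering: the filtered set is the analysis
population. Percentile intervals carry an $O(1/n)$ undercoverage; at the
ensemble sizes of real experiments (>1000 bursts) they are within a
percent of nominal, while on very small sets (~100 bursts) coverage drops
to ~92%.

## Degenerate inputs and numerical choices

* Bursts whose total corrected intensity is $\le 0$ have no burst-wise PR
  and are excluded from PR statistics (flagged, not clamped).
* Zero PR variance at a lag leaves the per-lag correlation undefined
  (`NA`); the global normalization errors outright, since its denominator
  is a single number.
* A recurrence delay with no qualifying start bins is `NA`.
* The Chung–Kennedy filter (window 10, exponent 10 by default; the source
  cites the filter without parameters) is visualization-only and never
  enters a statistic. Its variance weights use an $10^{-12}$ floor so a
  zero-variance window dominates any noisy one without overflow.
* `detect_bursts()` is an explicitly approximate stand-in for manual burst
  marking (threshold on the background-subtracted total, single-bin gaps
  bridged, segments under 5 bins discarded); pre-segmented data bypasses
  it.

## A worked example

```{r example, eval = FALSE}
set <- simulate_burst_ensemble(simulation_config(n_bursts = 300, seed = 7))
fset <- filter_bursts(set)
fit <- analyze_bursts(fset, max_lag = 100, n_boot = 200, seed = 7)
summary(fit)
plot(fit)
```

The summary reports the burst-wise PR distribution, the 1-ms
autocorrelation level (~0.35 here: roughly a third of the PR variance is
molecule identity, the rest shot noise), and the recurrence probabilities;
the four-panel plot overlays the re-colored nulls.

## Limitations

* Only one- and two-state exchange is generated; the estimators themselves
  are model-free, but multi-state ground truths must be supplied as data.
* No photon-level (sub-bin) correlators: 1 ms binning is the time
  resolution floor.
* The deposit adapter (`read_deposit_bursts()`) is configuration-driven
  because the archived data layout is not described in the text; it is a
  best-effort ingestion path, exercised in tests against schema-mapped
  fixtures only.
* No HDF5 container: no HDF5 R binding is available in the supported
  dependency set, so the CSV burst-table pair is the interchange format.
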