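---
title: "Covariance statistics of spatially organized balanced networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance statistics of spatially organized balanced networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models implemented in `critcov`, the
assumptions behind them, the parameters that matter, and the numerical
choices made where the design was genuinely open. It states no empirical
number that the package's tests and acceptance script do not themselves
compute.

## 1. The scientific question

Multielectrode recordings from motor cortex show pairwise spike-count
covariances of either sign between neurons separated by millimetres --- a
"salt-and-pepper" pattern far beyond the few hundred micrometres reached by
direct connections, and seemingly unrelated to cell types. `critcov`
implements a mechanistic account: in an excitatory--inhibitory network
with unstructured, short-range random connectivity, multi-synaptic paths
dominate the interaction between distant neurons once the *effective*
connectivity operates close to the edge of linear stability. The control
parameter is the spectral bound $R$, the largest real part among the
eigenvalues of the effective connectivity matrix $W = S \cdot J$ (synaptic
weights times postsynaptic gains). As $R \to 1$:

* the *mean* covariance stays small at all distances (inhibition-dominated
  balance keeps the population eigenvalue negative), while
* the *variance* of the covariance distribution decays exponentially with
  an effective length constant $d_\mathrm{eff}$ that diverges, so
  individual pairs at any distance can be strongly (anti-)correlated;
* because covariances are generated by the network state rather than by
  anatomy, a small change in the working point (per-neuron mean inputs,
  hence gains) reshapes the whole covariance pattern while leaving rates
  almost intact.

## 2. The spatial network model

`grid_geometry()` tiles a periodic square domain into $n \times n$ cells,
each housing four excitatory (E) and one inhibitory (I) neuron at the cell
centre; distances are cell-to-cell (minimal image). Connections between an
ordered pair are drawn from a binomial distribution with `n_trials` trials
at probability $q(x) = p_0\,k(x/d_b)$, where $k$ is an exponential
(default) or gaussian kernel and $d_b$ the length scale of the
*presynaptic* population ($d_E$, $d_I$). Multapses arise for
`n_trials > 1`. Weights depend only on the presynaptic population
($w_E > 0$, $-g\,w_E$ for inhibition), and
`assemble_effective_connectivity()` rescales a sampled matrix globally so
that its measured spectral bound equals a target $R$ exactly (tolerance
$10^{-3}$); an all-zero draw is an error.

Default parameters, and why:

| parameter | default | rationale |
|---|---|---|
| `pitch` | 0.4 | one lattice cell per electrode of a 400-micron-pitch array (units = mm) |
| `d_E`, `d_I` | 0.4, 0.4 | within the 0.1--0.4 mm reach of direct cortical connections; equal scales keep the inhibition-dominance condition independent of the profile ratio |
| `peak_probability` | 0.3 | sparse local connectivity with usable indegrees on a coarse lattice |
| `n_trials` | 1 | see "spectral outliers" below; multapses remain available as an option |
| `g_ratio` | 8 | twice the break-even value 4 of the 4E+1I composition: clearly inhibition-dominated (negative population eigenvalue) |

**Spectral outliers.** Binomial multapse draws with several trials at
peak probabilities around 0.2 concentrate a lot of synaptic weight in rare
local clusters, which produces isolated eigenvalues well beyond the
disorder bulk. Calibrating such an outlier to the target $R$ leaves the
bulk --- which carries the long-range covariance physics --- far
subcritical, and every realization-versus-theory comparison degrades. The
defaults therefore use Bernoulli synapses; `n_trials` is still a free
parameter for users who want multapses.

**Realized disorder.** Even without outliers, the extreme eigenvalue of a
finite realization fluctuates a few percent above the disorder bulk edge,
and $d_\mathrm{eff}$ is very sensitive to $R$ near criticality. For
realization-level comparisons the package therefore measures the *realized
disorder strength* (`realized_disorder()`): the zero mode of the squared
deviations of the calibrated matrix from its ensemble mean, reduced over
the two receiver populations. Theory curves for a given realization are
evaluated at this value, not at the nominal target.

## 3. Closed-form covariance statistics

Within linear-response theory, with ensemble mean $M$ and variance $S$ of
the effective connectivity and white-noise drive of strength $D$, the mean
and the variance of the distribution of time-lag--integrated pairwise
covariances are the matrix expressions

$$\bar c = (1-M)^{-1}\,\tfrac{D}{1-R^2}\,(1-M)^{-T}, \qquad
  \overline{\delta c^2} = (1-S)^{-1}\,\big(\tfrac{D}{1-R^2}\big)^2\,(1-S)^{-T},$$

implemented in `covariance_moments()` by linear solves (never explicit
inversion) and symmetrized. The normalization of $D$ is pinned by the
empty network: $M = S = 0$ gives the identity times $D$. The spectral
bound entering the prefactor is the square root of the zero mode of $S$;
because the excluded self-connection differs between E and I receivers,
this zero mode is computed exactly from the $2\times 2$
receiver-population matrix rather than from a row sum (at $g = 8$ the
difference is substantial).

By translation symmetry the eigenvalues of $S$ are the two-dimensional
Fourier transform $s(K)$ of the variance kernel
(`profile_fourier_kernel()`), and resumming all propagation paths gives
the spatial interaction kernel

$$B(x) = \frac{1}{(2\pi)^2}\int d^2k\, \frac{s(K)}{1-s(K)}\,e^{iKx},$$

evaluated either by radial quadrature of the exact kernel or through a
rational ([0/2] Pade) approximation of $s$ around $K=0$, which yields
modified Bessel functions: $B(x) \propto K_0(x/d_\mathrm{eff})$, and for
the two-fold spatial convolution entering the variance profile
$(B**B)(x) \propto x\,K_1(x/d_\mathrm{eff})$, i.e.
$x\,e^{-x/d_\mathrm{eff}}$ at long range. The pooled decay constant is

$$d_\mathrm{eff}^2 = \frac{c_2}{s_0\,(1-s_0)}, \qquad
  c_2 = \sum_b s_b\,\langle x^2\rangle_b/4, \quad s_0 = R^2,$$

which for a single exponential profile reduces to
$d_\mathrm{eff} = d\,\sqrt{3/2}\,/\sqrt{1-R^2}$: monotonically increasing
in $R$ and divergent at criticality. Per-population constants carry an
extra $\langle x^2\rangle_b/4$ term, so that
$d_{\mathrm{eff},E}^2 - d_{\mathrm{eff},I}^2$ equals the anatomical
difference $a\,(d_E^2 - d_I^2)$ *independently of* $R$ --- near
criticality both constants are large and their relative difference is
small. Second moments $\langle x^2\rangle_b$ are taken from the
implemented kernel (including the binomial $1-q$ factor), as discrete
lattice sums when a geometry is supplied and as continuum integrals
otherwise; the discrete lattice sum also serves as a test oracle for the
continuum transform. The accuracy of the rational approximation was
checked against the directly measured tail of the matrix expression on a
$30\times 30$-cell lattice (agreement ~1%); on small boxes, tail slopes
are extracted after dividing out the known $\sqrt{x}$ prefactor, because
naive curve fits over a window of a few $d_\mathrm{eff}$ are
systematically biased by the pre-asymptotic shape.

The mean covariance is governed by the *population eigenvalue* $m_0$ (zero
mode of the signed mean kernel; negative in inhibition-dominated
networks). Because the E and I mean kernels enter with opposite signs, the
[0/2] approximation is unreliable there; `mean_decay_constant()` instead
locates the pole of $m(K)/(1-m(K))$ by analytic continuation of the exact
continuum kernel (for $m_0 < 0$ the pole sits near the inverse excitatory
profile scale, so the mean decays steeply --- always below
$d_\mathrm{eff}$), and `mean_profile()` evaluates the full curve by
quadrature with per-population convolution terms. When no pole exists
before the branch point (e.g. exactly equal profiles), the decay is
limited by the direct profile and $\bar d = \max(d_E, d_I)$ is reported.

## 4. Rate dynamics

`simulate_rate_network()` integrates
$\tau\,\dot z_i = -z_i + \sum_j J_{ij}\,\phi(z_j) + \mu_i + \xi_i\sqrt{\tau}\,\sigma_i$
with Euler--Maruyama ($dt = \tau/20$ by default, enforced
$dt \le \tau/10$), identity or ReLU output, a divergence guard, and a
seed-reproducible noise stream. Integrated covariances are reported in
units of $\tau$, estimated from time-bin averages with bins of $50\tau$;
the convention is fixed so that `stationary_covariance_lyapunov()` --- the
deterministic zero-frequency solve $(1-W)^{-1}\mathrm{diag}(\sigma^2)(1-W)^{-T}$
--- reduces to $\mathrm{diag}(\sigma^2)$ for $W = 0$ and the two
estimators are directly comparable. The equal-time state variance is also
tracked (for the uncoupled Ornstein--Uhlenbeck case it equals
$\sigma^2/2$, one of the unit-test oracles).

## 5. The working-point experiment

One sparse random ReLU network (fixed indegree $K = pN$, weight
$w = -R/\sqrt{(N/2)p(1-p)}$, from viewing the half-active network as an
effective linear network of half the population size) is evaluated under
two external input patterns sharing a component of variance
$(1-\epsilon)\sigma_\mathrm{ext}^2$ and differing by independent
components of variance $\epsilon\sigma_\mathrm{ext}^2$, so the input
patterns correlate at $1-\epsilon$. The mean drive
$\mu_\mathrm{ext} = R\,\sigma_\mathrm{ext}\sqrt{Np/(\pi(1-p)-(\pi-1)R^2)}$
makes the self-consistent mean total input zero, hence half the population
active; the closed form and a numerical fixed-point route are both
implemented and agree to $10^{-6}$.

Design choices:

* $\epsilon = 0.1$ by default, inferred from the printed input-pattern
  correlation of 0.90; configurable.
* The default covariance estimator is the deterministic linear solve on
  the active subnetwork ($W = J\,\mathrm{diag}(\phi'(z))$ at the
  noise-free fixed point), which removes estimator noise; the full
  stochastic simulation is available as a cross-check and is the only
  route to split-half reliabilities. The noise-free fixed point is found
  by damped iteration (the damping factor is set from the strongly
  negative population feedback $K w$, making the iteration a stable
  discretization of the relaxation dynamics).
* Reported rates are *noise-averaged*: $E[\phi(z+\xi)]$ via the
  closed-form ReLU moments with each neuron's linearized stationary noise
  SD. This is the deterministic analogue of the time-averaged rates a
  stochastic simulation reports, and it matters for the silent-neuron
  cutoff: near-threshold neurons have small positive mean rates rather
  than exact zeros. With the bare fixed-point rates the exclusion below
  removes more neurons and the between-network rate correlation drops by
  a few hundredths.
* Rate-pattern correlations exclude neurons silent (rate $< 10^{-3}$) in
  either network; covariance-pattern correlations are computed on a
  seeded random sample of 5000 pairs with silent neurons included. These
  conventions follow the reference experiment's figure panels.

`sweep_spectral_bound()` repeats the experiment over a range of $R$: the
covariance-pattern similarity decays with $R$ much faster than the
rate-pattern similarity --- the working-point sensitivity of intrinsically
generated covariances near criticality.

## 6. The spike-analysis pipeline

The empirical pipeline mirrors standard multielectrode practice:

* **Classification** (`classify_units_by_waveform()`): two steps ---
  width thresholds on the average waveform (narrow = putative inhibitory,
  broad = putative excitatory, a gap stays unclassified; 0.33/0.34 ms and
  0.40/0.41 ms are the recommended monkey-specific thresholds), then
  demotion of units whose single-waveform agreement fraction falls below
  a threshold. That fraction is not published; the default is 0.60,
  configurable and surfaced in the unit table.
* **Filtering** (`filter_units()`): SNR $\ge$ 2.5 and mean rate $\ge$ 1 Hz,
  both inclusive, with a removal log; an optional simplified coincidence
  filter drops spikes synchronous across $\ge k$ electrodes within one
  30 kHz sampling step (a stand-in for full synchronous-artifact removal,
  which is out of scope).
* **Covariances** (`bin_and_covary()`): spike counts on concatenated
  analyzable intervals (1 s bins for resting state; one 200 ms bin per
  trial for task sub-periods), covariance with the $l-1$ normalization,
  correlations by diagonal normalization; zero-variance units yield
  flagged `NA` correlations but keep their covariances.
* **Distance resolution** (`variance_vs_distance()`): open (non-periodic)
  electrode geometry, all distinct inter-electrode distances, units on one
  electrode at distance 0; per distance and class (EE/EI/II, pairs with
  unclassified members pooled separately) the variance of cross-covariances
  with a finite-sample correction: the sampling variance of a covariance
  estimated from $l$ bins, $\approx (c_{ii}c_{jj}+c_{ij}^2)/(l-1)$,
  inflates the across-pair variance and is subtracted cell-wise. For
  long recordings the correction is a fraction of a percent (verified in
  the tests).
* **Fits** (`fit_exponential_decay()`): weighted least squares of
  $y = a\,e^{-x/d}$ with weights proportional to pair counts (normalized),
  either free per class or with one shared decay constant; the weighted
  mse of both is comparable (the constrained fit can never win).
  Optimization is multi-start Nelder--Mead on log-parameters;
  non-convergence raises an error carrying the last iterate. Cells with
  fewer than two pairs are flagged and excluded from fitting.
* **Epochs** (`segment_epochs()`, `compare_epochs()`): 200 ms sub-periods
  S1/S2 after trial start and P1/P2 after cue-off; per session two
  within-epoch and four between-epoch pattern correlations; a two-sided
  pooled t test with $df = (N_s\cdot2-1)+(N_s\cdot4-1)$, Shapiro--Wilk
  and F diagnostics, a Kolmogorov--Smirnov fallback when normality fails,
  and the confidence interval $m \pm t(df)\,s$ with the pooled standard
  deviation $s$.

## 7. The synthetic Utah-array generator

`generate_resting_dataset()` builds a calibrated spatial network on a
$26\times 26$-cell lattice (10.4 mm box) and reads out a central
$10\times 10$-electrode window, so that array distances (up to 5.1 mm) are
unaffected by the periodic boundary. About 130 units are sampled from the
window's neurons, with synthetic waveform widths (bimodal, straddling the
0.33/0.34 ms thresholds, a configurable fraction inside the gap and a
fraction with low single-waveform agreement to exercise both
classification steps), SNR values straddling 2.5, and log-normal base
rates spanning roughly 1--30 Hz (a few units below the 1 Hz filter on
purpose). Spiking is doubly stochastic: per 1 s bin a rate vector
$\lambda = r + \kappa z$ with $z \sim N(0, C)$ drawn from the network's
stationary covariance (rectified at zero), then Poisson counts and uniform
spike times snapped to the 30 kHz sampling grid (which also makes file
round trips lossless). The gain $\kappa$ is set so the spike-count
covariances have a target dispersion (default SD 1.5 per 1 s bin). The
dataset carries its ground truth: the true count-covariance matrix, the
realized disorder strength, and $d_\mathrm{eff}$ evaluated at it.

The generator's target spectral bound is 0.9. Two finite-size phenomena
shaped this and the lattice size: at $R = 0.95$ on smaller boxes the few
most-amplified spatial disorder modes are system-wide, and a single
realization's variance-versus-distance curve can be flat rather than
exponential (a genuine property of near-critical finite networks, not an
estimation failure). Even at $R = 0.9$ the per-realization fitted decay
constant is heavy-tailed across seeds; end-to-end checks therefore compare
the *median* fitted constant over a fixed seed set against the
ground-truth $d_\mathrm{eff}$.

`generate_task_dataset()` adds the instructed-delay event template (trial
start, warning signal at +0.4 s, cue at +0.8 s for 0.3 s, GO 1 s after
cue-off) and implements the epoch contrast through per-neuron gain fields
correlated $1-m$ between epochs ($m$ = `modulation`): log-normal rate
gains plus binary transmission gates that enter the effective
connectivity, calibrated so the larger of the two epoch-gated spectral
bounds equals $R$ (both epochs stable). At high $R$ and nonzero $m$, a
sizable fraction of pairs flips covariance sign between epochs while
within-epoch rates stay almost perfectly reproducible --- the pattern the
epoch-comparison statistics are designed to detect. Background Poisson
spiking between the analysis windows keeps overall unit rates realistic
for the filter.

What the generator deliberately does *not* emulate: spike waveform shapes
beyond a scalar width, refractoriness and spike-history effects,
non-stationarities (drift, movement transients), eye-movement artifacts,
electrode crosstalk, and the heavy-tailed unit-per-electrode counts of
real arrays. Passing end-to-end tests therefore demonstrates correctness
of the pipeline's statistics under the model's own assumptions, not
robustness to every artifact of real recordings; the pipeline itself runs
unchanged on real datasets loaded with `read_spike_dataset()`.

## 8. Problem sizes and numerical tolerances

Test and acceptance computations use sizes chosen to keep the full suite
comfortably reproducible on a laptop: $16\times 16$-cell lattices for
matrix-versus-theory comparisons at $R = 0.8$ (where the box spans several
$d_\mathrm{eff}$), the paired-network experiment at its native
$N = 2000$ averaged over five seeds, the spectral-bound sweep at
$N = 1500$ with one replicate per point, and six generator seeds for the
end-to-end median. Calibration tolerance is $10^{-3}$ on the spectral
bound; quadratures use relative tolerances of $10^{-6}$--$10^{-9}$ with
integration ranges set by the kernel support; fits run multi-start from
three initial length scales. Large eigenproblems use ARPACK (largest real
part) with a dense fallback.

## 9. Known limitations

* The closed-form statistics are linear-response results; they describe
  threshold-linear and spiking networks only to leading order in the
  fluctuations.
* The rational approximation of the Fourier kernel targets the
  long-range limit; below about two connectivity length scales the
  quadrature route (or the full matrix expression) should be used.
* Mean-profile theory for strongly asymmetric E/I profiles relies on a
  numerically continued pole and inherits its assumptions (isotropy,
  continuum limit).
* Near criticality, single realizations deviate strongly from ensemble
  theory on experimentally sized windows; all realization-level claims in
  the package are about typical (median) behaviour.
* The coincidence filter is a simplified stand-in, and the epoch t test
  uses the pooled degrees-of-freedom convention of the reference analysis
  rather than a mixed-model treatment of session dependence.
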