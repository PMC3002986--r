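---
title: "Stochastic adaptation and interspike-interval statistics: models, theory, and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic adaptation and interspike-interval statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptisi)
```

This vignette is the package's methods account: the models and their
assumptions, every tunable parameter with its units and default, the
derivations behind the closed-form theory, the numerical design decisions,
what the synthetic-data generators do and do not emulate, and the known
limitations. It states no empirical result that the test suite does not
itself recompute.

## 1. The model hierarchy

### Channel-coupled perfect integrate-and-fire neuron

The reference model is a perfect (non-leaky) integrate-and-fire neuron with
an inhibitory adaptation current carried by $N$ independent two-state
channels:

$$\dot v = \mu - \Delta\,a(t) + \sqrt{2D}\,\xi(t), \qquad
v \ge \theta \Rightarrow \text{spike},\ v \to 0 .$$

Voltages are measured in units of the threshold $\theta$ (default 1) and
time in milliseconds; $\mu$ (base drive) and $\Delta$ (maximal adaptation
drive) are in $\theta$/ms, the white-noise intensity $D$ in $\theta^2$/ms.
The open fraction $a = A/N$ follows first-order kinetics with time constant
$\tau_a$: each closed channel opens with rate $p_\infty/\tau_a$ and each
open channel closes with rate $(1-p_\infty)/\tau_a$, so that
$\tau_a \dot p = p_\infty - p$ for the single-channel open probability. The
activation $p_\infty(t)$ is a two-valued function of the spike history: 1
during a pulse of width $\delta$ after each spike (an idealized action
potential; a new spike restarts the pulse clock) and a subthreshold value
$p_0$ (default 0) otherwise.

Because the PIF firing rate is drive over threshold and the time-averaged
activation is $\langle a\rangle = p_0 + r\delta(1-p_0)$, the stationary rate
solves a fixed point,

$$r^* = \frac{\mu - \Delta p_0}{\theta + \Delta\delta(1-p_0)},$$

*independently of both noise sources* (`stationary_rate_adapted()`). This is
what makes the model a clean testbed: the noise composition can be changed
at a fixed operating point.

### Diffusion approximation

Splitting $a = \bar a + \eta$ into the deterministic filter
$\tau_a\dot{\bar a} = p_\infty - \bar a$ and a fluctuation, and treating the
channel shot noise as Gaussian with matched first and second jump moments,
$\eta$ becomes a stationary Ornstein–Uhlenbeck process with correlation time
$\tau_a$ and the binomial variance
$\sigma_a^2 = \langle a\rangle(1-\langle a\rangle)/N$ (additive-noise
approximation: the state dependence of the noise strength is frozen at its
mean). The *additive validity ratio* returned by
`channel_noise_intensity()` estimates the relative fluctuation of the noise
strength, $\sigma_x(1-2\langle a\rangle)/(2r(1-\langle a\rangle))$ with
$\sigma_x^2 = \alpha\Delta^2\sigma_a^2/\theta^2$ the variance of the
instantaneous rate; the approximation is trustworthy when this is well below
one (it is $\approx 0.02$ at the standard set below, and grows as
$N^{-1/2}$).

### Limit cases

* **Deterministic adaptation + white noise** ($N\to\infty$, $D>0$):
  `simulate_pif_white()`. For $\tau_a r^* \gg 1$ the adaptation variable is
  effectively constant and the ISI density is the inverse Gaussian of a PIF
  with reduced drive (mean-adaptation approximation).
* **Stochastic adaptation** ($D = 0$, finite $N$): the feedback can be
  eliminated exactly at the linear level. Writing the instantaneous drive
  $x = \mu - \Delta(\bar a + \eta)$ and using
  $p_\infty \approx \delta\,x/\theta$ for the slowly varying rate, $x$
  itself follows an OU process with mean $\alpha\mu$, correlation time
  $\alpha\tau_a$ and variance $\alpha\Delta^2\sigma_a^2$, where

  $$\alpha = \frac{\theta}{\theta + \Delta\delta(1-p_0)}$$

  is the **degree of adaptation** — every effective parameter is scaled by
  the common factor $\alpha$ (`effective_colored_params()`). With
  subthreshold activation the drive is $\alpha'(\mu-\Delta p_0)$ with
  $\alpha' = \theta/(\theta+\Delta\delta(1-p_0))$. The reduced model
  (`simulate_pif_colored()`) is a PIF neuron driven by constant drive plus
  an *independent* colored noise; its two dimensionless parameters are the
  weak-noise strength
  $\epsilon = \sigma^2_{\rm eff}\tau_{\rm eff}/(\mu_{\rm eff}\theta)$ (the
  IG limit has $CV^2 = 2\epsilon$) and the time-scale separation
  $\rho = \tau_{\rm eff} r^*$.

A design note on $\tau_{\rm eff}$: the package stores the reduced model's
correlation time as $\alpha\tau_a$, not $\tau_a$. That is what the exact
elimination above yields, it is what makes the measured step-response decay
and the SCC decay constant come out right, and it matches the classical
effective-time-constant result for spike-frequency adaptation. The field
$\rho$ of `eff_colored_params()` is accordingly $\tau_{\rm eff} r^*$.

### Step response

Averaging the adaptation filter gives the mean-field rate dynamics: after a
base-current step $\Delta\mu$ at $t_0$ the rate jumps by $\Delta\mu/\theta$
and relaxes exponentially to the adapted value with time constant
$\alpha\tau_a$ (`rate_step_response()`); the ratio of adapted to
instantaneous rate increase is exactly $\alpha$. Note the time constant is
$\alpha\tau_a$, not $\tau_a$ — the two coincide only for weak adaptation,
and the trial-averaged simulations (`simulate_step_response()`) resolve the
difference clearly at the standard parameters ($\alpha = 5/9$).

## 2. Standard parameters

Defaults of `pif_config_standard()`, chosen once as a realistic tonically
firing adapting neuron and used throughout tests and examples:

| parameter | symbol | default | rationale |
|---|---|---|---|
| threshold | $\theta$ | 1 | voltage unit |
| base drive | $\mu$ | 0.18 $\theta$/ms | gives $r^* = 100$ Hz |
| adaptation strength | $\Delta$ | 0.8 $\theta$/ms | $\alpha = 5/9$, a strong but common degree of adaptation (unadapted rate 180 Hz adapts to 100 Hz) |
| adaptation time constant | $\tau_a$ | 100 ms | typical M-current scale; $\rho_{\text{sep}} = \tau_a r^* = 10$ |
| spike pulse | $\delta$ | 1 ms | action-potential width, $\delta \ll \langle I\rangle$ |
| channels | $N$ | 1000 | mid-range of plausible M-channel counts; $\epsilon \propto 1/N$ ($0.018$ at $N{=}1000$, $0.178$ at $N{=}100$) |
| white noise | $D$ | $10^{-3}\,\theta^2$/ms when present | $CV \approx 0.14$ without adaptation, a typical cortical value |

With these values the mean open fraction is $r^*\delta = 0.1$ and the
expected number of closing transitions between spikes is $N\langle
a\rangle/\tau_a \approx 1$ per ms at $N = 1000$ — a sparse event stream on
the ISI scale, which is exactly the regime where the quality of the
diffusion approximation is interesting.

## 3. Closed-form theory

### Inverse-Gaussian reference and rescaled shape measures

The white-noise PIF without adaptation has the inverse-Gaussian ISI density
with mean $\theta/\mu$ and $CV^2 = 2D/(\mu\theta)$; its skewness is $3\,CV$
and its excess kurtosis $15\,CV^2$. The rescaled measures

$$\tilde S = \frac{\kappa_3/\kappa_2^{3/2}}{3\,CV}, \qquad
\tilde K = \frac{\kappa_4/\kappa_2^{2}}{15\,CV^2}$$

are therefore exactly 1 for IG data; the calibration is verified in the
tests by quadrature over `ig_density()` itself, not against stored
constants. (For an exponential law they evaluate to $2/3$ and $2/5$, used as
an independent estimator oracle.)

### Weak-noise ISI density of the colored-noise model

For the reduced model the unwrapped voltage
$x(s) = \mu_{\rm eff}s + \int_0^s\eta$ is Gaussian, and for weak noise the
ISI density is the probability flux of the free process across the
threshold,

$$p(I) = \big\langle (\mu_{\rm eff} + \eta(I))\,\delta(x(I)-\theta)
\big\rangle ,$$

with the noise at the preceding spike drawn from the *flux-weighted*
stationary density $p_0(\eta) \propto (\mu_{\rm eff}+\eta)\,
\phi_{\sigma^2}(\eta)$ — the distribution of a stationary OU process sampled
at spike times. All conditional moments are Gaussian, so the average is
available in closed form (`colored_isi_density()`); the rate-biased initial
condition is what makes the mean of the density exactly
$\theta/\mu_{\rm eff}$, reproducing the noise-independence of the firing
rate. Because a truncated asymptotic density is not exactly normalized, the
returned density is renormalized numerically over
$[0, \langle I\rangle + 10\sqrt{\kappa_2}\,]$ (a shape-preserving choice;
the raw normalization defect is $O(\epsilon)$).

In the quasi-static limit $I \ll \tau_{\rm eff}$ the noise is frozen within
the interval, $I = \theta/(\mu_{\rm eff}+\eta)$, giving
(`colored_isi_small_t()`)

$$p_0(I) = \frac{\theta^2}{\sqrt{2\pi\sigma^2}\,\mu_{\rm eff}\,I^3}
\exp\!\left(-\frac{(\theta/I-\mu_{\rm eff})^2}{2\sigma^2}\right),$$

whose mean is exact but whose second and higher moments diverge — it is a
small-interval tool only. The $I^{-3}$ tail of the quasi-static form is why
stochastic adaptation yields densities with a sharper peak *and* a heavier
tail than the matched IG.

### Weak-noise cumulants, shape functions, saturation constants

`weak_noise_shape(epsilon, rho)` computes $\kappa_1..\kappa_4$, $CV^2$ and
$\tilde S, \tilde K$ by high-resolution Simpson quadrature of the flux
density (an adaptive window around the deterministic period; cumulant
cancellation is controlled by integrating central moments directly). The
leading orders in $\epsilon$ — functions of $\rho$ alone — are evaluated at
$\epsilon_{\rm ref} = 10^{-4}$ (contamination $O(10^{-4})$). Two exact
anchors pin the function down:

* $\rho \to 0$: the noise decorrelates within an ISI, the density tends to
  the IG, so $\tilde S, \tilde K \to 1$ and $CV^2 \to 2\epsilon$;
* $\rho \to \infty$: the quasi-static expansion of
  $I = \theta/(\mu+\eta)$ with the rate-biased $\eta$ gives, to fourth
  order in $\sigma/\mu$: $\kappa_2 = \sigma_y^2$, $\kappa_3 = 6\sigma_y^4$,
  $\kappa_4 = 72\sigma_y^6$ (with $y = \eta/\mu$), hence skewness $6\,CV$
  and excess kurtosis $72\,CV^2$ and the saturation constants

  $$\tilde S \to 2, \qquad \tilde K \to \tfrac{72}{15} = \tfrac{24}{5}.$$

Both limits are asserted in the tests, and the full surface is validated
against the colored-noise simulator at $(\epsilon, \rho) = (0.05, 5)$ within
Monte-Carlo error.

### Serial correlations

**Stochastic adaptation.** Linearizing the interval around the period,
$\delta T_i = -\frac{1}{\mu_{\rm eff}}\int\eta$, and using the OU
autocovariance gives the geometric sequence (`scc_colored()`)

$$\rho_k = e^{-k\hat T}\,
\frac{\cosh\hat T - 1}{\hat T - 1 + e^{-\hat T}}, \qquad
\hat T = \frac{\langle I\rangle}{\tau_{\rm eff}} = \frac{1}{\rho},$$

positive at all lags, decay constant equal to the ratio of effective
correlation time to mean ISI, independent of the noise variance, vanishing
$\sim \rho/2$ in the white-noise limit and approaching 1 for very slow
adaptation.

**Deterministic adaptation.** The noise-free system has a stable limit
cycle: the adaptation drive decays from its post-spike value $x_0$ and jumps
by $\Delta\delta/\tau_a$ at each spike; the two defining conditions
(threshold crossing in the period $T^*$, periodicity) give
$T^* = (\theta+\Delta\delta)/\mu = 1/r^*$ and
$x_0 = (\Delta\delta/\tau_a)/(1-\beta)$, $\beta = e^{-T^*/\tau_a}$
(`limit_cycle()`). Weak noise makes the post-spike deviation $\delta x_i$ a
linear autoregressive map with multiplier $\gamma = \beta - u$,
$u = \beta x_0(1-\beta)/\dot v_T$, where $\dot v_T = \mu - x_0\beta$ is the
drift at threshold; propagating the same noise into the intervals yields
(`scc_deterministic()`)

$$\rho_k = -\frac{u\,(1-\gamma\beta)}{u^2 + 1 - \gamma^2}\;\gamma^{\,k-1}.$$

The noise intensity cancels in the covariance/variance ratio, odd lags are
always negative, even lags are negative iff $\gamma > 0$ (oscillating SCC
for strong adaptation, $\gamma < 0$), the coefficient vanishes in both
$\rho$ limits and is most negative near $\tau_a r^* \approx 1$. The theory
idealizes the pulse as an instantaneous jump; the simulator's finite pulse
(with its $1-a$ saturation) makes the effective jump a few percent smaller,
a visible but sub-tolerance systematic at desk-scale Monte-Carlo error.

## 4. Numerical design

* **Exact Gillespie with piecewise-constant rates.** Waiting times are
  capped at the next schedule breakpoint and redrawn; by memorylessness this
  is statistically exact, with none of the inefficiency of thinning.
* **Exact OU updates.** The OU fluctuation and its time integral over a step
  are a bivariate Gaussian with known covariance; the simulators use that
  exact conditional update (never Euler), removing one discretization error
  entirely. Series expansions guard the $h \to 0$ covariance entries
  against cancellation.
* **Event-driven exactness at D = 0.** The channel-coupled PIF has constant
  drift between events, so crossing times are analytic; the
  deterministic-adaptation case uses safeguarded bisection/Newton on the
  analytic voltage. With white noise, Euler–Maruyama steps of
  `dt = min(tau_a, mean ISI)/1e3` are used with linear-interpolated
  crossings; the known $O(\sqrt{dt})$ first-passage bias is below the MC
  tolerances at this step (the dt-halving test asserts it).
* **Perfect-integrator reset trick.** Because the drift never depends on
  $v$, reset is equivalent to unwrapped integration with spikes at every
  threshold multiple; the colored-noise simulator exploits this, so no reset
  error accumulates.
* **Pulse bookkeeping.** Integration segments are cut at pulse boundaries;
  when a spike lands inside a step, the deterministic filter is corrected
  analytically for the partial pulse, keeping the adaptation jump unbiased
  at $O(dt)$ without discarding noise draws. Overlapping pulses (ISI <
  $\delta$) restart the pulse clock; a warning fires when overlaps exceed 1%
  of spikes.
* **Stationary initialization.** Trials start from the stationary mean
  adaptation (binomial channel count, Gaussian OU value) and a uniformly
  distributed voltage phase — the exact stationary phase law of a PIF — so
  trial-averaged rates show no onset ringing. Remaining transients are
  removed by dropping spikes before `max(10 tau_a, 21st spike)`.
* **Estimators.** Cumulants use unbiased k-statistics (plug-in third and
  fourth moments are visibly biased at $n \sim 10^3$); SCCs use the pooled
  stationary estimator; all standard errors come from a circular block
  bootstrap with block length `max(10, 2 x decorrelation lag)`, which is
  essential for the strongly correlated sequences of slow adaptation noise.
  Histograms default to Freedman–Diaconis binning (overridable — the
  discrete ISI atoms of very small channel pools need explicit fine bins).
* **Quadrature.** Densities are integrated by composite Simpson on windows
  adapted to the density's center and width; the IG shape identity is
  reproduced to $10^{-10}$.
* **Traub–Miles integration.** Exponential-Euler gating updates (explicit
  and stable for the stiff spike-time rates) with Euler(–Maruyama) voltage
  steps at 0.01 ms; stochastic M channels are advanced by Gillespie with
  rates frozen for at most `refresh_cap` (0.05 ms default, well below every
  gating time constant); divergence raises an error naming the step.

## 5. What the generators emulate — and what they do not

The synthetic spike trains emulate: tonic suprathreshold firing with
spike-frequency adaptation, a single slow adaptation conductance with
two-state kinetics, fast fluctuations lumped into additive white noise, and
(in the Traub–Miles layer) a full spike-generating sodium/potassium
apparatus. They do **not** emulate: leaky or nonlinear subthreshold
integration in the PIF layer, multi-state or cooperative M-channel kinetics,
calcium-dependent adaptation (its slow calcium fluctuations would enter the
same equations in place of the channel noise), voltage-dependent noise
amplitudes, synaptic input structure, or multicompartment morphology. A
green test therefore establishes the internal consistency of this model
hierarchy and its theory — not that any particular biological neuron
matches it.

## 6. Calibrated Traub–Miles operating point

The M-current gating uses the Ermentrout-style sigmoid
$w_\infty(V) = 1/(1+e^{-(V+35)/10})$ and a bell-shaped $\tau_w(V)$ scaled by
`tauw_scale = 12.543`, calibrated so the exponential buildup of $w$ during
forced 100 Hz firing has a 100 ms time constant (`tm_w_buildup_constant()`
verifies this within 10%). `g_M = 2` mS/cm² and `current = 29.5` µA/cm² were
then calibrated to 100 Hz at $N = 1000$ stochastic channels (CV ≈ 0.23); a
CV as large as 0.6 at 100 Hz could not be reached with this gating shape
(CV saturates near 0.33 in $g_M$), so the operating point was chosen for a
clean noise-source dichotomy at matched rate and CV, with the white-noise
reference at $D = 2$, `current = 29.44` (CV ≈ 0.27). Drives must be retuned
(`tm_calibrate_drive()`) whenever $D$ or $N$ changes, since adaptation makes
the f–I curve noise-composition-dependent in rate-matched comparisons.

## 7. Known limitations

* The weak-noise SCC formula truncates at leading order: its error grows
  linearly in $\epsilon$ (measured: ~0.03 at lag 1 for $\epsilon = 0.18$,
  ~0.004 at $\epsilon = 0.044$, below MC resolution at $\epsilon = 0.011$).
  At moderate channel noise it is therefore distinguishable from simulation
  at high Monte-Carlo precision, and one figure-level acceptance clause is
  deliberately left failing rather than widening the band.
* The channel and diffusion models differ by ~2% in CV at the standard
  operating point (channel slightly larger) — within the 5% agreement the
  acceptance demands, but a real, resolvable difference; higher shape
  measures differ more at small $N$.
* The white-noise Traub–Miles ISI density is a *refractory-shifted*
  near-inverse-Gaussian: against the unshifted IG with matched mean and CV
  the L1 distance stays around 0.10–0.15 because ~5 ms of every interval is
  spike/AHP dead time at 100 Hz.
* The quasi-static small-interval density agrees with the full expression
  only across the bulk of the distribution in strongly slow-noise regimes;
  in far tails the exponents differ by construction.
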