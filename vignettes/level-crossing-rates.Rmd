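---
title: "Level-crossing firing rates for spatially extended neuron models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-crossing firing rates for spatially extended neuron models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricecable)
```

## The model

Many neurons are not electrically compact: the membrane voltage varies
substantially across their dendrites, soma and axon, and *in vivo* they are
bombarded by synaptic input distributed over the dendritic membrane. In the
fluctuation-driven, low-rate regime typical of cortex, an analytical handle
on the firing rate of such cells is valuable for network theory. This
package implements one: compute the stationary Gaussian statistics of the
subthreshold voltage at the spike-initiation site, and convert them into a
firing-rate estimate with Rice's level-crossing formula.

The subthreshold voltage $v(x,t)$ (measured from the leak reversal) on each
driven dendrite obeys the stochastic cable equation

$$\tau_v \frac{\partial v}{\partial t} =
  \mu - v + \lambda^2 \frac{\partial^2 v}{\partial x^2} + s(x,t),
\qquad
\tau_s \frac{\partial s}{\partial t} =
  -s + 2\sigma_s\sqrt{\lambda\tau_s}\,\xi(x,t),$$

where $\xi$ is space–time white noise. The drive field $s$ is temporally
filtered (time constant $\tau_s$) but spatially white; $\mu$ is the
effective resting potential produced by the mean synaptic conductance, and
$\sigma_s$ sets the fluctuation amplitude. This additive-noise description
arises from lumping excitatory and inhibitory Poissonian synaptic
bombardment into mean plus Gaussian fluctuations and dropping the
multiplicative conductance–voltage cross term, which is justified when
fluctuations are weak relative to the synaptic driving force (excitatory
reversal far above rest). Everything downstream assumes passive membranes
and this linear regime.

Two structural consequences of the mean synaptic conductance matter
throughout. Writing $\epsilon = g/g_L = (E_L - E_s)/(E_L + \mu - E_s)$ for
the total-to-leak conductance ratio, a passive axon or soma that shares the
dendrite's per-area capacitance and leak has the *longer* time constant
$\tau_\alpha = \epsilon\,\tau_1$, and the axonal length constant follows
from the radius ratio as
$\lambda_\alpha = \lambda_1\sqrt{\epsilon\, a_\alpha/a_1}$ (using
$\lambda \propto \sqrt{a/g}$ and $g_1/g_\alpha = \epsilon$). Only such
ratios, never absolute conductances or radii, enter the computations; this
is why `neuron_model()` is parametrized by `mu`, `a_ratio` and the
dominance factors. When sweeping `mu` at fixed `lambda_1` the dendritic
radius is implicitly rescaled as $a_1 \propto g_1(\mu)$
(ratio $\epsilon(11\,\mathrm{mV})/\epsilon(8\,\mathrm{mV}) \approx 1.05$
across the usual drive range).

## Closed forms for the sealed dendrite

For a dendrite of length $L$ with sealed (zero-flux) ends, a cosine-mode
calculation gives the stationary variances in terms of the kernel

$$C(x,\eta) = \frac{\cosh\!\big((L-x)\sqrt{\eta}/\lambda\big)
  \cosh\!\big(x\sqrt{\eta}/\lambda\big)}
  {\sqrt{\eta}\,\sinh\!\big(L\sqrt{\eta}/\lambda\big)},$$

as

$$\sigma_v^2(x) = 2\sigma_s^2\frac{\tau_s}{\tau_v}\{C(x,1) - C(x,\kappa)\},
\qquad
\sigma_{\dot v}^2(x) = \frac{2\sigma_s^2}{\tau_v\tau_s}C(x,\kappa),
\qquad
\kappa = 1 + \tau_v/\tau_s.$$

Two length scales appear: $\lambda$ and the shorter $\lambda/\sqrt{\kappa}$.
The derivation is worth a sentence because the placement of the square
roots is easy to get wrong: diagonalizing the cable on Neumann modes and
integrating the Ornstein–Uhlenbeck temporal kernel yields
$\int_0^\infty \mathrm{d}q\,[(1+\lambda^2q^2)(\kappa + \lambda^2 q^2)]^{-1}$-type
integrals whose arctangent values carry $1/\sqrt{\kappa}$, not $1/\kappa$.
The package's unit tests pin these forms three independent ways: against
the frequency-domain spectrum below, against direct simulation of the
discretized model, and against the slow-membrane limit
$\sigma_v^2 \to \sigma_s^2$ as $\tau_s/\tau_v \to \infty$.

Letting $L/\lambda \to \infty$ at a sealed end gives the one-dendrite
statistics ($\sigma_v^2 = 2\sigma_s^2(\tau_s/\tau_v)(1 - 1/\sqrt{\kappa})$,
$\sigma_{\dot v}^2 = (2\sigma_s^2/\tau_v\tau_s)/\sqrt{\kappa}$), and at the
midpoint the two-dendrite (junction) statistics, exactly half of them. Note
that $\lambda$ has dropped out entirely — with only semi-infinite neurites
no other quantity carries units of length, so the firing rate of these
models cannot depend on the electrotonic length, a property the test suite
checks both analytically and by simulation.

## Rice's formula and its domain of validity

For a stationary Gaussian voltage with mean $\langle v\rangle$, standard
deviation $\sigma_v$ and derivative standard deviation $\sigma_{\dot v}$,
the rate of positive-going crossings of the threshold $v_{th}$ is

$$r_{uc} = \frac{1}{2\pi}\frac{\sigma_{\dot v}}{\sigma_v}
  \exp\!\left(-\frac{(v_{th} - \langle v\rangle)^2}{2\sigma_v^2}\right).$$

The derivative variance must exist, which is why the temporally filtered
drive is essential: white-noise input gives infinite $\sigma_{\dot v}$.

The upcrossing rate is used as a proxy for the firing rate of the same
model with an integrate-and-fire reset. Two caveats deserve emphasis,
because the package's own simulations quantify them:

* **Crossing clustering.** Rice's rate counts *every* upcrossing,
  including rapid re-crossings that follow a recent one; the whole-cell
  reset removes those cluster partners, so the reset rate is always below
  the upcrossing rate. In long-run simulations at the standard parameters
  ($\sigma_s = 3$ mV) the excess is about 16% at $3.6\sigma$ below
  threshold ($\approx$ 0.05 Hz), 21% at $3.1\sigma$ ($\approx$ 0.3 Hz)
  and grows to roughly 40% by $2.6\sigma$ ($\approx$ 1 Hz). The
  approximation is therefore quantitatively tight only in the deeply
  subthreshold tail, and should be read as an upper bound with the right
  exponential dependence elsewhere. The acceptance suite states this
  comparison as a hard 20% band across the sub-5 Hz range and documents
  where it fails; the failures are a property of the approximation, not of
  either engine.
* **Sub- vs suprathreshold.** When the mean at the trigger point exceeds
  threshold the model fires deterministically;
  `deterministic_lif_rate()` provides that reference
  ($1/[\tau_v\ln((\langle v\rangle - v_{re})/(\langle v\rangle - v_{th}))]$).
  Morphologies with axonal or somatic load can remain subthreshold even
  when $\mu > v_{th}$, since the DC transfer to the trigger point is
  below one.

## Composite morphologies in the frequency domain

For dendrite(s) plus axon and soma the statistics at the trigger point are
computed by quadrature of the voltage power spectrum. The building blocks:

* The **sealed-end spectrum** of a single driven dendrite,
  $S_{end}(\omega) = 2\sigma_s^2\tau_s\big/\big[(1+\omega^2\tau_s^2)
  \sqrt{1+\omega^2\tau_v^2}\,\mathrm{Re}\,\gamma_v(\omega)\big]$ with
  $\gamma(\omega) = \sqrt{1 + i\omega\tau}$ (principal branch). Its
  moments reproduce the closed forms above to quadrature accuracy.
* The **relative input admittance** $\tilde f(\omega)$ of one driven
  dendrite within the whole neuron, built from semi-infinite-cable input
  admittances $G_\lambda\gamma(\omega)$ with weights
  $G_j \propto g_j^2\lambda_j^3$ (the form the $a \propto g\lambda^2$
  convention induces at fixed per-area parameters). With a lumped soma the
  denominator gains $\gamma_0^2 = 1 + i\omega\tau_0$ and the weights become
  the dominance factors $\rho_k = G_{\lambda k}/G_0$.
* The **composition rule**
  $S(\omega) = n\,|\tilde f(\omega)|^2\,
  e^{-2 x_{th}\mathrm{Re}\,\gamma_\alpha(\omega)/\lambda_\alpha}\,
  S_{end}(\omega)$: each of the $n$ independently driven dendrites
  contributes its sealed-end spectrum filtered by its admittance fraction,
  attenuated down the passive axon. The rule is derived from the junction
  Green's function and is enforced, rather than assumed, by limit tests:
  it must reduce to the one- and two-dendrite closed forms, collapse the
  soma model onto the nominal-soma model as $\rho_1 \to \infty$, and match
  the simulator on composite morphologies.
* The **mean transfer** $\langle v\rangle = n\mu\tilde f(0)
  e^{-x_{th}/\lambda_\alpha}$.

Because $|\tilde f|^2 \sim 1/n^2$ for large $n$, the total variance scales
as $1/n$ while the mean saturates — the origin of the non-monotonic
dependence of the firing rate on dendrite count and of the interior optimum
in the axon-to-dendrite radius ratio when the trigger sits down the axon
(attenuation length grows with radius, conductance load grows too; the
competition peaks near $a_\alpha/a_1 \approx 0.25$ at the standard
parameters).

**Quadrature.** $\sigma_{\dot v}^2$ is an $\omega^2 S$ integral whose tail
decays only as $\omega^{-3/2}$; truncating it would bias every rate.
`stats_from_psd()` therefore integrates adaptively on $[0, \omega_c]$
($\omega_c = 50/\min\tau$) and maps the remainder onto $(0,1]$ exactly with
$\omega = \omega_c/t^2$, where the integrand is bounded and smooth. Both
panels use `stats::integrate` at a relative tolerance of $10^{-10}$ and the
achieved error bound is attached to the result; closed-form comparisons in
the tests hold to $10^{-8}$.

## The simulator

`run_simulation()` is the ground truth for every analytic claim. It
integrates the discretized cable with an explicit Euler–Maruyama scheme on
a staggered grid: voltage and drive at $(k+\tfrac12)\Delta_x$, spatial
derivative at $k\Delta_x$, drive noise $2\sigma_s\sqrt{\lambda\tau_s/
(\Delta_x\Delta_t)}\,\psi$ per site and step. Choices a user should know:

* **Truncation.** Semi-infinite neurites are cut at
  $L = \max(1000\,\mu m,\,10\lambda)$ with sealed far ends; at the default
  $\lambda$ values boundary effects at the junction are far below
  Monte-Carlo resolution.
* **Junctions.** All neurites share one junction voltage; a nominal soma
  imposes discrete flux balance with weights $\lambda_k G_{\lambda k}$
  (current is conserved exactly on the lattice), a lumped soma advances its
  own voltage with the same explicit step. Proximal derivative nodes use
  the half spacing, an $O(\Delta_x)$ approximation at the junction only.
* **Stability.** $\Delta_t \le 2\tau/(1 + 4\lambda^2/\Delta_x^2)$ per
  neurite (and the analogous somatic bound) is checked at lattice build;
  the defaults $\Delta_x = 20\,\mu m$, $\Delta_t = 0.02$ ms sit at a
  safety factor of about 2.5 for $\lambda = 200\,\mu m$, and halving both
  steps leaves measured variances unchanged within Monte-Carlo error (a
  test asserts this).
* **Measurement.** The trigger voltage is read at the node containing
  $x_{th}$ (the junction itself for $x_{th}=0$; the sealed-end node sits at
  $\Delta_x/2$, where the closed-form variance is evaluated for
  comparisons). $\dot v$ is estimated by forward differences, which biases
  $\sigma_{\dot v}^2$ low by $O(\Delta_t)$ (about 6% at the defaults); it
  is reported for diagnostics and never used to *compute* rates.
  Threshold crossings are detected on the time grid; resets set every
  voltage node to $v_{re}$ and leave the synaptic field untouched.
* **Reproducibility.** One R-RNG stream per run (seeded via `set.seed`),
  consumed in a fixed site order; resets draw nothing, so reset and
  no-reset runs with the same seed share their noise realization exactly
  until the first spike — a property the tests exploit.
* **Transient.** $10\max(\tau_v, \tau_s, \tau_0)$ is discarded by default
  (configurable).

## Study conditions and what the tests do (and do not) show

The defaults encode the standard parameter set used throughout:
$E_L = -70$ mV, $E_s = 0$ mV, $\mu = 4\text{–}12$ mV,
$\tau_1 = 10$ ms, $\tau_s = 5$ ms, $\lambda_1 = 200\,\mu m$,
$\lambda_\alpha = 100\text{–}200\,\mu m$, $\sigma_s = 1\text{–}3$ mV,
$\rho_1 = 1\text{–}16$, $v_{th} = 10$ mV, $v_{re} = 0$ mV,
$x_{th} \in \{0, 30\}\,\mu m$. Simulation-based checks in the test suite
use 20 s of simulated time per seed (10 seeds) for variance comparisons,
100–400 s per grid point for rate comparisons, and 3-standard-error bands
throughout; these problem sizes were chosen so the whole suite runs
comfortably on a single core while keeping Monte-Carlo error a factor of a
few below the effects under test. The axon-load experiment at drive
$\mu = 8$ mV keeps every soma variant subthreshold at the junction; larger
drives push small-soma variants ($\rho_1 = 16$) suprathreshold, where the
1 Hz calibration underlying that experiment is meaningless.

The synthetic data generator *is* the model: Gaussian, additive,
stationary, passive. Passing tests therefore demonstrate the internal
consistency of the analytics and the correctness of the numerics — not
that real neurons behave this way. In particular the model omits
multiplicative conductance fluctuations, non-Poissonian presynaptic
statistics, active dendritic and somatic currents, back-propagating action
potentials and refractoriness; trigger positions on driven dendrites at
$x_{th} > 0$ and spatially heterogeneous drive are out of scope.

## Known limitations

* The upcrossing approximation's accuracy degrades from ~15% to ~40%
  between $3.6\sigma$ and $2.6\sigma$ threshold distance (see above); use
  it as a low-rate approximation, and validate with `run_simulation()`
  when absolute rates matter.
* Rates below ~0.05 Hz require very long simulations to verify; the
  analytic engine is effectively the only practical tool there.
* The lumped-soma explicit step inherits a stability bound that tightens
  with $n\rho_1\lambda_1$; very many dendrites on a very small soma need a
  smaller $\Delta_t$ (the lattice builder refuses unstable combinations
  rather than silently subcycling).

```{r example}
nm <- neuron_model(mu = 5, sigma_s = 3, a_ratio = 0.25, x_th = 30)
tidy(firing_rate(nm))
```
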