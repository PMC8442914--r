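---
title: "Controlling chaos-chaos intermittency by RRO feedback: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling chaos-chaos intermittency by RRO feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrocr)
```

## The model

Frontal-cortex activity is modelled as a scalar map

$$x(n+1) = F(x(n)) = K\left(B\tanh(w_2 x) - A\tanh(w_1 x)\right),$$

the net drive of an excitatory population (output weight $B$, input weight
$w_2$) opposed by an inhibitory one ($A$, $w_1$), attenuated by the
strength $K \in (0, 1]$ of the sensory-to-frontal feedback loop.  The map
is odd, with an unstable fixed point at $x = 0$ and, for the working
parameter set ($B = 5.821$, $w_1 = 0.2223$, $w_2 = 1.487$, $A \approx
13$), a local maximum $f_{\max} > 0$ and minimum $f_{\min} = -f_{\max}$
within $|x| < 1$.  Two qualitatively distinct regimes matter:

* **separated attractors** — the image of the extremum stays on its own
  side ($G(f_{\max}) > 0$), and a chaotic orbit is confined to one sign of
  $x$ forever;
* **merged attractors** — $G(f_{\max}) < 0$ and $G(f_{\min}) > 0$, the
  extremal images cross the origin, and the orbit hops chaotically between
  the positive and negative regions: chaos-chaos intermittency (CCI), the
  model's analogue of abnormally fluctuating neural activity.

Control is applied in two parts,

$$x(n+1) = F(x(n)) + C\,u(x(n)) + S(n), \qquad
u(x) = -(x - x_d)\,e^{-(x-x_d)^2/(2\sigma^2)},$$

with the Gaussian-windowed *reduced region of orbit* (RRO) feedback $C
u(x)$ and the weak periodic reference $S(n) = \alpha\sin(2\pi n/p)$.  The
feedback leaves the fixed-point structure alone but lowers $|f_{\max}|$
and $|f_{\min}|$ of the composite map $G(x) = F(x) + C u(x)$, so sweeping
$C$ moves the system through the attractor-merging bifurcation at
$G(f_{\max}) = 0$.  Chaotic resonance is the empirical observation that
slightly *below* that bifurcation the residual hopping entrains to the
weak reference.

Noisy estimation of the activity is modelled by
$u_e(x) = u(x + D\xi(n))$ with i.i.d. standard-normal $\xi(n)$ redrawn
every iteration: the corrupted measurement enters both the prefactor and
the window of $u$, while the state update itself uses the true $x(n)$.

## Parameters and defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| $A$ | inhibitory output weight | 13.0 | CCI territory for intermediate $K$ |
| $B, w_1, w_2$ | remaining synaptic weights | 5.821, 0.2223, 1.487 | fixed working set of the model |
| $K$ | sensory attenuation | 0.9 | inside the CCI band $0.85 \lesssim K \lesssim 0.98$ at $A = 13$ |
| $x_d$ | feedback centre | 0 | the map is point-symmetric about 0, the merging point |
| $\sigma$ | feedback window width | 1.0 | covers the extrema, which lie within $|x| < 1$ |
| $C$ | feedback strength | 0.2 | resonance peak at the defaults |
| $\alpha, p$ | stimulus amplitude, period | 0.15, 32 | weak stimulus; long periods entrain best ($p \in \{4, 8, 16, 32\}$ studied) |
| $D$ | measurement-noise strength | 0 | noise-free baseline |
| transient / recorded | run lengths | $10^3$ / $2\times 10^4$ | metric convergence at desk scale (see below) |
| trials | independent $x(0)$ | 10 | the standard trial count for mean ± SD aggregation |

All parameters are plain dimensionless map quantities; "time" is the
iteration index $n$.

## What the simulator emulates — and what it does not

The generator *is* the stated world: trajectories of the scalar controlled
map from random initial conditions.  Initial states are drawn uniformly on
$[-2, 2]$, excluding a band $|x(0)| < 10^{-3}$ around the unstable fixed
point so no trial is wasted sitting on the invariant point; the interval
spans both attractor basins.  Each trial seeds its own substream as
`seed + trial`, so enlarging a study never perturbs existing trials.  A
divergence guard aborts if $|x| > 10^6$; the map is bounded, so this can
only fire on an implementation defect.

A green test here establishes properties of this map, not of any neural
tissue: there is no spatial structure, no spiking, no EEG measurement
model, and the "stimulus" acts additively on a scalar.  Conclusions about
neurofeedback transfer only through the modelling analogy.

## Numerical choices

**Extrema of $G$.**  A coarse grid (10001 points by default) on
$[x_d, x_d + 3\sigma]$ and its mirror brackets each extremum, followed by
golden-section refinement (`optimize`, tolerance $10^{-12}$ in $x$), which
puts the error in $G$ well below $10^{-8}$.  The bracket is three window
widths wide — generous, since the extrema sit within one $\sigma$ — and a
coarse argmax landing on a bracket end is reported as an explicit
*no-extremum* result (monotone $G$, e.g. when inhibition is negligible)
rather than an error.  Sweeps reduce the coarse grid to about $10^3$
points; a regression test pins the refined values to the full-resolution
ones at $10^{-8}$.

**Critical feedback strength.**  $G(f_{\max})(C)$ is monotone through the
transition, so plain bisection on its sign over $C \in [0, 0.5]$ to a
tolerance of $10^{-4}$ suffices; the result is returned together with the
residual $G(f_{\max})$ at the root.  A range with no sign change returns
an explicit *no-transition* result.

**Lyapunov exponent.**  The perturbation method: replicas displaced by
$d_0 = 10^{-8}$ are evolved alongside the orbit for $\tau$ steps and the
mean log separation growth $\frac{1}{\tau M}\sum_k \ln(d_k(\tau)/d_0)$ is
accumulated over $M = 10^4$ non-overlapping windows after a $10^3$-step
transient.  The default $\tau = 1$ renormalizes every step, which keeps
separations far from both underflow and attractor size.  The closed-form
derivative average $\langle \ln|G'(x(n))|\rangle$ is kept as an
independent cross-check (test-only, never the primary path) and agrees
within 0.01.  Exponents are only meaningful for the autonomous map
($\alpha = 0$, $D = 0$); the estimator warns and ignores stimulus and
noise settings, and no exponent is reported for forced or noisy sweeps.
Sweep tables classify a point as chaotic when $\lambda > 10^{-3}$, a small
positive threshold absorbing estimator noise near zero.

**Synchronization.**  The binarized activity $X(n) = \pm 1$ ($+1$ iff
$x(n) \ge 0$; the tie at exactly zero goes to $+1$, immaterial on a
chaotic orbit) is correlated with the delayed stimulus $S(n + \tau)$ by
Pearson correlation.  The delay search is restricted to $\tau \in \{0,
\dots, p-1\}$ — $S$ is $p$-periodic, so larger delays are redundant — and
the analysis window is trimmed to the largest whole number of stimulus
periods, which makes the circular delay shift exact and the identities
$\langle S \rangle = 0$, $\langle S^2 \rangle = \alpha^2/2$ hold to
machine precision.  An orbit that never changes sign has zero variance in
$X$; such "pinned" runs are reported as correlation 0 with an explicit
flag rather than NaN, since they are precisely the no-CCI-response cases
and 0 is the value the resonance curves decay to.  Trial aggregation
reports mean ± SD of the per-trial delay-maximized correlation; with a
single trial the SD is reported as 0.

**Perturbation magnitude.**  $\Theta = \langle S(n)^2 + (C
u(x(n)))^2\rangle$ is the plain time-averaged sum of squares.  An RMS
reading ($\sqrt{\Theta}$) would be an alternative interpretation of the
same symbol; the sum-of-squares reading is the default because it
reproduces the headline scale $\Theta \approx 0.02$ at $\alpha = 0.15$,
$C = 0.2$ (the stimulus alone contributes $\alpha^2/2 = 0.01125$), whereas
the RMS reading would give $\approx 0.14$.  The RMS variant stays
available behind `perturbation_theta(..., rms = TRUE)`.

**CCI regions.**  A grid point belongs to the CCI region iff the analytic
merging condition holds *and* $\lambda > 10^{-3}$; regions are maximal
contiguous runs of such points, and each edge is refined by one bisection
level (the midpoint to the neighbouring non-CCI grid point is
re-evaluated).  Periodic windows embedded in a chaotic band split runs;
the package reports all runs and leaves any joining to the caller.

## Findings the package surfaces without resolving

* **Onset of the CCI band in $A$ at $K = 1$.**  The analytic merging
  condition opens at $A \approx 9.55$, and from there the orbit
  demonstrably hops with $\lambda > 0$, so `cci_regions()` reports a lower
  edge near 9.55.  Published figure-based readings of this onset quote
  $\approx 9.8$; on an 8-unit axis that is within eyeball resolution of
  the bifurcation diagram, but the two numbers differ by more than the
  merging condition's numerical error by orders of magnitude.  The package
  reports the computed value.
* **Direction of the peak shift with $K$.**  The merging thresholds
  $C^*$ increase with $K$ (0.23, 0.285, 0.34 at $K = 0.89, 0.90, 0.91$),
  and the computed resonance peak tracks them from below (peak near
  $C^* - 0.07$ in each case), i.e. the peak moves to *larger* $C$ as $K$
  grows.  Published prose also describes the opposite direction; both the
  thresholds and the peak locations are computable with this package, and
  the regression suite asserts only the relation the model actually obeys
  (peak below threshold, both increasing).
* **Time-series feedback strengths.**  Published examples show confined
  orbits variously at $C = 0.5$ and $C = 0.8$; both are deep in the
  separated regime at the defaults, and the package exposes $C$ freely.

## Scaling of the test suite

The full stated protocol (ten trials of $10^3 + 2\times10^4$ steps; grids
of a few hundred points) runs in seconds to a couple of minutes because
the system is a scalar map, and the acceptance-level checks use it
unchanged.  Unit and property tests use shorter runs (typically 4000–8000
recorded steps, 2–4 trials) and coarser grids where only qualitative
structure is asserted; the noise-robustness check uses a $D$ grid step of
0.05 rather than 0.02 for runtime, which does not affect the monotone
trend being asserted.

## Known limitations

* Exponents for the forced or noisy system are deliberately not computed.
* Region extraction depends on the grid: a periodic window narrower than
  one grid step can go unnoticed; the single-level bisection refinement
  sharpens edges but does not hunt for sub-grid windows.
* The trial mean of the delay-maximized correlation has a small positive
  bias for unsynchronized series (a maximum over $p$ noisy values), which
  is why fully asynchronous settings report $\approx 0.05$ rather than 0.
* `sweep_noise` regenerates noise inside per-trial substreams; changing
  the $D$ grid therefore changes the noise realisations (trial-level
  reproducibility is guaranteed, grid-level is not).
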