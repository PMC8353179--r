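---
title: "Simulating deuteron quadrupolar CEST under magic-angle spinning"
author: "qcest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating deuteron quadrupolar CEST under magic-angle spinning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcest)
```

## The experiment and the model

Chemical exchange saturation transfer (CEST) probes slow conformational
dynamics by parking a weak RF field at a series of resonance offsets
$\Omega$ and recording how much longitudinal magnetization survives a
saturation period $T$.  For a deuteron (spin 1) in a rotating solid the
relevant interaction is the quadrupolar coupling, whose secular frequency

$$\omega_Q = \frac{3\pi}{2} C_q\left(\frac{3\cos^2\theta - 1}{2} +
\frac{\eta}{2}\sin^2\theta\cos 2\phi\right)$$

depends on the orientation of the electric-field-gradient tensor
($C_q = e^2qQ/h$, asymmetry $\eta$).  Under magic-angle spinning (MAS) the
orientation becomes time periodic; for an axially symmetric tensor

$$\omega_Q(t) = \frac{3\pi}{4} C_q\left(\sqrt{2}\,\sin 2\beta\,
\sin(\omega_\mathrm{MAS}t + \alpha) - \sin^2\beta\,
\cos(2\omega_\mathrm{MAS}t + 2\alpha)\right),$$

with $(\alpha, \beta)$ the crystallite azimuth and polar angle about the
rotor axis.  The printed literature form of the first coefficient is
ambiguous between $2$ and $\sqrt{2}$; deriving the expression from the
explicit rotation composition (crystallite $\to$ rotor $\to$ magic-angle
tilt) fixes it to $\sqrt{2}$, and `quad_frequency_mas()` is tested against
that rotation oracle at $10^{-9}$ relative accuracy.  For $\eta > 0$ or
tilted tensors the package always rotates the full rank-2 Cartesian tensor
instead of using a closed form.

The density matrix of each site is expanded in the eight trace-orthonormal
operators returned by `spin_basis()` (four single-quantum, two
double-quantum, Zeeman order $S_z$, quadrupolar order $Q$).
Trace-orthonormality is the one normalization that makes the set a basis and
renders the commutator superoperator of any Hermitian Hamiltonian real and
antisymmetric, so the whole Liouvillian is a real matrix.  In the tilted
frame the secular Hamiltonian is
$H = \sqrt{2/3}\,\omega_Q Q + \sqrt{2}\,\omega_{RF} S_x + \sqrt{2}\,\Omega S_z$,
whose coefficients are locked by an independent construction with the
conventional spin-1 operators.

Exchange among $N$ sites (different tensor orientations, or different $C_q$)
enters as a direct product: the state vector holds 8 coherences per site,
the kinetic generator $K$ (column convention, $K p_\mathrm{eq} = 0$,
detailed balance) couples identical coherences across sites, and one
augmentation slot carries the Bloch--McConnell-style return of $S_z$ to its
site equilibrium as a homogeneous matrix term, so every propagation step is
a single real matrix exponential.  A phenomenological $T_1$ applies $-1/T_1$
to all eight coherences (a switch restricts it to $S_z$ only).

## Numerical scheme

The saturation propagator is assembled per rotor period as a time-ordered
product of 20 step exponentials with $\omega_Q(t)$ held at the step
midpoint, and saturation times are reached by matrix powers plus a
fractional-rotation factor; coherent evolution, exchange and relaxation are
exponentiated together (no operator splitting).  Matrix exponentials are
dense Pade evaluations in compiled code (RcppArmadillo).

Accuracy of the 20-step rule was measured against 100- and 2000-step
references.  At 25 kHz MAS the rotor propagator agrees elementwise to
$10^{-3}$ with the 100-step reference and powder-averaged saturation
observables agree with the 2000-step reference well below $10^{-3}$.  At
1 kHz MAS the converged 20-step error on powder-averaged observables is a
few $10^{-3}$ (up to a few percent for the purely coherent no-motion case
near rotary resonances): the per-step midpoint phase errors alternate in
sign over the rotor period and largely cancel, but not perfectly at slow
spinning.  A step-averaged (Gauss--Legendre) variant of the quadrature was
implemented and measured *worse* at 1 kHz -- it destroys precisely that sign
cancellation -- which is why the midpoint rule is the one shipped.  The
default of 20 steps per period therefore matches the standard practice for
this experiment class at the 10--120 kHz spinning rates where it is used;
below a few kHz the `n_rotor_steps` parameter should be raised.

Detection applies an ideal 90-degree read pulse ($S_z \to S_x$ per site) and
propagates only the four transverse coherences, sampling at the dwell time
with substeps of at most one twentieth of the rotor period.  Band
intensities integrate the real spectrum in windows one rotor frequency wide
centred on $k\,\omega_\mathrm{MAS}/2\pi$; every bin belongs to its nearest
band centre, so the partition is exact and the summed band areas equal the
first FID point (discrete Parseval identity -- the test suite asserts it to
$10^{-10}$).  The first FID point is halved (and the spectrum doubled) to
remove the constant baseline of the one-sided transform; a mild exponential
apodization (default 100 Hz, configurable) stabilizes narrow lines.
Because the all-bands intensity equals the total detected Zeeman order
exactly, `band_mode = "all_bands"` profiles skip the FFT pipeline and read
the site-summed $S_z$ directly; `band_mode = "central"` runs the full
detection block.  Every profile point is divided by a $T = 0$ simulation run
through the identical pipeline, which cancels pipeline constants.

## Motional models

* `two_site_flip()` -- two equally-(or unequally-)populated orientations
  whose tensor axes subtend a jump angle; the dimethyl-sulfone (DMS)
  rotameric flip uses the methyl-averaged $C_q = 55.3$ kHz and a 106
  degree jump.  Throughout the package $k_\mathrm{ex}$ denotes the *sum* of
  forward and reverse rate constants, so equal populations give
  $k_\mathrm{ex} = 2 k_\mathrm{flip}$.  This convention is asserted by
  tests because the field's usage varies.
* `methyl_three_site()` -- fast three-site jumps on a cone (tetrahedral by
  default).  In the fast limit the exchange-averaged tensor equals
  `average_tensor_fast_rotation()`, i.e. $C_q \to C_q/3$ for tetrahedral
  geometry; the suite checks the propagated lineshape at
  $k_3 = 10^{12}\,\mathrm{s}^{-1}$ against the pre-averaged tensor.
* `sphere_diffusion_plus_bound()` -- the amyloid-fibril side-chain model: a
  free state whose orientation diffuses isotropically (coefficient $D$,
  rad$^2$/s) over a near-uniform spherical grid, in exchange (rate
  $k_\mathrm{ex}$, bound fraction default 8%) with one rigid bound site.
  The literature model uses 192 surface sites but does not print the grid
  construction or the mapping from $D$ to inter-site rates.  We use a
  deterministic golden-spiral point set, nearest-neighbour edges weighted by
  inverse squared arc length, and a single global rescaling calibrated so
  the rank-2 orientational correlation of the generator decays at exactly
  $6D$; the rank-1 mode then lands within 5% of $2D$, which is the
  discretization-quality check the tests enforce.  The bound-site tensor is
  fixed along the reference z-axis (the model does not specify the binding
  orientation; with $\eta = 0$ surface tensors and detailed-balance uniform
  coupling the choice only matters through the bound-state spectrum itself).
* `compose_exchange()` -- direct product of a slow outer motion with a fast
  inner motion, used to verify that explicitly including methyl three-site
  jumps reproduces the pre-averaged-tensor description: at the DMS
  conditions the two CEST profiles agree to a maximum difference of about
  $10^{-3}$ in $I(T)/I(0)$.

## Longitudinal relaxation from methyl jumps

The secular Liouvillian conserves total $S_z$ without RF, so genuine $T_1$
must come from the non-secular quadrupolar fluctuations.  These are handled
outside the propagation engine: `t1_three_site_jumps()` evaluates the
rank-2 correlation functions of the jump model exactly (eigenmode sums of
the three-site generator), forms spectral densities at $\omega_0$ and
$2\omega_0$, and uses

$$\frac{1}{T_1} = \frac{3}{80}\,\chi^2\,[J_1(\omega_0) + 4 J_2(2\omega_0)],
\qquad \chi = 2\pi C_q,$$

with $J_m$ normalized so that an isotropically tumbling tensor with
correlation time $\tau$ gives $J = 2\tau/(1 + \omega^2\tau^2)$.  The
orientation-dependent rate is powder averaged; the average over each
crystallite's azimuth about its own axis is performed analytically (Wigner
cross-terms cancel), leaving a $\sin\beta$-weighted polar average.  For the
tetrahedral cone only $8/9$ of the second moment fluctuates, which the mode
amplitudes reproduce exactly.  An independent numerical quadrature of the
correlation functions agrees with the analytic Lorentzian route to better
than 1%.  The inverse map `t1_to_k3()` root-finds on the fast-motion branch
($3k_3 > \omega_0$).  With the DMS jump rates fitted in the literature
($4.9\cdot10^9$ and $3.2\cdot10^9\,\mathrm{s}^{-1}$) the forward map gives
$T_1 \approx 41$ ms at 115.1 MHz and $\approx 27$ ms at 92.1 MHz,
reproducing the measured calibration values; the published MAS correction
to $T_1$ at fast spinning is not printed anywhere we could verify, so it is
deliberately omitted and absorbed by the stated 25% tolerance.

## Powder and RF-inhomogeneity averaging

Powder sets are deterministic and seedless (`spiral`, golden-angle, or
product grid); 3000 orientations reproduce the analytic second moment of
the axial powder pattern to 1%, and reduced counts (16--300) are used in
the test suite, chosen so that the assertions are powder-converged at their
stated tolerances.  RF inhomogeneity is a measured distribution of field
scales $\omega_{RF}/\langle\omega_{RF}\rangle$: the package ships the two
six-point probe grids at scales $0.25\ldots1.5$ (weights
0.084/0.143/0.126/0.176/0.285/0.187 for the 1.3 mm probe and
0.065/0.097/0.103/0.236/0.499/0 for the 2.5 mm probe), interpolates them to
30 points for offsets within 2 kHz of resonance (where coherent
oscillations demand a denser grid), and averages simulated intensities over
the grid.  `rf_profile_from_nutation()` recovers such distributions from
nutation decays by cosine transform (mean subtraction, Hann window,
fourfold zero padding, 2% noise-floor clipping -- the windowing choices are
ours; the mixture-recovery test pins them down).  A five-point
$\pm 0.5$ kHz averaging mode reproduces the simpler scheme used for
profile modelling.

## Fitting

`grid_search()` scores every node of a named parameter grid by the mean
absolute difference between measured and simulated intensities, pooled over
all (offset, $T$) points -- when several saturation times are fitted
jointly, all points enter one mean rather than being averaged per $T$
first.  The full objective surface is returned because the minima are
typically shallow; `correlation_diagnostic()` extracts the
$k_\mathrm{ex}^*(D)$ ridge that exposes the positive $D$--$k_\mathrm{ex}$
correlation (fast diffusion narrows the pattern, slow exchange widens it).
Ties break toward the smallest parameter values.  Experimental offsets are
matched to simulated ones by nearest neighbour within 50 Hz, else linear
interpolation.  Node simulations are cached across calls, which makes
repeated fits of noise replicates against one grid cheap.

## The synthetic-data generator

`make_fixture()` is the stand-in for experimental profiles: it simulates a
configured model and adds i.i.d. Gaussian noise (default
$\sigma = 0.01$, the order of the scatter visible in measured DMS
profiles), clipped below zero, with the seed recorded in the file header
and byte-identical output for identical inputs.  The default DMS-like
design mirrors the measured one: 25 kHz MAS, $\omega_{RF}/2\pi = 1.3$ kHz,
saturation times 3 and 20 ms, offsets spanning $\pm 60$ kHz.  What the
generator does *not* emulate: probe detuning drift (the reason measured
offsets are acquired in random order), temperature instability, finite
pulse effects and $T_2$ weighting during detection, and offset-correlated
noise.  Passing the recovery tests therefore shows that the estimator is
consistent and well-conditioned under the stated noise model, not that
real-data systematics are harmless.

## Numerical choices and edge cases

* All user-facing frequencies are Hz; everything internal is rad/s.  ZYZ
  Euler angles, active rotations, magic angle $\arccos(1/\sqrt 3)$.
* Positive offset means the carrier sits above the deuteron Larmor
  frequency; profiles are reported against $\Omega/2\pi$.
* $T = 0$ returns the thermal state unchanged; saturation times that are
  not integer rotor multiples use a partial-period propagator on the same
  step grid.
* Band integration refuses a dwell time whose spectral width cannot hold
  one rotor frequency.  Signed real-part integration is used (not
  magnitude): per-crystallite sideband amplitudes are phased, and only the
  signed areas add up to the exact Parseval total.
* The mono-exponential $R_\mathrm{CEST}$ fit leaves the amplitude free and
  flags decays whose relative fit rms exceeds 5% as non-exponential (fast
  relaxation pathways make decays strongly non-exponential, in which case
  profile fitting at selected $T$ is the right analysis).
* Profiles can undershoot zero slightly at $|\Omega| \lesssim$ 1--2 kHz for
  single crystallites (coherent nutation); powder and RF averaging restore
  $0 \le I/I_0 \le 1$ within $10^{-3}$ away from exact resonance.

## Known limitations

* Non-secular quadrupolar terms, chemical-shift anisotropy and dipolar
  couplings are outside the coherent engine; $T_1$ is phenomenological (or
  supplied by the three-site-jump module).
* Centre-band and all-bands DMS profiles agree to a mean difference of
  about 1.5% over the measured offset schedule, but differ by up to ~4%
  point-wise at the $n = 2$ rotary-resonance offsets ($\pm 50$ kHz at
  25 kHz MAS), where saturation is strongly orientation-selective.
* The fibril model is exercised at reduced scale (16--96 surface sites) in
  the tests; the full 192-site network is constructed by the same code and
  calibration but takes correspondingly longer per grid node.
* At spinning rates of a few kHz and below, 20 rotor steps limit absolute
  profile accuracy to the few-per-mille level; raise `n_rotor_steps` when
  that matters.

## Problem sizes used by the shipped checks

The test suite and the acceptance script use 16--100 powder orientations
for exchange profiles, 300 for the no-motion resonance-position scan, 200
polar nodes for $T_1$ averages, 96 surface sites for diffusion-spectrum
checks, and a 10-node flip-rate grid with 20 noise replicates for recovery
-- sizes at which each asserted quantity was verified to be converged
relative to its stated tolerance.
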