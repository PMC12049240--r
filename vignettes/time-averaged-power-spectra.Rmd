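---
title: "Time-averaged vibrational power spectra from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-averaged vibrational power spectra from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibspec)
```

## The problem

Classical molecular dynamics is the workhorse for computing vibrational
spectra of systems too large for quantum treatments: the Fourier transform
of the velocity autocorrelation function (VACF) of an MD run peaks at the
classical vibrational frequencies, which approximate the fundamentals
observed in IR spectroscopy.  The standard VACF spectrum of a polyatomic
molecule is, however, as crowded as the experiment itself — every mode
contributes to every Cartesian component — which makes assignment of
individual bands difficult.

`vibspec` implements a time-averaging formulation that solves both the
sign problem and the assignment problem at once.  For a scalar momentum
(or velocity, or dipole-component) series $p(t)$ sampled over a total time
$T$, the time-averaged autocorrelation

$$C(t) = \frac{1}{T}\int_0^T p(t_0)\,p(t_0+t)\,dt_0$$

has a Fourier transform that, when the $t_0$ integration limit is extended
past the end of the run (the added samples contribute nothing), collapses
to a manifestly positive-definite quantity:

$$I(\omega) \;=\; \frac{1}{2T}\,\bigl|\tilde p(\omega)\bigr|^2,
\qquad \tilde p(\omega) = \int_0^T p(t)\,e^{i\omega t}\,dt .$$

Peak maxima of $I(\omega)$ are the classical vibrational frequencies.
Applied per normal mode $j$, $I_j(\omega)$ contains only the signal of
mode $j$ and of the modes coupled to it, so a crowded band can be
decomposed mode by mode.

## From Cartesian dynamics to mode momenta

The mode basis comes from the standard harmonic analysis: the Hessian at
the potential minimum is mass-weighted, $H_{ij}/\sqrt{m_i m_j}$, and
diagonalized; the eigenvectors with nonzero eigenvalue form the columns of
an orthogonal matrix $C$ (3N − 6 of them for a nonlinear molecule,
3N − 5 for a linear one), ordered by ascending harmonic frequency
$\tilde\nu_j = \sqrt{\lambda_j}$.  Normal-mode positions and momenta follow
by the linear maps $Q = C^{\mathsf T} x$ and $P = C^{\mathsf T} v$ applied
to the mass-weighted coordinates.

Two points in this pipeline were genuinely open and are resolved as
follows:

* **Mass weighting of velocities.**  Since $C$ diagonalizes the
  *mass-weighted* Hessian, `project_to_modes()` multiplies each velocity
  component by $\sqrt{m}$ before applying $C^{\mathsf T}$.  This is what
  makes $p_j$ the conjugate momentum of the mass-weighted normal
  coordinate, and what makes the per-frame kinetic energy identity
  $\sum_j p_j^2/2 = \sum_i m_i v_i^2/2$ hold exactly for velocity fields
  inside the retained subspace (a property the test suite asserts at
  1e-10).  Uploads that are already mass-weighted should therefore be
  supplied as normal-mode momentum files, not as Cartesian velocities.
* **Eckart alignment.**  The equilibrium-geometry $C$ matrix is only
  approximately valid along the trajectory; a small amount of apparent
  rotation leaks into the low-frequency modes.  `eckart_align()` removes
  the mass-weighted center of mass and applies the mass-weighted
  least-squares (Kabsch) rotation onto the reference.  Alignment is **on**
  by default when positions are present and **off** for velocity-only
  sources (e.g. Tinker dumps), where no rotation can be fitted.  The
  high-frequency range is essentially unaffected either way; only
  low-frequency intensities change slightly.

Zero modes are removed **by count** (6, or 5 for linear molecules), taking
the eigenvalues of smallest magnitude, rather than by a numeric threshold:
force-field Hessians place the translational/rotational eigenvalues at
noise level but not at zero, and a threshold would be fragile.  If the
discarded block is not separated from the retained one by six orders of
magnitude a warning lists the smallest eigenvalues.  A retained negative
eigenvalue is an error (the geometry is a saddle point, not a minimum).
Within a degenerate eigenvalue block the eigenvector ordering is
backend-dependent; spectra are unaffected because they are computed per
retained mode and summed over selections, so this is documented rather
than "fixed".  For reproducibility across linear-algebra backends each
eigenvector's sign is chosen so its largest-magnitude component is
positive.

## Discrete conventions

The continuous identities above are made exact on the sampled grid by
fixing the discrete conventions once:

* transform: $\tilde p(\omega_k) = \Delta t \sum_n p_n e^{i\omega_k t_n}$
  on a grid $\omega_k = 2\pi k/(M\Delta t)$ zero-padded to
  $M = \texttt{pad\_factor}\times N$ points;
* normalization: $I(\omega_k) = |\tilde p(\omega_k)|^2/(2T)$ with
  $T = N\Delta t$ (the number of samples times the step — each sample
  "owns" one step of integration time).  With this choice the Parseval
  identity $\int I\,d\omega/2\pi = \langle p^2\rangle/2$ and the discrete
  Wiener–Khinchin equivalence between the squared-magnitude route and the
  Fourier transform of the biased autocorrelation
  $C_k = \frac1N\sum_{n} p_n p_{n+k}$ are *exact*, and the test suite
  holds them to 1e-8 and 1e-10 respectively.  Trajectory containers also
  carry the conventional duration $(N-1)\Delta t$ as metadata, but the
  spectral normalization uses $N\Delta t$.

The biased (1/N) autocorrelation is not a defect: it is precisely the
discrete form of the time average with the extended upper limit, and it is
what keeps $I(\omega)$ nonnegative bin by bin.

Defaults and the parameters that matter:

| parameter      | default | meaning |
|----------------|---------|---------|
| `pad_factor`   | 8       | zero-padding; peak localization is one padded bin, $1/(8N\Delta t)$ — about 7 cm⁻¹ for a 25,000 a.u. run |
| `taper`        | `"rect"`| no window; `"hann"` available for close-peak position work |
| `remove_mean`  | `TRUE`  | suppresses the $\omega = 0$ artifact from drift; switch off for Parseval checks |
| `freq_window`  | 0–4000 cm⁻¹ | reporting window; upper bound checked against Nyquist $1/(2\Delta t)$ |

All internal quantities are Hartree atomic units (bohr, atomic time,
electron masses); conversions happen once at the I/O boundary, and the
frequency axis is reported as wavenumbers $\tilde\nu = \omega/(2\pi c)$
in cm⁻¹.

## What the synthetic generators emulate

`generate_harmonic_trajectory()` stands in for a real MD engine.  It
evolves a set of modes — optionally coupled by a symmetric bilinear term —
**analytically** (exact cosine/sine solutions), so no integrator error
enters any test.  Initial conditions follow the quasi-classical
prescription used to launch production runs: each eigenmode receives its
harmonic zero-point energy $\omega_a/2$, with a uniformly random phase; a
single trajectory (not an ensemble) is generated, matching how such
spectra are computed in practice.  The mode space is embedded into the
Cartesian space of a fictitious molecule through a random orthonormal
completion orthogonal to the translations and rotations of a random
reference geometry, with element labels drawn from H/C/N/O so that the
mass table is exercised; this makes the Cartesian route, the projection
and the Eckart machinery all do real work in tests.

`generate_morse_trajectory()` supplies controlled anharmonicity: a 1D
Morse oscillator $V(x) = D_e(1-e^{-ax})^2$ integrated with an adaptive
high-order scheme (deSolve's `ode45`, rtol 5e-14) that conserves energy to
better than 1e-10 relative over production-length runs.  Its classical
frequency at energy $E$ is analytic, $\omega(E) = \omega_0\sqrt{1-E/D_e}$,
so the red shift of the spectral peak has a known truth value — the same
mechanism that separates harmonic from anharmonic band positions in real
molecules.

What these fixtures do **not** contain: rotation–vibration coupling,
force-field noise, thermostats, multi-dimensional anharmonic resonances,
or overtone/combination intensities.  A passing suite therefore
demonstrates the *spectral estimator and the projection algebra* are
correct, not that any particular force field reproduces experiment.

Frozen study conditions (chosen once, stated here as the package's own
choices): the single-mode fixture runs 2,500 steps of 10 a.u. — a 25,000
a.u. (~0.6 ps) trajectory, the scale of a typical short ab initio run —
giving a raw grid of ~55 cm⁻¹ and a padded grid of ~6.9 cm⁻¹.  The coupled
pair uses nominal 3,000/3,100 cm⁻¹ modes with a 3×10⁵ cm⁻² bilinear
coupling (eigenfrequencies ≈ 2,979/3,120 cm⁻¹).  Because the *positions*
of two nearby peaks are read off, that analysis uses a Hann taper and
5,000 steps: through a rectangular window the sidelobes of the stronger
line bias the weaker line's maximum by more than a padded bin, which is a
property of the window, not of the estimator.  The Morse fixture uses
$\omega_0 = 3{,}000$ cm⁻¹, $D_e = 0.18$ hartree and $m = 1837\,m_e$ —
a hydrogen-stretch-like oscillator.

## Degenerate and edge inputs

Constant-zero signals are legal and produce zero spectra.  A constant
nonzero velocity (a free drifter) produces a zero spectrum when mean
removal is on.  Flat spectra have no peaks; `find_peaks()` otherwise
returns all strict local maxima above a relative height threshold, always
including the global maximum, and `dominant_peak()` breaks exact intensity
ties toward the lower frequency for determinism.  Parsers reject
inconsistent atom/mode counts, non-numeric fields (with the line number),
and files with fewer than two frames; unknown element labels are an error
rather than a silent default, because masses feed the Hessian weighting.
Units are never inferred: the time step and the velocity units must be
declared, exactly as in the interactive tools this package's driver
mirrors.

## Known limitations

* Intensities are relative: temperature and field prefactors of absolute
  IR absorption are out of scope, as are quantum correction factors.
* The dipole-autocorrelation route (for selection rules) is supported only
  mechanically, through the generic scalar-signal interface.
* The equilibrium-geometry $C$ matrix applied along an anharmonic
  trajectory mixes a small amount of rotation into low-frequency modes
  even with Eckart alignment.
* Only the package's own plain-text dialects are read; binary MD formats
  (DCD/XTC/TRR) and electronic-structure outputs are not parsed.
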