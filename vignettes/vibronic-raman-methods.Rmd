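---
title: "Methods: nonadiabatic resonance Raman from LVC wavepacket dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonadiabatic resonance Raman from LVC wavepacket dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vibraman)
```

## The model and its assumptions

`vibraman` treats a molecule as a set of diabatic excited electronic
states sharing the harmonic potential of the electronic ground state.
In dimensionless ground-state normal coordinates $q_j$ (frequencies
$\omega_j$, energies in eV, $\hbar = 1$):

$$V_g = \sum_j \tfrac{\omega_j}{2} q_j^2, \qquad
  V_i = E_i + V_g + \sum_j \lambda_{ii,j}\, q_j, \qquad
  V_{ij} = \sum_j \lambda_{ij,j}\, q_j \;(i \ne j),$$

with the kinetic energy $\sum_j \tfrac{\omega_j}{2} p_j^2$. This is the
linear vibronic coupling (LVC) ansatz: every excited diabat is the
ground-state paraboloid rigidly tilted by a gradient (its minimum sits at
$q_j = -\lambda_j/\omega_j$, Huang–Rhys factor
$S_j = \lambda_j^2 / 2\omega_j^2$), and interstate couplings are linear
in the coordinates. Because the diabatic states vary slowly with
geometry, the transition dipoles $\mu^{gi}$ are taken constant
(Franck–Condon approximation). With all couplings zero the model reduces
to the vertical-gradient (VG) displaced-oscillator model.

What the ansatz excludes — frequency changes, Duschinsky rotation,
anharmonicity — is excluded here too; see *Limitations*.

## From wavepackets to Raman intensities

The transition polarizability for the fundamental of mode $f$ is, in its
sum-over-states form, a sum over all vibronic eigenstates with a common
phenomenological lifetime width $\gamma$ in the denominator,
$E_{kn} - i\gamma - E_{g0} - \omega_I$. The package evaluates the
equivalent time-dependent form:

1. for each bright state $m$, propagate
   $|\Psi(0)\rangle = |d_m; \mathbf{0}\rangle$ exactly in a truncated
   harmonic product basis;
2. read off the cross-correlations
   $C^{km}_f(t) = \langle d_k; \mathbf{0}{+}1_f| e^{-iHt} |d_m;
   \mathbf{0}\rangle$ as basis-element amplitudes;
3. compose
   $\chi^f_{\rho\sigma}(t) = \sum_{k,m} \mu^{gk}_\rho \mu^{gm}_\sigma
   C^{km}_f(t)$;
4. half-Fourier transform with Lorentzian damping,
   $\alpha^{f0}_{\rho\sigma}(\omega_I) = i\int_0^\infty
   e^{i(\omega_I + E_{g0})t} e^{-\gamma t} \chi^f_{\rho\sigma}(t)\,dt$;
5. form the rotational invariants and the intensity
   $I^{f0} = \omega_I\,\omega_S^3\,(45|a|^2 + 7g^2 + 5d^2)/45$,
   $\omega_S = \omega_I - \omega_f$.

Both routes are implemented; `sum_over_states_alpha()` is kept as an
independent oracle and the equivalence of the two is asserted to 1e-3
(in practice ~1e-6) in the acceptance suite.

The same machinery yields absorption by placing the ground vibrational
state on both sides of the bracket ($C^{km}_0$), with a time-domain
Gaussian $G(t) = e^{-t^2\sigma^2/2}$, $\sigma = \mathrm{HWHM}/\sqrt{2\ln
2}$, instead of the Lorentzian damping.

### The three protocols

* **`lvc`** — full propagation on the coupled surfaces: interstate
  couplings *and* interference between quasi-resonant states.
* **`vg_int`** — couplings zeroed; only $k = m$ survives, but the
  per-state tensors are summed *before* the invariants, keeping the
  interference of the amplitudes.
* **`vg_sum`** — couplings zeroed and intensities computed one state at
  a time, then added: no interference at all.

Comparing `vg_sum` to `vg_int` isolates interference; comparing `vg_int`
to `lvc` isolates genuine nonadiabatic coupling. The suite asserts the
collapse identities: `lvc` $\equiv$ `vg_int` when every coupling is zero,
and `vg_int` $\equiv$ `vg_sum` with a single bright state.

At the Franck–Condon level the uncoupled correlation functions have 0 K
closed forms,

$$C_0(t) = e^{-iE_vt} \prod_j \exp\!\big[S_j\,(e^{-i\omega_j t} - 1 +
i\omega_j t)\big], \qquad
C_f(t) = \frac{\delta_f}{\sqrt 2}\,(e^{-i\omega_f t} - 1)\, C_0(t),$$

used by default for the VG protocols (`vg_route = "analytic"`). The sign
of $C_f$ is convention-dependent; it was fixed **positive** by requiring
agreement with the exact propagator under the pinned
$q_{min} = -\lambda/\omega$ convention (verified to 1.5e-14 on a
one-mode probe before freezing). Herzberg–Teller dipoles
$\mu(q) = \mu_0 + \mu' q$ are supported for single-state calculations via
explicit ladder-operator application (`apply_dipole_operator()`); the
analytic HT correlation functions are left as future work because the
numerical route is exact at desk scale and is oracle-checked to 1e-4.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `gamma_ev` | eV | 0.04 (alt. 0.12) | 0.04 is a typical homogeneous line width; 0.12 additionally mimics inhomogeneous broadening. Lorentzian HWHM along $\omega_I$. |
| `dt` | $\hbar$/eV | 0.05 (0.033 fs) | Nyquist margin for a ~10 eV spectral span; trapezoid error per pole scales as $(\Delta\,dt)^2/12$. |
| `tmax` | $\hbar$/eV | max(300 fs, $10\hbar/\gamma$) | bounds the damped-tail truncation by $e^{-\gamma T} \lesssim 10^{-8}$; a warning fires if $e^{-\gamma T} \ge 10^{-6}$. |
| `n_tot` | quanta | 10 | total-quanta cap of the product basis; see the convergence discussion below. |
| `omega_step_ev` | eV | 0.005 | excitation-grid resolution, well under $\gamma$. |
| abs `hwhm_ev` | eV | 0.04 / 0.12 | Gaussian broadening of the absorption sticks. |
| section HWHM | cm$^{-1}$ | 15 | visualization convolution along the Raman shift. |
| `scale` | — | 1 (CLI: 0.96) | post hoc Raman-axis scaling; the common empirical correction for harmonic-frequency overestimation. Positions only, never the dynamics. |

## Numerical choices

* **Propagation** is by cached symmetric eigendecomposition up to
  dimension 4000 (exact to machine precision; norm drift < 1e-14 in the
  suite) and by a Lanczos/Krylov exponential action above, with a
  per-step error estimate and recursive step halving (target 1e-9,
  cross-checked against the eigen route to 1e-8).
* **Basis truncation.** The basis holds every occupation with
  $\sum_j n_j \le N_{tot}$ (optional per-mode caps), replicated per
  electronic state, in a pinned state-major, graded-lexicographic order.
  A displaced state occupies a Poisson distribution with mean $\sum_j
  S_j$, but the *propagating* wavepacket transiently reaches ~4x that
  (coherent-state breathing), which sets the practical $N_{tot}$: for the
  three-mode reference fixture ($\sum S = 1.0$) the correlation error is
  1.6e-4 at $N_{tot} = 14$ and 3.8e-7 at 18 — hence $N_{tot} = 18$ where
  1e-6 agreement is asserted. `convergence_check()` automates the
  $N_{tot} \to N_{tot}+2$ comparison and flags changes above 1e-3.
* **Quadrature** is trapezoidal on the stored grid; with the default
  `dt` and window the dual-route deviation is ~1e-6. Halving `dt` moves
  the pole transform by < 1e-6 (asserted).
* **Ladder truncation** in the Herzberg–Teller operator: amplitude
  raised out of the basis is dropped, *accumulated and reported* in the
  result notes and the CLI manifest — never silently ignored.
* **Tie-breaks and degenerate inputs.** Off-grid section requests snap
  to the nearest excitation grid point with a warning (interpolating
  complex amplitudes would scramble phases). `vrr_intensity()` rejects
  $\omega_I \le \omega_f$ (non-Stokes). Absorption intensities are
  clipped at zero, removing quadrature noise at the 1e-13 level so the
  positivity contract holds exactly. Zero-dipole states participate in
  the bra sums but contribute nothing, so "dark" states need no special
  casing.
* **Hermiticity** is structural: the same double is written to both
  triangles, so `identical(H, t(H))` holds bitwise.

## The synthetic-model generator

`random_model()` draws frequencies (400–1800 cm$^{-1}$), vertical
energies (4–6.5 eV), gradient/coupling magnitudes (0–0.12 eV) and dipole
components (0–1) uniformly with random signs, using R's Mersenne–Twister
stream in a documented order, so fixtures are reproducible cross-platform
from a single seed. The ranges put Huang–Rhys factors and coupling/gap
ratios in the regime typical of rigid UV chromophores: vibronic
progressions a few members long, couplings strong enough to mix
near-degenerate states.

What the generator (and the hand-built fixtures) emulate: displaced
multi-mode progressions, near-degenerate bright states, symmetry-
forbidden fundamentals activated by coupling, interference between
overlapping bands. What they do **not** emulate: mode mixing and
frequency changes between states, dense >30-mode spectral congestion,
finite-temperature hot bands, solvent broadening beyond the single
phenomenological $\gamma$. A green suite therefore establishes the
correctness of the LVC pipeline, not the realism of any particular
molecular parametrization.

## Design decisions taken where the design was open

* The $-i\gamma$ enters the sum-over-states denominator additively in
  eV, state-independent — the simplest reading consistent with a common
  phenomenological lifetime, and the one that makes the TD and SOS
  routes agree exactly.
* Rotational invariants use the standard complex-tensor forms
  ($|a|^2$, $g^2 = \tfrac32\sum|\alpha^S_{\rho\sigma} -
  a\delta_{\rho\sigma}|^2$, $d^2 = \tfrac32\sum|\alpha^A|^2$) and the
  intensity prefactor $\omega_I\omega_S^3$ with a global constant 1
  (arbitrary units). Only relative intensities are meaningful; the
  choice is recorded in the output metadata, and every symmetry/protocol
  test is normalization-independent.
* The interference acceptance demonstration runs at $\gamma = 0.12$ eV:
  on a minimal one-mode two-state model the lower state's vibronic
  progression plants poles inside the inter-band valley, and only the
  larger of the two stated damping values smooths them the way spectral
  congestion would in a many-mode molecule. At $\gamma = 0.04$ eV the
  Int < Sum ordering still holds between the progression lines but not
  pointwise across the whole valley.
* The optional HDF5 correlation cache was dropped (no HDF5 R bindings in
  the supported stack); all artifacts are TSV/JSON text.

## Limitations

Exact propagation scales combinatorially: ~8 modes is the practical
ceiling, which is the point — the package is a desk-scale reference
implementation of the nonadiabatic vRR protocol, not a production
propagator for 39-mode systems (that regime belongs to ML-MCTDH-class
engines). No VH/AH models, overtones, combination bands, depolarization
ratios, absolute cross sections, finite temperature, or two-step
homogeneous/inhomogeneous broadening.
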