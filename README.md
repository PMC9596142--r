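# vibraman

Nonadiabatic **vibrational resonance Raman (vRR)** and absorption spectra
for molecules with several close-lying, possibly coupled excited
electronic states, described by **linear vibronic coupling (LVC)** models.

When the excitation energy is near-resonant with more than one electronic
transition, the transition polarizability is a coherent sum over all
quasi-resonant vibronic states: the contributions of different electronic
states *interfere*, and interstate couplings redistribute intensity in
ways a single-state treatment cannot capture. `vibraman` computes these
spectra exactly (at desk scale) by wavepacket propagation on the coupled
diabatic surfaces, and provides the limiting protocols needed to
disentangle interference from genuine nonadiabatic coupling.

## Model and method

The LVC Hamiltonian in dimensionless ground-state normal coordinates
`q` (energies in eV, `hbar = 1`):

    H = K + V,   K = sum_j (omega_j / 2) p_j^2
    V_g  = sum_j (omega_j / 2) q_j^2                      (ground state)
    V_i  = E_i + V_g + sum_j lambda_ii,j q_j              (diabatic state i)
    V_ij = sum_j lambda_ij,j q_j                          (coupling, i != j)

Transition dipoles `mu^{gi}` are constant vectors (Franck–Condon
approximation, natural in a diabatic basis). For each bright state `m`, a
wavepacket `|Psi(0)> = |d_m; 0>` is propagated exactly in a truncated
harmonic product basis, and cross-correlation functions

    C^{km}_f(t) = < d_k; 0 + 1_f | exp(-i H t) | d_m; 0 >

are assembled into the tensor correlation function
`chi_{rho sigma}^f(t) = sum_{k,m} mu_rho^{gk} mu_sigma^{gm} C^{km}_f(t)`.
Its damped half-Fourier transform is the transition polarizability

    alpha_{rho sigma}^{f0}(omega_I)
      = i int_0^Inf dt e^{i (omega_I + E_g0) t} e^{-gamma t}
        chi_{rho sigma}^f(t),

and the vRR intensity of fundamental `f` follows from the rotational
invariants of the complex tensor:

    I^{f0}(omega_I) = omega_I (omega_I - omega_f)^3
                      (45 |a|^2 + 7 g^2 + 5 d^2) / 45 .

Three protocols are exposed:

| protocol | interstate couplings | interference between states |
|----------|----------------------|-----------------------------|
| `lvc`    | included             | included                    |
| `vg_int` | zeroed               | included (tensors summed before invariants) |
| `vg_sum` | zeroed               | discarded (intensities summed) |

With all couplings zero the LVC model collapses onto the vertical-gradient
(VG) displaced-oscillator model, for which closed-form 0 K correlation
functions are also implemented (`vg_autocorrelation_fc()`,
`vg_cross_correlation_fc()`) and cross-checked against the propagator.
A brute-force sum-over-states route (`sum_over_states_alpha()`) serves as
an independent oracle for the whole pipeline, and Herzberg–Teller dipoles
`mu(q) = mu0 + mu' q` are available for single-state calculations.

## Worked example

A two-mode / two-state conical-intersection-style model: one totally
symmetric tuning mode (1400 cm-1, displaced in both states) and one
coupling mode (900 cm-1) carrying the single interstate coupling
component (0.08 eV):

```r
library(vibraman)

model <- fixture_conical(coupling = 0.08)
model
#> LVC model: 2 mode(s), 2 state(s), 1 coupling vector(s)
#>   zero-point energy E_g0 = 0.142582 eV
#>   state S1         A'   E = 4.8000 eV  |mu| = 1.0000
#>   state S2         A'   E = 5.2000 eV  |mu| = 0.6325
round(huang_rhys(model, "S1"), 3)
#> [1] 0.4 0.0

s <- spectrum_settings(gamma_ev = 0.04, n_tot = 12, omega_step_ev = 0.01)

ab <- absorption_spectrum(model, "lvc", hwhm_ev = 0.04, settings = s)
round(abs_peak(ab), 4)
#> [1] 4.7263          # 0-0 line of S1, red of E_1 by the reorganization energy

spec <- compute_vrr(model, "lvc", settings = s, scale = 0.96)
spec
#> vRR spectrum (lvc): 2 modes, omega_I in [3.800, 6.200] eV (241 points),
#> gamma = 0.04 eV
#>   Raman axis scaled by 0.96

sec <- spectrum_section(spec, 5.0, conv_hwhm_cm1 = 15)
sec$raman_shift_cm1[which.max(sec$intensity)]
#> [1] 1344            # the scaled tuning-mode fundamental (1400 * 0.96)

vgi <- compute_vrr(model, "vg_int", settings = s, scale = 0.96)
max(abs(spec$intensity - vgi$intensity)) / max(vgi$intensity)
#> [1] 0.147           # nonadiabatic coupling changes intensities by ~15%
```

The absorption maximum sits at the 0-0 vibronic line (4.726 eV, not at the
vertical energy 4.8 eV); the 1D section at 5.0 eV excitation is dominated
by the displaced tuning mode; and switching the interstate coupling off
(`vg_int`) changes the Raman intensities by ~15% — the purely
nonadiabatic part of the signal.

## Command line

```sh
vibraman fixtures --seed 1 --out models/
vibraman vrr --model models/conical_2mode.json --protocol lvc \
         --gamma-ev 0.04 --excitation-nm 233,250 --scale 0.96 --out run/
vibraman abs --model models/conical_2mode.json --abs-hwhm-ev 0.04,0.12 --out run/
vibraman profile --model models/conical_2mode.json --mode 1 --out run/
vibraman validate --model models/conical_2mode.json
vibraman convergence --model models/conical_2mode.json --basis-ntot 10
```

(`vibraman` is the wrapper installed at `inst/exec/vibraman`; equivalently
call `vibraman::vibraman_cli(c("vrr", ...))` from R.) Flags taking several
values accept comma-separated lists. Any flag can instead be given in a
YAML file via `--config`; explicit flags win. Every run writes a
`manifest.json` recording all parameters and any convergence or
truncation warnings, so the run is reproducible bit for bit.

### Model files

JSON, one model per file (`schema_version: "1"`): frequencies in cm-1,
energies/gradients in eV, unknown keys rejected. `write_fixture_set()`
or the `fixtures` subcommand emit canonical examples, including a
seeded random-model generator (`random_model()`, Mersenne-Twister with a
documented draw order: frequencies; per state energy, gradient, dipole;
per pair keep-flag and coupling vector).

## Limitations

Desk-scale exact propagation (roughly <= 8 modes); no Duschinsky rotation
or frequency changes (VH/AH models), no overtones/combination bands, no
finite temperature, no solvent model, single phenomenological damping.
See the methods vignette (`vignettes/vibronic-raman-methods.Rmd`) for the
full numerical and design discussion.
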