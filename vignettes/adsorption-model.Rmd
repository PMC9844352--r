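---
title: "Modelling adsorption-limited electrochemical serotonin detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adsorption-limited electrochemical serotonin detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensokin)
```

## The model

Serotonin (5-HT) detection at carbon-surface electrodes is adsorption
limited: molecules must first bind to the electrode before oxidation
contributes current. `sensokin` couples two classical descriptions of that
process.

**Langmuir binding.** The electrode is modelled as a finite molar pool of
one-to-one binding sites, `ELD_tot` (mol), rather than an area. At
equilibrium the adsorbed amount follows the Langmuir isotherm

$$\mathrm{bound}_{eq} = \frac{C \cdot ELD}{K_D + C},$$

and during an accumulation period at constant applied concentration $C$ the
bound amount approaches equilibrium exponentially with lumped rate
$\lambda = C\,k_{on} + k_{off}$:

$$\mathrm{bound}(t_{acc}) = \mathrm{bound}_{eq}\,
  \bigl(1 - e^{-\lambda t_{acc}}\bigr).$$

When the analyte is removed ($C = 0$) the bound pool decays as
$e^{-k_{off} t}$. The two regimes are kept separate, exactly as defined; no
general solver for time-varying $C(t)$ is provided.

**Adsorption-limited current.** The anodic peak current of a surface-bound
redox species is proportional to the adsorbed amount and the scan rate:

$$I_{pa} = g\,\frac{n^2 F^2}{4RT}\,\nu\,\mathrm{bound},$$

with $n$ electrons per molecule, Faraday constant $F$, gas constant $R$,
temperature $T$, scan rate $\nu$, and a dimensionless gain $g$. Surface area
and coverage enter only through their product, which is the bound amount in
moles, so neither is represented separately.

Because the concentration-to-current map is strictly increasing at fixed
$t_{acc}$, the chain inverts uniquely:
`concentration_from_current()` recovers $C$ from a measured $I_{pa}$ by
bracketed root finding on $\log_{10} C$ (relative tolerance ~1e-9), refusing
currents at or above the all-sites-occupied ceiling.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `K_D` | M | 7e-7 | reference affinity of 5-HT for a CNT-coated Au electrode |
| `k_on` | M⁻¹ s⁻¹ | 130 | reference association rate |
| `k_off` | s⁻¹ | 9.1e-5 | reference dissociation rate; `k_off/k_on` equals `K_D` to all printed digits |
| `ELD_tot` | mol | 5e-11 | total site pool of the reference electrode |
| `n` | – | 2 | electrons per 5-HT oxidation (convention; also the value that reproduces the published sensitivity table) |
| `temperature` | K | 298.15 | benchtop PBS experiments; never reported explicitly, so the standard laboratory value is assumed |
| `scan_rate` | V/s | user-set (0.4 typical) | sweep speed; current is linear in it |
| `gain` | – | 1 | bare physical conversion. The empirical 1.8× factor reported for fouling/titration fits must be set explicitly — it is never applied silently, because its physical origin is unresolved |

All storage and computation are SI (M, mol, s, V, A); only human-facing
reports use nM or µA.

## Fitting

`fit_isotherm()` estimates `(K_D, ELD_tot)` by unweighted nonlinear least
squares of the isotherm on the bound (mol) scale; current inputs are first
converted to moles through the gain-corrected conversion factor. Replicates
enter as individual points — consistent with one fresh electrode per point.
The response is rescaled to order 1 internally (a mol-scale sum of squares
of ~1e-22 defeats absolute convergence tests); starting values are
`K_D = median(C)` and `ELD_tot = 1.05 * max(bound)`, with positivity
enforced by bounded (`port`) optimisation and a direct-search fallback.

`fit_kinetics()` fits the exponential approach at a single fixed
concentration with the equilibrium level supplied externally. Such data
identify only the lumped rate $\lambda$; therefore the default
*constrained* mode imposes $k_{off} = K_D\,k_{on}$ (one free rate), which is
also how the printed rate pair is mutually consistent with the printed
$K_D$. A *lumped* mode reports $\lambda$ alone with an explicit caveat, and
requesting both rates unconstrained from single-concentration data is an
error rather than a silently ill-posed fit.

## Fouling

Repeated oxidation polymerises some of the detected analyte onto the
surface. The model treats this as a per-cycle fractional loss of sites: each
cycle binds `bound_i` from the currently available pool `eld_i` (isotherm
with `eld_i`, then the exponential-approach factor), and

$$eld_{i+1} = eld_i - a\,\mathrm{bound}_i,$$

with fouling fraction $a \in [0, 1]$. Each cycle's adsorption starts from
zero bound — no carry-over or inter-cycle desorption — which is a stated
simplification of the underlying chemistry. Consequences tested as
invariants: `eld` is non-increasing, the cumulative fouled amount equals
$a \sum_i \mathrm{bound}_i$ to machine precision, and $a = 0$ reproduces the
fouling-free forward model identically.

`fit_fouling()` excludes the first six cycles by default
(`fit_start_cycle = 7`): real series often show an initial signal *rise*
that the model deliberately does not describe. The fouling fraction is
grid-seeded across $[0.05, 0.95]$ and refined by bounded scalar
minimisation; the gain is fixed (1.8 is the conventional choice for this
electrode family) unless joint estimation is requested. The synthetic
generator `gen_fouling()` can add a phenomenological linear rise ramp over
the first cycles to exercise exactly this exclusion.

## CV trace processing

`lowpass_smooth()` is a zero-phase forward–backward pass of a second-order
Butterworth low-pass with odd-reflection padding; the per-pass corner is
pre-warped so the *combined* response has half power at the nominal cutoff.
The published processing recipe names only a 3 Hz cutoff at 2 kHz sampling,
not a topology — the forward–backward biquad is this package's choice, made
for zero phase lag at the peak.

`extract_peak()` works on the ascending (anodic) segment only: an OLS line
over a pre-peak baseline window (default 0.10–0.25 V) is extrapolated across
the peak window (default 0.25–0.45 V, bracketing the ~0.33 V serotonin
oxidation potential) and subtracted; the peak is the maximum of the
corrected current, ties broken toward lower potential. Adding any straight
line to a trace leaves the result unchanged to machine precision. A
non-positive corrected maximum yields a no-peak *result*, not an error; a
maximum on the window edge sets a boundary flag.

**A deliberate deviation.** The synthetic test peak (Gaussian, sd 0.03 V,
swept at 0.4 V/s) has a spectral width of ~2.1 Hz — overlapping a 3 Hz
cutoff. *Any* filter with half power at 3 Hz attenuates that peak by ~12%;
this is integrable analytically and is pinned by a test, and higher filter
order does not change it. Recovery-accuracy tests therefore smooth at a
30 Hz cutoff, where the passband genuinely covers the peak band while still
suppressing ~97% of broadband noise amplitude. The 3 Hz default remains
appropriate for real voltammograms, whose peaks are broader and where a
consistent attenuation is absorbed into calibration.

## Synthetic data: what it does and does not establish

Generators produce every input the package consumes: equilibrium isotherms,
fixed-concentration time courses, fouling series, and raw traces, each with
its ground truth embedded in the output and deterministic under an integer
seed (R's Mersenne-Twister). Default noise is multiplicative Gaussian with
a 5% coefficient of variation, matching the reported replicate relative
standard deviation of fresh electrodes (<10%, rising past 15% as electrodes
foul).

What the generators do **not** emulate: electrode-to-electrode variability
from CNT drop-casting (scatter is i.i.d. here, not electrode-correlated),
the chemistry behind the initial signal rise (only a phenomenological ramp
is offered), non-Gaussian peak shapes, and any diffusion-limited signal
component. A green recovery test therefore establishes that the estimators
are consistent and well-conditioned under the model's own assumptions — not
that the model captures every mechanism of a real electrode.

## Numerical choices

- Root-finding bracket for inversion: `[1e-15, 1e-1]` M, expanded ×10 on
  demand; exhaustion is an error, never a clamp.
- NLS convergence 1e-12 on the scaled problem, max 1000 iterations, with a
  Nelder–Mead fallback on log-parameters.
- `linear_range()` is exhaustive over contiguous windows (grids are ~10
  points, so O(n²) OLS fits are trivial) and deterministic: widest window
  wins, ties prefer the lower low end. With the default 10% tolerance and
  the default decade grid at 30 min accumulation it selects a *lower*
  window than the visually chosen published one — both windows are 5 grid
  points wide and the tie-break is by construction; the published
  sensitivities are reproduced by evaluating over the published windows.
- The equilibrium sensitivity row is reproduced with a fit window extending
  to 1 µM; the printed range's nominal 0.5 µM high end gives a ~40% larger
  slope on this grid, so the wider window is treated as the published fit
  window (both behaviours are reachable through the API).

## Known limitations

- Single-analyte model: no interference panel, no multi-peak deconvolution.
- No Randles–Ševčík (diffusion-limited) branch.
- Jacobian-based standard errors only; no bootstrap or Bayesian uncertainty.
- The fouling model is phenomenological; its fraction `a` is not a rate
  constant and the 1.8× gain is an unexplained empirical factor.
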