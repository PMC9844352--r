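# sensokin

Modelling toolkit for **adsorption-limited electrochemical detection of
serotonin (5-HT)**, for electrochemists and biosensor developers who need to
predict, calibrate and de-bias voltammetric 5-HT measurements.

Electrochemical 5-HT detection is adsorption limited: molecules bind to a
finite pool of electrode sites before oxidising, so the anodic peak current
depends on accumulation time, and repeated measurements foul the surface and
erode sensitivity. `sensokin` couples Langmuir binding kinetics to the
adsorption-limited peak-current equation:

```
bound_eq(C)    = C · ELD_tot / (K_D + C)                      (Langmuir isotherm)
bound(t_acc)   = bound_eq · (1 − exp(−(C·k_on + k_off)·t_acc)) (approach to equilibrium)
Ipa            = g · n²F²/(4RT) · ν · bound                    (peak current)
eld_{i+1}      = eld_i − a · bound_i                           (per-cycle fouling)
```

with dissociation constant `K_D = k_off/k_on` (M), total site pool `ELD_tot`
(mol), scan rate `ν` (V/s), `n` electrons per molecule, gain `g`, and
fouling fraction `a ∈ [0,1]`.

The package provides:

- **forward model and inverses** — adsorbed moles, peak current, and unique
  concentration recovery from a measured current (`equilibrium_bound`,
  `adsorption_at_time`, `desorption_at_time`, `bound_to_current`,
  `concentration_from_current`);
- **parameter fitting** — `(K_D, ELD_tot)` from equilibrium isotherms,
  `(k_on, k_off)` from fixed-concentration time courses with an explicit
  identifiability treatment (`fit_isotherm`, `fit_kinetics`);
- **fouling** — simulation and fitting of per-cycle site loss, titration
  prediction with accumulated fouling (`simulate_series`, `fit_fouling`,
  `predict_titration`);
- **characterization** — sensitivity curves, algorithmic linear range,
  3σ/10σ LOD/LOQ, linear calibration of unknowns (`sensitivity_curve`,
  `linear_range`, `lod_loq`, `calibrate_linear`, `quantify`);
- **CV processing** — zero-phase 3 Hz low-pass smoothing and
  baseline-subtracted anodic peak extraction (`lowpass_smooth`,
  `extract_peak`);
- **seeded synthetic data** for every input (`gen_isotherm`,
  `gen_timecourse`, `gen_fouling`, `gen_trace`);
- a **CLI** (`sensokin_main()`, wrapper in `inst/cli/sensokin`) with
  `fit`, `characterize`, `fouling`, `peaks`, `quantify` and `synth`
  subcommands.

## Worked example

```r
library(sensokin)

params <- serotonin_cnt_params()   # K_D = 7e-7 M, k_on = 130, k_off = 9.1e-5, ELD_tot = 5e-11
config <- electrochem_config(n = 2, scan_rate = 0.4, temperature = 298.15)

# Model-predicted sensitivity at 30 min accumulation over 0.1-2.5 uM
curve <- sensitivity_curve(1800, params, config)
sensitivity(curve, c(0.1e-6, 2.5e-6))
#> [1] 12.087        # A/M; the published model value is 11.8 A/M (within 2.5%)

# Detection limits from blank noise (3*sigma = 501 nA) and measured sensitivity
ll <- lod_loq(sigma_blank = 501e-9/3, sensitivity = 17.8)
c(lod_nM = ll$lod * 1e9, loq_nM = ll$loq * 1e9)
#>  lod_nM  loq_nM
#>    28.1    93.8  # 5-HT quantifiable down to ~100 nM at 30 min accumulation

# Forward prediction and exact inversion
ipa <- bound_to_current(adsorption_at_time(5e-7, 1800, params), config)
ipa
#> [1] 7.66e-06      # A, predicted peak current for 500 nM at 30 min
concentration_from_current(ipa, 1800, params, config)
#> [1] 5e-07         # M, recovered exactly

# Fouling: fit the site-loss fraction to a noisy 50-cycle series
cfg18 <- electrochem_config(scan_rate = 0.4, gain = 1.8)
obs <- gen_fouling(params, cfg18, a = 0.25, noise = noise_spec(level = 0.02, seed = 1))
fit_fouling(obs, params, cfg18)
#> Fouling-model fit
#>   a (fouling fraction): 0.2492
#>   gain                : 1.8
#>   fit from cycle      : 7
#>   R^2                 : 0.9968
```

The fouling fit recovers the true fraction (0.25) from 2%-noise data while
skipping the initial-rise cycles that the model deliberately does not
describe.

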