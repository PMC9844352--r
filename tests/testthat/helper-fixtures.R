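# Shared fixtures: the reference 5-HT / Au-CNT parameter set and the standard
# measurement configuration (2-electron oxidation, 0.4 V/s, 298.15 K).

ref_params <- function() serotonin_cnt_params()

ref_config <- function(gain = 1.0) {
  electrochem_config(n = 2, scan_rate = 0.4, temperature = 298.15, gain = gain)
}

# lambda = C*k_on + k_off for the reference parameters.
ref_lambda <- function(C) C * 130 + 9.1e-5
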