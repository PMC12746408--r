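# Default calibration for the Gd-DTPA / agarose / soy lecithin hydrogel
# system at 3 T and 20 degC. Relaxivities and ADC coefficients are specific
# to the characterized product sources; re-characterize other products with
# fit_relaxivity() / fit_adc_model().
relaxivity:
  units: s^-1 per mM (Gd-DTPA) or per % wt/vol (lecithin, agarose)
  r1_gd: 3.78
  r2_gd: 4.24
  r1_lec: 0.10
  r2_lec: 0.69
  r2_agar: 6.62
adc_model:
  units: amplitudes in 10^-3 mm^2/s, decay constants in (% wt/vol)^-1
  a_fast: 0.36
  k_fast: 2.79
  a_slow: 1.60
  k_slow: 0.13
solvent:
  units: times in ms, temperature in degC, field in Tesla
  t1w_ms: 3000
  t2w_ms: 2000
  temperature: 20
  field: 3
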