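linkers:
- modulator_name: 4-ClPhSO2
  t_half_ref_h: 9.0
  ph_ref: 7.4
  temp_ref_c: 37.0
  t_rg_h: 1000.0
- modulator_name: PhSO2
  t_half_ref_h: 27.0
  ph_ref: 7.4
  temp_ref_c: 37.0
  t_rg_h: 1000.0
- modulator_name: 4-MePhSO2
  t_half_ref_h: 40.0
  ph_ref: 7.4
  temp_ref_c: 37.0
  t_rg_h: 1000.0
- modulator_name: MeSO2
  t_half_ref_h: 160.0
  ph_ref: 7.4
  temp_ref_c: 37.0
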