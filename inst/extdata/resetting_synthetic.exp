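experiment control_no_factors_2iL bound=20
  input LIF=on CH=on PD=on
  initial Oct4=low Sox2=low Sall4=low Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=low Tcf3=low
  expect step 0..20 never Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high
experiment episc_2iL bound=20
  input LIF=on CH=on PD=on
  initial Oct4=high Sox2=high Sall4=high Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=high Tcf3=high
  expect step 20..20 stable Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high
experiment episc_2i_only bound=20
  input LIF=off CH=on PD=on
  initial Oct4=high Sox2=high Sall4=high Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=high Tcf3=high
  expect step 0..20 never Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high
experiment episc_2i_tfcp2l1_forced bound=20
  input LIF=off CH=on PD=on
  force Tfcp2l1 high from=0 to=inf
  initial Oct4=high Sox2=high Sall4=high Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=high Tcf3=high
  expect step 19..20 held Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high
experiment nanog_ko_episc_2iL bound=20
  input LIF=on CH=on PD=on
  force Nanog low from=0 to=inf
  initial Oct4=high Sox2=high Sall4=high Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=high Tcf3=high
  expect step 0..20 never Oct4=high Sox2=high Sall4=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high
experiment nanog_ko_episc_LIF_CH bound=20
  input LIF=on CH=on PD=off
  force Nanog low from=0 to=inf
  initial Oct4=high Sox2=high Sall4=high Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=high Tcf3=high
  expect step 0..20 reached Oct4=high Esrrb=high Klf2=high Tfcp2l1=high Klf4=high Stat3=high
experiment episc_2iL_sall4_forced bound=20
  input LIF=on CH=on PD=on
  force Sall4 high from=0 to=inf
  initial Oct4=high Sox2=high Sall4=high Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=high Tcf3=high
experiment episc_2iL_ref bound=20
  input LIF=on CH=on PD=on
  initial Oct4=high Sox2=high Sall4=high Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=high Tcf3=high
comparative sall4_not_faster_than_control treated=episc_2iL_sall4_forced reference=episc_2iL_ref
  target Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high
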