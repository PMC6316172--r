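# Synthetic reconstruction of maintenance-era constraints (naive state
# self-renewal in 2i+LIF and in 2i alone; no spontaneous network
# activation from the empty state). Not the original supplementary
# constraint set.
experiment esc_2iL_maintenance bound=20
  input LIF=on CH=on PD=on
  initial Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high MEKERK=low Tcf3=low
  expect step 20..20 stable Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high
experiment esc_2i_maintenance bound=20
  input LIF=off CH=on PD=on
  initial Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high MEKERK=low Tcf3=low
  expect step 20..20 stable Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high
experiment esc_collapse_from_empty bound=20
  input LIF=on CH=on PD=on
  initial Oct4=low Sox2=low Sall4=low Nanog=low Esrrb=low Klf2=low Klf4=low Tfcp2l1=low Gbx2=low Tbx3=low Stat3=low MEKERK=low Tcf3=low
  expect step 0..20 never Oct4=high Sox2=high Sall4=high Nanog=high Esrrb=high Klf2=high Klf4=high Tfcp2l1=high Gbx2=high Tbx3=high Stat3=high
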