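# Synthetic reconstruction of the naive-pluripotency interaction network.
# Signal axes (LIF -> Stat3, CH -| Tcf3, PD -| MEKERK) and the local
# topology of Tfcp2l1 (definite activators Stat3, Esrrb; optional activators
# Tbx3, Gbx2, Klf2, Klf4; inhibitor Tcf3) and Esrrb (definite activators
# Sall4, Nanog, Tfcp2l1; definite inhibitor Tcf3, optional inhibitor
# MEKERK) follow published descriptions; the remaining optional
# interactions are invented so that the bundled resetting constraints are
# satisfiable. MEKERK and Tcf3 carry definite self-activations so they
# latch their culture-determined activity when their inhibitory input is
# absent.
component LIF signal
component CH signal
component PD signal
component MEKERK gene conditions=0-8
component Tcf3 gene conditions=0-8
component Stat3 gene conditions=0-8
component Oct4 gene conditions=0-8
component Sox2 gene conditions=0-8
component Sall4 gene conditions=0-8
component Nanog gene conditions=0-8
component Esrrb gene conditions=0-8
component Klf2 gene conditions=0-8
component Klf4 gene conditions=0-8
component Tfcp2l1 gene conditions=0-8
component Gbx2 gene conditions=0-8
component Tbx3 gene conditions=0-8
LIF -> Stat3 definite
CH -| Tcf3 definite
PD -| MEKERK definite
MEKERK -> MEKERK definite
Tcf3 -> Tcf3 definite
Stat3 -> Tfcp2l1 definite
Esrrb -> Tfcp2l1 definite
Tcf3 -| Tfcp2l1 definite
Sall4 -> Esrrb definite
Nanog -> Esrrb definite
Tfcp2l1 -> Esrrb definite
Tcf3 -| Esrrb definite
MEKERK -| Esrrb optional
Tbx3 -> Tfcp2l1 optional
Gbx2 -> Tfcp2l1 optional
Klf2 -> Tfcp2l1 optional
Klf4 -> Tfcp2l1 optional
Sox2 -> Oct4 optional
Sall4 -> Oct4 optional
Oct4 -> Sox2 optional
Sall4 -> Sox2 optional
Oct4 -> Sall4 optional
Sox2 -> Sall4 optional
Tfcp2l1 -> Nanog optional
Klf2 -> Nanog optional
Oct4 -> Klf2 optional
Sall4 -> Klf2 optional
Stat3 -> Klf4 optional
Esrrb -> Klf4 optional
Klf2 -> Klf4 optional
Stat3 -> Gbx2 optional
Klf2 -> Gbx2 optional
Nanog -> Tbx3 optional
Esrrb -> Tbx3 optional
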