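# Reference ion mobilities of the hydronium water-cluster series
# (H3O+)(H2O)n, the reactant ions of positive-mode drift-tube IMS.
# All mobilities in cm^2 V^-1 s^-1 (drift gas N2/air, ambient conditions).
# reference: particle-tracing / reaction-simulation literature values that
#   reproduce measured reactant-ion-peak flight-time distributions.
# mulliken / mk / hirshfeld: trajectory-method mobilities computed from
#   DFT-optimized cluster geometries with per-atom partial charges from the
#   Mulliken, Merz-Kollman-Singh and Hirshfeld schemes respectively.
# Printed MUE row of the source table (percent, 2 decimals):
#   mulliken 11.29, mk 10.45, hirshfeld 11.68
species,reference,mulliken,mk,hirshfeld
n=0,3.57,3.16,3.00,3.23
n=1,2.76,2.71,2.65,2.75
n=2,2.35,2.50,2.45,2.55
n=3,1.97,2.38,2.26,2.37
n=4,1.88,2.18,2.13,2.25
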