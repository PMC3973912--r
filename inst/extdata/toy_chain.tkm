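# toy thermokinetic model: linear chain glc -> g6p -> pyr -> ac
# with explicit ATP stoichiometry and a conserved adenylate pool

[context]
T = 310.15
p = 101325
pH = 7
I = 0.25
a_h2o = 1
c_ref = 1

[compartments]
c: phi = 0
e: phi = 0

[metabolites]
glc_e: dfg0 = 0, z = 0, compartment = e, carbon = 6, external
g6p: dfg0 = 13.5, z = 0, compartment = c, carbon = 6
pyr: dfg0 = -79, z = 0, compartment = c, carbon = 3
ac_e: dfg0 = 13, z = 0, compartment = e, carbon = 2, external
co2: dfg0 = -157.5, z = 0, compartment = e, carbon = 1, external, gas
atp: dfg0 = 30.5, z = 0, compartment = c
adp: dfg0 = 0, z = 0, compartment = c

[reactions]
HEX: atp + glc_e <-> adp + g6p | k = 6
GLY: 3 adp + g6p <-> 3 atp + 2 pyr | k = 13
ACK: adp + pyr <-> ac_e + atp + co2 | k = 6
ATPASE: atp <-> adp | k = 4

[moieties]
pool adenylate: members = atp adp, base = adp, total = 3

[chemostat]
D = 0.2
v_cell = 0.002
c_in.glc_e = 10
k_out.co2 = 60

[start]
glc_e = 2.5
g6p = 0.0109
pyr = 1.25
ac_e = 15
co2 = 0.05
atp = 0.6
adp = 2.4

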