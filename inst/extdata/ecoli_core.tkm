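# core thermokinetic model of E. coli central carbon and energy
# metabolism across the aerobiosis scale (packaged fixture)

[context]
T = 310.15
p = 101325
pH = 7
I = 0.25
a_h2o = 1
c_ref = 1

[compartments]
c: phi = -0.15
e: phi = 0

[metabolites]
glc_e: dfg0 = 0, z = 0, compartment = e, carbon = 6, external
g6p: dfg0 = 10.5, z = 0, compartment = c, carbon = 6
f6p: dfg0 = 13, z = 0, compartment = c, carbon = 6
fdp: dfg0 = 27.5, z = 0, compartment = c, carbon = 6
dhap: dfg0 = 22, z = 0, compartment = c, carbon = 3
g3p: dfg0 = 27.5, z = 0, compartment = c, carbon = 3
pg3: dfg0 = -74.8, z = 0, compartment = c, carbon = 3
pep: dfg0 = -73.8, z = 0, compartment = c, carbon = 3
pyr: dfg0 = -132.3, z = 0, compartment = c, carbon = 3
accoa: dfg0 = -69.6, z = 0, compartment = c, carbon = 2
coa: dfg0 = 0, z = 0, compartment = c
actp: dfg0 = -49.6, z = 0, compartment = c, carbon = 2
cit: dfg0 = -366, z = 0, compartment = c, carbon = 6
icit: dfg0 = -357.5, z = 0, compartment = c, carbon = 6
akg: dfg0 = -265.8, z = 0, compartment = c, carbon = 5
succoa: dfg0 = -197.6, z = 0, compartment = c, carbon = 4
succ: dfg0 = -230.1, z = 0, compartment = c, carbon = 4
fum: dfg0 = -224.1, z = 0, compartment = c, carbon = 4
mal: dfg0 = -227.5, z = 0, compartment = c, carbon = 4
oaa: dfg0 = -261.3, z = 0, compartment = c, carbon = 4
atp: dfg0 = 30.5, z = 0, compartment = c
adp: dfg0 = 0, z = 0, compartment = c
amp: dfg0 = -30.5, z = 0, compartment = c
nad: dfg0 = 0, z = 0, compartment = c
nadh: dfg0 = 61.8, z = 0, compartment = c
nadp: dfg0 = 0, z = 0, compartment = c
nadph: dfg0 = 60.8, z = 0, compartment = c
q8: dfg0 = 0, z = 0, compartment = c
q8h2: dfg0 = -19.3, z = 0, compartment = c
mqn8: dfg0 = 0, z = 0, compartment = c
mql8: dfg0 = 14.3, z = 0, compartment = c
o2: dfg0 = 316.6, z = 0, compartment = e, external, gas
co2: dfg0 = -157.5, z = 0, compartment = e, carbon = 1, external, gas
ac_e: dfg0 = -104.1, z = 0, compartment = e, carbon = 2, external
etoh_e: dfg0 = 29, z = 0, compartment = e, carbon = 2, external
for_e: dfg0 = -78.7, z = 0, compartment = e, carbon = 1, external
succ_e: dfg0 = -230.1, z = 0, compartment = e, carbon = 4, external
h_c: dfg0 = 0, z = 0, compartment = c, clamped
pmf: dfg0 = 0, z = 0, compartment = e

[reactions]
PGI: g6p = f6p
FBA: fdp = dhap + g3p
TPI: dhap = g3p
ENO: pg3 = pep
ACONT: cit = icit
FUM: fum = mal
ADK: amp + atp = 2 adp
PTAr: accoa = actp + coa
GLCpts: glc_e + pep <-> g6p + pyr | k = 9, enzyme = pts
GAPD: adp + g3p + nad <-> atp + nadh + pg3 | k = 12, enzyme = gapa
PFK: atp + f6p <-> adp + fdp | k = 7, enzyme = pfk, activator = adp @ 0.0005
PYK: adp + pep <-> atp + pyr | k = 8, enzyme = pyk
PDH: coa + nad + pyr <-> accoa + co2 + nadh | k = 10, enzyme = pdh
PFL: coa + pyr <-> accoa + for_e | k = 7, enzyme = pfl
ACKr: actp + adp <-> ac_e + atp | k = 8, enzyme = ack
ADHEr: accoa + 2 nadh <-> coa + etoh_e + 2 nad | k = 10, enzyme = adhe
ACS: ac_e + atp + coa <-> accoa + amp | k = 9, enzyme = acs
CS: accoa + oaa <-> cit + coa | k = 10, enzyme = cs
ICDHyr: icit + nadp <-> akg + co2 + nadph | k = 10, enzyme = icd
AKGDH: akg + coa + nad <-> co2 + nadh + succoa | k = 10, enzyme = suca
SUCOAS: adp + succoa <-> atp + coa + succ | k = 8, enzyme = sucoas
SUCDH: q8 + succ <-> fum + q8h2 | k = 7, enzyme = sdh
FRD: fum + mql8 <-> mqn8 + succ | k = 7, enzyme = frd
MDH: mal + nad <-> nadh + oaa | k = 5, enzyme = mdh
PPC: co2 + pep <-> oaa | k = 8, enzyme = ppc
THD: nadh + nadp <-> nad + nadph | k = 8, enzyme = thd
NADHIq8: 4 h_c + nadh + q8 <-> nad + 4 pmf + q8h2 | k = 9, enzyme = nuo
NADHImq: 2 h_c + mqn8 + nadh <-> mql8 + nad + 2 pmf | k = 7, enzyme = nuo
NADHII: nadh + q8 <-> nad + q8h2 | k = 8, enzyme = ndh
CYTBO3: 8 h_c + o2 + 2 q8h2 <-> 8 pmf + 2 q8 | k = 15, enzyme = cyo
CYTBD: 4 h_c + o2 + 2 q8h2 <-> 4 pmf + 2 q8 | k = 15, enzyme = cyd
ATPS: adp + 4 pmf <-> atp + 4 h_c | k = -2, enzyme = atps
LEAK: pmf <-> h_c | k = -2
SUCCt: succ <-> succ_e | k = 4

[transcription_factors]
fnr: signal = "o2", k_half = 0.003, n = -1.5
arca: signal = "(q8h2 / (q8 + q8h2) + mql8 / (mqn8 + mql8)) / 2", k_half = 0.55, n = 3
crp: signal = "pep / pyr", k_half = 0.3, n = 2
frur: signal = "fdp", k_half = 2, n = -2

[genes]
pts: basal = 0.2
gapa: basal = 0.2
pfk: basal = 0.2
pyk: basal = 0.2, reg = frur -1
pdh: basal = 0.2, reg = arca -3
pfl: basal = 0.2, reg = fnr +1; arca +1
ack: basal = 0.2
acs: basal = 0.2, reg = crp +2
adhe: basal = 0.2, reg = fnr +1; arca +1
cs: basal = 0.2, reg = arca -1
icd: basal = 0.2, reg = arca -1
suca: basal = 0.2, reg = arca -1; fnr -2
sucoas: basal = 0.2
sdh: basal = 0.2, reg = arca -1; fnr -2; crp +1
frd: basal = 0.2, reg = fnr +2
mdh: basal = 0.2, reg = arca -1
ppc: basal = 0.2
thd: basal = 0.2
nuo: basal = 0.2, reg = arca -1; fnr -1
ndh: basal = 0.2, reg = fnr -1
cyo: basal = 0.2, reg = arca -2; fnr -1
cyd: basal = 0.2, reg = arca +2; fnr -1
atps: basal = 0.2

[biomass]
x_carbon = 40
k_a = 0.05
k_b = 22.8
k_lo = 1
k_hi = 2.5
m_max = 45
m_lo = 1
m_hi = 30
nu.g6p = 1.46
nu.g3p = 0.13
nu.pg3 = 1.5
nu.pep = 0.52
nu.pyr = 2.83
nu.accoa = 3.75
nu.akg = 1.08
nu.oaa = 1.79
nu.atp = 41.3
nu.nadph = 18.2
nu.nad = 3.5

[moieties]
pool adenylate: members = atp adp amp, base = amp, total = 5
pool nicotinamide: members = nad nadh, base = nad, total = 2
pool nicotinamide_p: members = nadp nadph, base = nadp, total = 0.25
pool coenzyme_a: members = coa accoa succoa, base = coa, total = 1.5
quinone ubiquinone: members = q8 q8h2, base = q8, intercept = 0.15, slope = 0.0035
quinone menaquinone: members = mqn8 mql8, base = mqn8, intercept = 0.6, slope = -0.004
dead_pool_ox = 0.2

[chemostat]
D = 0.2
v_cell = 0.002
c_in.glc_e = 20
k_out.co2 = 20
k_out.o2 = 60
o2_id = o2

[start]
glc_e = 0.05526
g6p = 0.3778
f6p = 0.1433
fdp = 2.221
dhap = 1.923
g3p = 0.2278
pg3 = 0.3663
pep = 0.2486
pyr = 3.044
accoa = 0.7254
coa = 0.766
actp = 0.4056
cit = 0.03499
icit = 0.001296
akg = 0.4892
succoa = 0.00865
succ = 1.301
fum = 0.1113
mal = 0.4159
oaa = 0.000122
atp = 4.333
adp = 0.587
amp = 0.07952
nad = 0.5556
nadh = 1.444
nadp = 0.06885
nadph = 0.1812
q8 = 0.0000002719
q8h2 = 0.15
mqn8 = 0.1235
mql8 = 0.4765
o2 = 0.0000000000000001415
co2 = 0.05685
ac_e = 13.77
etoh_e = 19.92
for_e = 30.1
succ_e = 1.217
pmf = 27550
c_X = 0.2904

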