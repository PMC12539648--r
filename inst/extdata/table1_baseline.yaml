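# Baseline material and G&R parameters for the non-dilated Marfan-like murine
# ascending aorta (membrane/ring reduction; angles from the axial direction).
a0_mm: 0.809
h0_mm: 0.041
phi_e: 0.354
phi_m: 0.345
phi_c: 0.311
beta_theta: 0.012
beta_z: 0.012
beta_d: 0.976
c1m_kPa: 1.26
c2m: 30.0
c1c_kPa: 665.6
c2c: 2.14
ce_kPa: 42.03
G_theta_e: 1.74
G_z_e: 2.24
Gm: 1.19
Gc: 1.25
alpha0_deg: 51.1
delta: 0.0
xi: 0.0
eta: 0.9
Ktauw_over_Ksigma: 0.9
gamma: 0.2
# Energy convention for the amorphous elastin matrix: (ce/2)(I1 - 3) when true.
neo_hookean_half: true
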