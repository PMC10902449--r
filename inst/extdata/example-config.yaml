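grid_width: 40
grid_height: 40
dx: 20.0
duration: 30.0
dt: 0.0416666666666666643537
record_every: 1.0
field_solve_every: 1
seed: 7
p_D: 0.0050000000000000001041
p_delta: 0.6999999999999999555911
p_n: 0.0005000000000000000104
D_O: 1820.0
D_g: 500.0
D_H: 1080.0
O_0: 0.0555999999999999966471
G_0: 5.0
pH_0: 7.4000000000000003552714
V_O: 0.0120000000000000002498
k_O: 0.0050000000000000001041
k_G: 0.0400000000000000008327
k_H: 0.0002500000000000000052
A_d: 0.3499999999999999777955
A_q: 0.8000000000000000444089
p_H_min: 6.0999999999999996447286
p_H_norm: 6.6500000000000003552714
delta_H: 0.0030000000000000000625
p_G_max: 50.0
delta_G: 0.1499999999999999944489
tau_min: 0.9499999999999999555911
p_P_min: 5.0
p_P_norm: 2.7000000000000001776357
delta_P: 0.1000000000000000055511
sigma_min: 80.0
sigma_mean: 150.0
nu_mean: 20.0
p_ang: 0.9000000000000000222045
T_M: 1.0
tau_T: 1.0
alpha_T: 0.0100000000000000002082
beta_T: 10.0
d_e: 0.042000000000000002609
H_e: 6.5999999999999996447286
sigma_e: 4.0
H_p: 6.5999999999999996447286
sigma_p: 6.0
L_i: 65.3499999999999943156581
L_0: 21.7800000000000011368684
L_g: -16.6700000000000017053026
inactivation_permanent: yes
D_A: 100.0
gamma_A: 0.5
gamma_P: 0.0010000000000000000208
K_A: 0.1000000000000000055511
k_on: 100.0
proton_yield: 0.0050000000000000001041
proton_clearance: 0.0020000000000000000416
proton_clearance_peri: 0.0500000000000000027756
peri_radius: 2
g_floor: 0.0001000000000000000048
T_w: 1.0
normal_regrowth: 0.1000000000000000055511
init_tumor_radius: 5
treatment:
  anti_pdl1:
    'on': no
    start: 100.0
    end: 160.0
    source: 1.0
  buffer:
    'on': no
    start: 100.0
    end: 160.0
    B: 0.8000000000000000444089
solver:
  tolerance: 3.0000000000000000760026e-06
  max_iterations: 20000
  tracking_sweeps: 40
  omega: 1.8200000000000000621725
  boundary: zero-flux

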