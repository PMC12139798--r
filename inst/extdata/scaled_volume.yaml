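kBT: 0.0041
seg_len: 0.14
k_ext: 100.0
Lp_actin: 9.0
d_actin: 0.007
eta: 0.086
drag_scale: 30.0
dt: 0.0034042
C_A: 10.0
actin_scale: 0.3
R_X: 0.08
R_C: 0.08
R_M: 0.04
monomers_per_um: 370.0
mean_fil_len: .na
F_sev: 40.0
k_on: 30.0
k_off0: 0.05
r0_bond: 0.0003
F_stall: 5.7
k_walk0: 40.0
step_size: 0.007
heads_per_side: 8.0
motor_k_off0: 0.05
motor_backbone: 0.42
k_backbone: 300.0
k_motor: 100.0
motor_rest: 0.03
k_acp: 100.0
acp_rest: 0.07
k_anchor: 100.0
anchor_rest: 0.05
anchor_r0_bond: 0.0003
anchor_drag: 0.2
capture_range: 0.14
max_arms_per_seg: 4.0
R_mem: 1.5
mesh_subdiv: 3.0
k_area: 100.0
k_bend_mem: 0.05
k_vol: 4000.0
k_mem_rep: 50.0
excess_area: 0.04
k_rep: 100.0
rep_range_scale: 3.0
t_assembly: 4.0
t_activate: 4.0
t_end: 28.0
n_kinetics: 10.0
measure_every: 0.5
snapshot_every: 2.0
bleb_cutoff: 0.8
bleb_height: 0.12
shell_thickness: 0.4
weak_threshold: 1.05
seed: 1
region: volume
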