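kBT: 0.0041
seg_len: 0.14
k_ext: 100.0
Lp_actin: 9.0
d_actin: 0.007
eta: 0.086
drag_scale: 1.0
dt: 9.4561939e-05
C_A: 10.0
actin_scale: 1.0
R_X: 0.08
R_C: 0.08
R_M: 0.01
monomers_per_um: 370.0
mean_fil_len: .na
F_sev: 300.0
k_on: 30.0
k_off0: 0.5
r0_bond: 0.001
F_stall: 5.7
k_walk0: 20.0
step_size: 0.007
heads_per_side: 8.0
motor_k_off0: 0.1
motor_backbone: 0.42
k_backbone: 300.0
k_motor: 100.0
motor_rest: 0.03
k_acp: 100.0
acp_rest: 0.07
k_anchor: 100.0
anchor_rest: 0.05
anchor_r0_bond: 0.001
anchor_drag: 0.2
capture_range: 0.14
max_arms_per_seg: 4.0
R_mem: 4.0
mesh_subdiv: 4.0
k_area: 120.0
k_bend_mem: 0.1
k_vol: 10000.0
k_mem_rep: 50.0
excess_area: 0.04
k_rep: 100.0
rep_range_scale: 3.0
t_assembly: 50.0
t_activate: 50.0
t_end: 300.0
n_kinetics: 10.0
measure_every: 0.5
snapshot_every: 5.0
bleb_cutoff: 0.8
bleb_height: 0.15
shell_thickness: 0.4
weak_threshold: 1.05
seed: 1
region: shell
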