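# Reference parameter set of the lumen-morphogenesis simulator
# (low-density matrix). Units: eta Pa.s; T_ini/T_pol/dt_exo hours;
# forces pN; radii um; dt_mech/dt_bio minutes; t_sim days.
eta: 20
F_lim: 0.07
T_ini: 30
T_pol: 100
F_bottom: 0.42
F_top: 1.17
a_max: 0.6
b: 0.1
n_tc: 5
dt_exo: 5
R_p: 2
F_rep_cc: 4.80
F_adh_cc: 24
F_rep_pp: 4.80
F_adh_pp: 24
F_rep_cp: 0.60
lambda: 7
dt_mech: 0.01
dt_bio: 6
t_sim: 7
seed: 42
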