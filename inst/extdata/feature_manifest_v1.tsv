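name	group
comp_A_w5	composition
comp_C_w5	composition
comp_D_w5	composition
comp_E_w5	composition
comp_F_w5	composition
comp_G_w5	composition
comp_H_w5	composition
comp_I_w5	composition
comp_K_w5	composition
comp_L_w5	composition
comp_M_w5	composition
comp_N_w5	composition
comp_P_w5	composition
comp_Q_w5	composition
comp_R_w5	composition
comp_S_w5	composition
comp_T_w5	composition
comp_V_w5	composition
comp_W_w5	composition
comp_Y_w5	composition
comp_A_w11	composition
comp_C_w11	composition
comp_D_w11	composition
comp_E_w11	composition
comp_F_w11	composition
comp_G_w11	composition
comp_H_w11	composition
comp_I_w11	composition
comp_K_w11	composition
comp_L_w11	composition
comp_M_w11	composition
comp_N_w11	composition
comp_P_w11	composition
comp_Q_w11	composition
comp_R_w11	composition
comp_S_w11	composition
comp_T_w11	composition
comp_V_w11	composition
comp_W_w11	composition
comp_Y_w11	composition
comp_A_w21	composition
comp_C_w21	composition
comp_D_w21	composition
comp_E_w21	composition
comp_F_w21	composition
comp_G_w21	composition
comp_H_w21	composition
comp_I_w21	composition
comp_K_w21	composition
comp_L_w21	composition
comp_M_w21	composition
comp_N_w21	composition
comp_P_w21	composition
comp_Q_w21	composition
comp_R_w21	composition
comp_S_w21	composition
comp_T_w21	composition
comp_V_w21	composition
comp_W_w21	composition
comp_Y_w21	composition
comp_A_global	composition
comp_C_global	composition
comp_D_global	composition
comp_E_global	composition
comp_F_global	composition
comp_G_global	composition
comp_H_global	composition
comp_I_global	composition
comp_K_global	composition
comp_L_global	composition
comp_M_global	composition
comp_N_global	composition
comp_P_global	composition
comp_Q_global	composition
comp_R_global	composition
comp_S_global	composition
comp_T_global	composition
comp_V_global	composition
comp_W_global	composition
comp_Y_global	composition
frac_disorder_promoting_w5	composition
frac_order_promoting_w5	composition
frac_aromatic_w5	composition
frac_disorder_promoting_w11	composition
frac_order_promoting_w11	composition
frac_aromatic_w11	composition
frac_disorder_promoting_w21	composition
frac_order_promoting_w21	composition
frac_aromatic_w21	composition
entropy_w5	physchem
entropy_w11	physchem
entropy_w21	physchem
net_charge_w5	physchem
hydropathy_kd_w5	physchem
isoelectric_point_w5	physchem
flexibility_w5	physchem
net_charge_w11	physchem
hydropathy_kd_w11	physchem
isoelectric_point_w11	physchem
flexibility_w11	physchem
net_charge_w21	physchem
hydropathy_kd_w21	physchem
isoelectric_point_w21	physchem
flexibility_w21	physchem
pos_charge_run	physchem
neg_charge_run	physchem
rel_position	physchem
terminal_distance	physchem
log_length	physchem
cf_helix_w5	structure
cf_sheet_w5	structure
cf_turn_w5	structure
beta_agg_w5	structure
cf_helix_w11	structure
cf_sheet_w11	structure
cf_turn_w11	structure
beta_agg_w11	structure
cf_helix_w21	structure
cf_sheet_w21	structure
cf_turn_w21	structure
beta_agg_w21	structure
hydrophobic_cluster_len	structure
hydrophobic_cluster_dist	structure
hydrophobic_cluster_density_w5	structure
hydrophobic_cluster_density_w11	structure
hydrophobic_cluster_density_w21	structure
tandem_repeat	pattern
tandem_repeat_copies	pattern
slim_motif_count	pattern
low_complexity	pattern
profile_A	evolution
profile_C	evolution
profile_D	evolution
profile_E	evolution
profile_F	evolution
profile_G	evolution
profile_H	evolution
profile_I	evolution
profile_K	evolution
profile_L	evolution
profile_M	evolution
profile_N	evolution
profile_P	evolution
profile_Q	evolution
profile_R	evolution
profile_S	evolution
profile_T	evolution
profile_V	evolution
profile_W	evolution
profile_Y	evolution
profile_entropy	evolution
gap_fraction	evolution
query_agreement	evolution
n_eff	evolution
profile_entropy_w5	evolution
profile_entropy_w11	evolution
hclass_conservation	evolution
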