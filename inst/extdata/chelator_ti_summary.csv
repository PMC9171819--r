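metal,dg_exp_edta_kj_mol,dg_exp_nta_kj_mol,dg_sim_default_edta_kj_mol,dg_sim_zero_edta_kj_mol,dg_extrap_zero_edta_kj_mol,dg_sim_default_nta_kj_mol,dg_sim_zero_nta_kj_mol,m_o_edta_kj_mol_per_c4,m_o_nta_kj_mol_per_c4,m_n_edta_kj_mol_per_c4,m_n_nta_kj_mol_per_c4
Ca2+,-60.8,-37.5,-56.0,-41.3,-24.0,-32.7,-17.6,-0.593,-0.442,-0.177,-0.081
Mg2+,-50.1,-30.6,-88.1,-37.6,-21.8,-84.9,-52.5,-1.028,-0.842,-0.124,0.077
Y3+,-103.2,-65.5,-156.0,-81.2,-82.6,-148.9,-107.1,-0.752,-0.691,-0.058,0.008
La3+,-87.6,-59.1,-123.3,-85.0,-79.0,-115.4,-86.7,-0.632,-0.491,-0.056,-0.028
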