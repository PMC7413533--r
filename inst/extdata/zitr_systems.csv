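system,zinc_sites,dna_bound,water_molecules,total_atoms,pdb_id,pme_grid_angstrom
Zn_apo-ZitR,none,no,26812,85260,5YI1,108
Zn_apo-ZitR-DNA,none,yes,16482,71854,5YI3,96
Zn_mono-ZitR,site1,no,26435,84127,5YHY,108
Zn_mono-ZitR-DNA,site1,yes,16482,55240,5YI3,96
Zn_di-ZitR,sites1+2,no,21951,70685,5YHX,100
Zn_di-ZitR-DNA,sites1+2,yes,15664,52804,5YI2,90
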