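#!/usr/bin/env Rscript
# Dual-boost acceleration parameters for the six simulation systems of the
# zinc-regulator study registry (inst/extdata/zitr_systems.csv).
#
# The thresholds depend on conventional-MD energy averages that only exist
# once the solvated systems have been run; here the averages are set to
# zero, so the table reports the size-dependent terms: alpha_P and the
# offsets added to the averages. The protein dimer contributes 2 x 147
# residues; the DNA-bound systems add the duplex, whose residue count is
# not part of the registry, so alpha_D is reported for the protein-only
# systems.

library(allodyn)

dir.create("results", showWarnings = FALSE)
systems <- read.csv(system.file("extdata", "zitr_systems.csv",
                                package = "allodyn"))
protein_residues <- 2L * 147L

rows <- lapply(seq_len(nrow(systems)), function(k) {
  sys <- systems[k, ]
  p <- dual_boost_parameters(0, 0, n_atoms = sys$total_atoms,
                             n_residues = protein_residues)
  data.frame(system = sys$system, pdb_id = sys$pdb_id,
             total_atoms = sys$total_atoms,
             alpha_p = p$alpha_p,
             e_thresh_p_offset = p$e_thresh_p,
             alpha_d_protein_only = if (sys$dna_bound == "no") p$alpha_d else NA,
             e_thresh_d_offset_protein_only =
               if (sys$dna_bound == "no") p$e_thresh_d else NA)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/amd_parameters.csv", row.names = FALSE)

cat("Dual-boost parameters (kcal/mol), zero cMD averages:\n")
print(tab, row.names = FALSE)
cat("\nLargest system (", tab$system[1], "):",
    "alpha_P =", tab$alpha_p[1],
    "- the total-potential boost scale grows with 0.16 kcal/mol per atom;",
    "the dihedral boost uses 4 kcal/mol per residue.\n")
cat("Wrote results/amd_parameters.csv\n")
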