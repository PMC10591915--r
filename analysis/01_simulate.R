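#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# a screening plate, displacement titrations for the assayed compounds,
# apo/holo crystallographic ensembles, apo/holo H/D-exchange spectra and
# a nine-system trajectory study. All files land under results/data/.

suppressPackageStartupMessages(library(crbpflex))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42L

# Screening plate: 384 wells, 2% fluorescence noise
plate <- simulate_plate(384, config = generator_config(seed = seed))
write_plate_csv(plate, file.path(out, "plate.csv"))
cat(sprintf("plate: %d wells, %d true binders\n", nrow(plate),
            sum(plate$true_class == "binder", na.rm = TRUE)))

# Titrations: the six confirmed inhibitors (uM) and the positive control
panel <- c(inh1 = 9.0e-6, inh2 = 7.1e-6, inh3 = 8.3e-6, inh4 = 9.5e-6,
           inh5 = 10.6e-6, inh6 = 10.7e-6)
for (nm in names(panel)) {
  s <- simulate_titration(panel[[nm]],
                          generator_config(seed = seed + match(nm, names(panel))))
  write_titration_csv(s, file.path(out, paste0("titration_", nm, ".csv")))
}
abn <- simulate_titration(67e-9,
                          generator_config(seed = seed + 10L,
                                           concentration_grid = titration_grid(1e-6)))
write_titration_csv(abn, file.path(out, "titration_abnCBD.csv"))
cat("titrations: 6 inhibitors (0-10 uM) + abn-CBD (0-1 uM), 3 replicates each\n")

# Crystallographic ensembles: portal flexibility reduced 3-fold in holo
apo <- simulate_ensemble(12, apo_flexibility_profile(),
                         generator_config(seed = seed + 20L),
                         structure_id = "apo")
holo <- simulate_ensemble(12, holo_flexibility_profile(),
                          generator_config(seed = seed + 21L),
                          structure_id = "holo")
write_ensemble_pdb(apo, file.path(out, "ensemble_apo.pdb"))
write_ensemble_pdb(holo, file.path(out, "ensemble_holo.pdb"))
cat("ensembles: 12 models each, apo and holo\n")

# H/D exchange: same peptide map for both states
seqc <- synthetic_sequence(133)
writeLines(seqc, file.path(out, "sequence.txt"))
hx_a <- simulate_hdx(seqc, apo_protection_profile(133),
                     generator_config(seed = seed + 30L))
hx_h <- simulate_hdx(seqc, holo_protection_profile(133),
                     generator_config(seed = seed + 31L),
                     peptides = hx_a$peptides)
write_hdx_spectra_csv(hx_a$spectra, file.path(out, "hdx_apo.csv"))
write_hdx_spectra_csv(hx_h$spectra, file.path(out, "hdx_holo.csv"))
utils::write.csv(hx_a$peptides, file.path(out, "hdx_peptides.csv"),
                 row.names = FALSE)
cat(sprintf("HDX: %d peptides x timepoints 1/2/5/10 min, apo + holo\n",
            nrow(hx_a$peptides)))

# Trajectory study: 9 systems x 2 replicates, ligand/portal coupling 0.9
study <- simulate_md_study(n_systems = 9, coupling_r2 = 0.9,
                           config = generator_config(seed = seed + 40L))
for (i in seq_along(study$trajectories)) {
  for (tr in study$trajectories[[i]]) {
    write_trajectory_frames(tr, file.path(
      out, sprintf("traj_%s_rep%d.trj", tr$system, tr$replicate)))
  }
}
utils::write.csv(study$systems, file.path(out, "systems.csv"),
                 row.names = FALSE)
cat(sprintf("trajectories: 9 systems x 2 replicates x %d frames\n",
            study$n_frames))
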