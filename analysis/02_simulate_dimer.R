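#!/usr/bin/env Rscript
# Build the coarse-grained two-chain dimer and run the paired unboosted /
# boosted Langevin simulations that every later analysis stage consumes.
# Writes fixture bundles (topology PDB, DCD trajectory, region YAML,
# ground-truth JSON) under results/dimer/.
#
# Two regimes are simulated:
#   deep:     barrier 4 kcal/mol - a slow two-state switch where plain
#             dynamics stay trapped and the dual-boost mathematics shows
#             its effect (well-crossing enhancement);
#   crossing: barrier 1.2 kcal/mol - an equilibrating regime for landscape
#             and correlation analyses.

library(allodyn)

seed <- 2024L
out <- "results/dimer"

deep <- build_dimer_model()   # barrier 4, wells 24/32 A
cross <- build_dimer_model(doublewell_spec = list(d1 = 24, d2 = 32,
                                                  barrier = 1.2, delta_g = 0))

runs <- list(
  deep_unboosted = list(model = deep, boost = NULL,
                        n_steps = 200000L, dt = 0.002),
  deep_boosted = list(model = deep, boost = list(e_thresh = 5, alpha = 1),
                      n_steps = 200000L, dt = 0.002),
  crossing = list(model = cross, boost = NULL,
                  n_steps = 150000L, dt = 0.004))

summary <- NULL
for (nm in names(runs)) {
  r <- runs[[nm]]
  tr <- simulate_dimer(r$model, n_steps = r$n_steps, dt = r$dt, seed = seed,
                       stride = 20L, boost = r$boost)
  write_fixture(r$model, tr, file.path(out, nm))
  d <- tr$observables$centroid_distance
  dw <- r$model$doublewell
  summary <- rbind(summary, data.frame(
    run = nm, frames = n_frames(tr),
    crossings = count_well_crossings(d, dw$d1, dw$d2),
    fraction_closed = mean(d < (dw$d1 + dw$d2) / 2),
    mean_boost_kcal = mean(tr$observables$delta_v)))
}
write.csv(summary, "results/dimer_runs.csv", row.names = FALSE)
cat("Simulated", nrow(summary), "trajectories:\n")
print(summary, row.names = FALSE)
cat("\nThe boosted deep-well run crosses between wells",
    summary$crossings[2], "time(s) where the unboosted run crosses",
    summary$crossings[1], "time(s): the boost flattens the barrier",
    "without moving the well positions.\n")
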