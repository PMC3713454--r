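#!/usr/bin/env Rscript
# Generate the synthetic study systems: a straight and a Her2-like bent arm,
# closed- and open-interface dimers, and a closed-to-open pseudo-trajectory.
# Everything downstream (02-06) runs off these files.

suppressMessages(library(ectodimer))

seed <- 1L
outdir <- "results/fixtures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

straight <- make_toy_arm(180, n_res = 40, sidechains = TRUE, seed = seed)
bent <- make_toy_arm(156, n_res = 40, sidechains = TRUE, seed = seed)
write_structure(straight, file.path(outdir, "arm_straight.pdb"))
write_structure(bent, file.path(outdir, "arm_bent156.pdb"))

closed <- make_toy_dimer(toy_dimer_params(bend = 156, gap = 0, n_res = 40, seed = seed))
open <- make_toy_dimer(toy_dimer_params(bend = 156, gap = 10, n_res = 40, seed = seed))
write_dimer_model(closed, file.path(outdir, "dimer_closed.pdb"))
write_dimer_model(open, file.path(outdir, "dimer_open.pdb"))

traj <- make_pseudo_trajectory(pseudo_trajectory_params(
  start = toy_dimer_params(bend = 156, gap = 0, n_res = 40, seed = seed),
  end = toy_dimer_params(bend = 156, gap = 10, n_res = 40, seed = seed),
  n_frames = 25, spacing_ns = 20, noise_sd = 0.3, seed = seed))
write_trajectory_pdb(traj, file.path(outdir, "trajectory_closed_to_open.pdb"))

cat(sprintf("wrote %d fixture files to %s\n", length(list.files(outdir)), outdir))
cat(sprintf("trajectory: %d frames, %g ns span\n", n_frames(traj), max(traj$times)))
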