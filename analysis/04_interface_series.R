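#!/usr/bin/env Rscript
# Buried interface area: static gap sweep, and the windowed time series over
# the closed-to-open pseudo-trajectory (the desk-scale analogue of interface
# collapse after ligand removal).

suppressMessages(library(ectodimer))

dir.create("results", showWarnings = FALSE)
dm <- toy_domain_map(40)

gaps <- c(0, 1, 2, 3, 5, 8, 10)
areas <- vapply(gaps, function(g) {
  d <- make_toy_dimer(toy_dimer_params(gap = g, n_res = 40))
  buried_interface_area(assign_radii(dimer_subunit(d, "A")),
                        assign_radii(dimer_subunit(d, "B")), domain_map = dm)
}, numeric(1))
utils::write.csv(data.frame(gap_A = gaps, buried_area_A2 = areas),
                 "results/burial_vs_gap.csv", row.names = FALSE)
cat("buried area vs interface gap (straight arms):\n")
print(data.frame(gap_A = gaps, buried_area_A2 = round(areas, 1)), row.names = FALSE)
cat(sprintf("monotone decreasing: %s\n\n", all(diff(areas) <= 0)))

traj <- read_trajectory_pdb("results/fixtures/trajectory_closed_to_open.pdb",
                            dt = 20)
ser <- interface_series(traj, "A", "B", domain_map = dm, window = 200)
write_series(ser, "results/interface_series.csv", "results/interface_series.json")
cat(sprintf("windowed series over %d frames (200-ns window): %0.f -> %0.f A2\n",
            n_frames(traj), ser$windowed[1], ser$windowed[length(ser$windowed)]))
cat(sprintf("raw series fluctuates (sd %.0f A2); windowing leaves a clean trend\n",
            stats::sd(ser$values - ser$windowed)))
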