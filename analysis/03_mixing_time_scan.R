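#!/usr/bin/env Rscript
# Scans the mixing time (speed of dilution) over 1-40 s and records how
# the wild-type calcium peak and its latency depend on it.
# Writes:  results/mixing_time_scan.csv

suppressPackageStartupMessages(library(calshock))
dir.create("results", showWarnings = FALSE)

scan <- mixing_time_scan(1:40,
                         strain = strain_config("wild-type",
                                                target_baseline = 215))
write.csv(scan, "results/mixing_time_scan.csv", row.names = FALSE)

t_opt <- attr(scan, "t_m_opt")
cat("Mixing-time scan (d = 5 shock, wild-type):\n\n")
print(scan[scan$t_m %in% c(1, 5, 10, 15, t_opt, 20, 30, 40), ],
      row.names = FALSE, digits = 5)
cat(sprintf("\nPeak response is maximal at t_m = %d s (peak %.0f nM).\n",
            t_opt, max(scan$peak)))
cat("Time-to-peak grows monotonically with the mixing time:",
    all(diff(scan$time_to_peak) > 0), "\n")
cat("Faster dilution speeds the response but does not maximise the peak:",
    "\nvery fast mixing removes extracellular calcium before the channels",
    "\nare fully open; very slow mixing lets the calmodulin feedback close",
    "\nthem first.\n")
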