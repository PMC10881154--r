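#!/usr/bin/env Rscript
# Generate the synthetic study: four fixed-tissue angle conditions, tissue
# sections per genotype, two tumor cohorts and a live-imaging track set,
# all with known ground truth. Writes the CSV tables every later stage
# consumes to results/data/.

suppressPackageStartupMessages(library(epispindle))
seed <- 20260920
out <- "results/data"

st <- simulate_study(seed = seed)

angles <- do.call(rbind, lapply(st$angle_samples, function(s)
  data.frame(division_id = sprintf("%s_%03d", s$condition, seq_len(s$n)),
             condition = s$condition, mouse_id = NA, angle_deg = s$angles)))
write_table(angles, file.path(out, "angles.csv"))
write_table(st$tissue$counts, file.path(out, "section_counts.csv"))
write_table(st$tissue$geometry, file.path(out, "section_geometry.csv"))
# the membrane trace is deterministic per condition (sections share it);
# persist one trace per condition, thinned to 10 µm vertex spacing
tr <- st$tissue$traces
first_ids <- tapply(tr$trace_id, sub("_m[0-9]+_s[0-9]+$", "", tr$trace_id),
                    function(x) x[1])
tr <- tr[tr$trace_id %in% first_ids & (tr$point_index - 1) %% 10 == 0, ]
write_table(tr, file.path(out, "bm_traces.csv"))
write_table(st$cohorts$tumors, file.path(out, "tumors.csv"))
write_table(st$cohorts$mice, file.path(out, "mice.csv"))
write_table(st$tracks, file.path(out, "tracks.csv"))
write_table(st$frames, file.path(out, "track_frames.csv"))
write_json_summary(list(seed = seed,
                        tissue_truth = st$tissue$truth,
                        cohort_truth = st$cohorts$truth),
                   file.path(out, "ground_truth.json"))

cat(sprintf("simulated %d divisions across %d conditions, %d tissue sections, %d mice with %d tumors, %d live tracks\n",
            nrow(angles), length(st$angle_samples),
            nrow(st$tissue$geometry), nrow(st$cohorts$mice),
            nrow(st$cohorts$tumors), nrow(st$tracks)))
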