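#!/usr/bin/env Rscript
# Tissue morphometry per animal and condition: basal/spinous density per µm
# of basement membrane, folding ratio, basal marker fractions, and rare
# events per µm (proliferative spinous cells, TUNEL+ per layer). The
# proliferative-spinous frequencies feed the Gaussian-simulation outlier
# test against the PTEN wild-type reference.

suppressPackageStartupMessages(library(epispindle))
seed <- 20260920

counts <- read_counts("results/data/section_counts.csv")
geometry <- read_geometry("results/data/section_geometry.csv")
agg <- aggregate_morphometry(counts, geometry)
write_table(agg$per_animal, "results/morphometry_per_animal.csv")
write_table(agg$per_condition, "results/morphometry_per_condition.csv")
print(agg$per_condition[, c("condition", "basal_density", "spinous_density", "folding")])

# outlier test: proliferative-spinous frequency of the combined-loss group
# against the Gaussian fitted on the PTEN LGN wild-type animals
pa <- agg$per_animal
ref <- pa$proliferative_spinous_per_um[pa$condition == "PTEN_LGN_wt"]
tested <- pa$proliferative_spinous_per_um[pa$condition == "PTEN_LGN_ko"]
threshold <- 0.0007 # events/µm; explicit parameter of the test
res <- flag_outlier_animals(tested, ref, threshold, seed = seed)
print(res$test)
cat(sprintf("%d of %d combined-loss animals exceed %.4g events/um\n",
            res$n_flagged, length(tested), threshold))
write_json_summary(list(threshold = threshold, n_flagged = res$n_flagged,
                        probability = res$test$probability,
                        probability_analytic = res$test$probability_analytic),
                   "results/outlier_test.json")
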