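#!/usr/bin/env Rscript
# Stage 3 - localization scoring with chance-level normalization.
# Generates localization responses for three synthetic observers that mimic
# the qualitative cue-type pattern (accurate with native cues, rear-biased
# quadrant confusions with flat/novel cues), scores them, and normalizes by
# a virtual chance experiment.

library(loomingbias)
dir.create("results", showWarnings = FALSE)
set.seed(301)

targets <- expand.grid(target_lat = seq(-80, 80, by = 20),
                       target_pol = seq(-60, 240, by = 20))
targets <- targets[rep(seq_len(nrow(targets)), 6), ]

observers <- list(
  native = list(gain = 0.95, bias_lat = 0, bias_pol = 0,
                scatter_lat = 6, scatter_pol = 14,
                confusion_rate = 0.04, confusion_center = 180),
  flat   = list(gain = 0.85, bias_lat = 0, bias_pol = 20,
                scatter_lat = 8, scatter_pol = 28,
                confusion_rate = 0.18, confusion_center = 180),
  novel  = list(gain = 0.85, bias_lat = 0, bias_pol = 25,
                scatter_lat = 8, scatter_pol = 32,
                confusion_rate = 0.24, confusion_center = 180)
)

rows <- list()
for (cue in names(observers)) {
  resp <- gen_localization_responses(targets, observers[[cue]],
                                     seed = 300 + match(cue,
                                                        names(observers)))
  obs <- score_trials(resp)
  chance <- chance_simulation(targets, uniform_response_sampler(
    range(targets$target_lat), range(targets$target_pol)),
    n_sim = 200, seed = 310, observed = obs)
  rows[[cue]] <- data.frame(
    cue = cue,
    lateral_error = obs$lateral_error,
    local_polar_error = obs$local_polar_error,
    quadrant_error_rate = obs$quadrant_error_rate,
    lateral_ratio = chance$ratios["lateral_error"],
    local_polar_ratio = chance$ratios["local_polar_error"],
    quadrant_ratio = chance$ratios["quadrant_error_rate"])
}
tab <- do.call(rbind, rows)
write.table(tab, "results/03_localization_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE, digits = 3)
cat("\nNormalized ratios rise from native toward novel cues;",
    "1 = chance-level performance, 0 = error-free.\n")
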