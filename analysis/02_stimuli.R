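#!/usr/bin/env Rscript
# Stage 2 - stimulus synthesis.
# Builds the two stimulus families: spectrally manipulated noise bursts for
# the localization task and Schroeder-phase harmonic complexes with a
# jittered raised-cosine transition ("flattened" / "shaped") for the
# looming task. Writes per-stimulus annotations to results/.

library(loomingbias)
dir.create("results", showWarnings = FALSE)

cue_files <- file.path("results", paste0("cue_", c("native", "flat",
                                                   "novel"), ".tsv"))
if (!all(file.exists(cue_files)))
  stop("run analysis/01_hrtf_manipulation.R first")
sets <- lapply(cue_files, read_spectrum_table)
names(sets) <- c("native", "flat", "novel")

rows <- list()
# localization stimuli: 500 ms noise bursts through each cue set x direction
nb <- noise_burst(duration = 0.5, ramp = 0.01, fs = 44100, seed = 201)
for (cue in names(sets)) for (d in 1:4) {
  st <- rms_equalize(apply_hrtf(nb, sets[[cue]], d))[[1]]
  rows[[length(rows) + 1]] <- data.frame(
    family = "noise_burst", cue = cue,
    polar = sets[[cue]]$directions$polar[d],
    f0 = NA, transition_time = NA,
    rms_db = 20 * log10(sqrt(mean(st$samples^2))),
    peak = max(abs(st$samples)))
}

# looming stimuli: harmonic complexes, flat <-> shaped/native transitions
f0s <- seq(100, 140, length.out = 12)
for (f0 in f0s[c(1, 6, 12)]) {
  hc <- harmonic_complex(f0, 1000, 16000, phase_curvature = 0.5,
                         duration = 1.2)
  for (d in c(1, 3)) {
    a <- apply_hrtf(hc, sets$native, d)   # shaped endpoint: native cues
    b <- apply_hrtf(hc, sets$flat, d)     # flat endpoint
    eq <- rms_equalize(list(a, b))
    flattened <- make_transition(eq[[1]], eq[[2]], onset_nominal = 0.6,
                                 jitter = 0.05, crossfade = 0.01,
                                 seed = round(f0) * 10 + d)
    shaped <- make_transition(eq[[2]], eq[[1]], onset_nominal = 0.6,
                              jitter = 0.05, crossfade = 0.01,
                              seed = round(f0) * 10 + d)
    for (lab in c("flattened", "shaped")) {
      st <- get(lab)
      rows[[length(rows) + 1]] <- data.frame(
        family = lab, cue = "native",
        polar = sets$native$directions$polar[d], f0 = f0,
        transition_time = st$annotations$transition_time,
        rms_db = 20 * log10(sqrt(mean(st$samples^2))),
        peak = max(abs(st$samples)))
    }
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/02_stimulus_annotations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Synthesized", nrow(tab), "stimuli; transitions realized in [",
    round(min(tab$transition_time, na.rm = TRUE), 3), ",",
    round(max(tab$transition_time, na.rm = TRUE), 3),
    "] s (0.6 s nominal, +/-50 ms jitter).\n")
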