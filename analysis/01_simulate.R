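#!/usr/bin/env Rscript
## Generate the synthetic study sessions used by the downstream analysis
## scripts and write them to results/sessions/ in the plain-text layout.
## Each session has a different planted emphasis so every later stage has a
## ground-truth surface to recover.

suppressPackageStartupMessages(library(arenaneuro))
seed <- 1
out <- "results/sessions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

configs <- list(
  ## mixed session: spatial fields + body-frame kinematic drives, used for
  ## encoding, spatial decoding and residualization
  mixed = session_config(
    duration_s = 600, n_units = 60, K = 6,
    seed = substream_seed(seed, "encoding"),
    spatial_gain_hz = 8, syllable_gain_hz = 0,
    frame_weight_hz = 2, frame_mix = c(0, 1, 0, 0),
    frame_feature_mask = c(1, 1, 0, 0, 0, 0), baseline_hz = 8),
  ## reference-frame session: half allocentric, half body-centric units
  frames = session_config(
    duration_s = 600, n_units = 60, K = 6,
    seed = substream_seed(seed, "frames"),
    spatial_gain_hz = 0, syllable_gain_hz = 0,
    frame_weight_hz = 0.5, frame_mix = c(0.5, 0.5, 0, 0), baseline_hz = 8),
  ## syllable session: sustained syllable gains, long bouts, used for
  ## syllable decoding, TGM, tuning
  syllables = session_config(
    duration_s = 600, n_units = 50, K = 4,
    seed = substream_seed(seed, "syllables"),
    spatial_gain_hz = 0, syllable_gain_hz = 5, frame_weight_hz = 0,
    baseline_hz = 8, model = syllable_model(K = 4, dwell_s = 4)),
  ## context session: syllable x tier interaction on half the units
  context = session_config(
    duration_s = 1200, n_units = 80, K = 6,
    seed = substream_seed(seed, "context"),
    spatial_gain_hz = 0, syllable_gain_hz = 5, frame_weight_hz = 0,
    context_gain = 1.5, baseline_hz = 8,
    model = syllable_model(K = 6, dwell_s = 2.5, z_jitter = 0.7)),
  ## ramp session: anticipatory blend toward the upcoming syllable
  ramp = session_config(
    duration_s = 360, n_units = 40, K = 5,
    seed = substream_seed(seed, "ramp"),
    spatial_gain_hz = 0, syllable_gain_hz = 4, frame_weight_hz = 0,
    ramp_amp = 1, ramp_lead_s = 1, baseline_hz = 8,
    model = syllable_model(K = 5, dwell_s = 4)))

for (nm in names(configs)) {
  ses <- generate_session(configs[[nm]])
  write_session(ses, file.path(out, nm))
  cat(sprintf("%-10s %4.0f s, %3d units, K=%d -> %s\n", nm,
              configs[[nm]]$duration_s, configs[[nm]]$n_units,
              configs[[nm]]$K, file.path(out, nm)))
}
cat("Sessions written. Ground truth is in each truth.yaml.\n")
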