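#!/usr/bin/env Rscript
## Pose cleaning, kinematics, encoding feature groups, spatial labels and
## the lagged design matrix for each simulated session. Writes per-session
## features.csv and labels.csv under results/features/.

suppressPackageStartupMessages(library(arenaneuro))
in_dir <- "results/sessions"
out <- "results/features"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (nm in list.dirs(in_dir, recursive = FALSE, full.names = FALSE)) {
  ses <- read_session(file.path(in_dir, nm))
  sp <- smooth_and_constrain_pose(ses$pose)
  kin <- compute_kinematics(sp)
  feats <- compute_feature_groups(kin, ses$arena)
  labs <- assign_spatial_labels(feats, ses$arena)
  des <- build_design_matrix(feats)
  utils::write.csv(feats, file.path(out, paste0(nm, "_features.csv")),
                   row.names = FALSE)
  utils::write.csv(labs, file.path(out, paste0(nm, "_labels.csv")),
                   row.names = FALSE)
  cat(sprintf(
    "%-10s %d bins, %d valid after lag trimming, %d design columns, %d zones\n",
    nm, nrow(feats), sum(des$valid), ncol(des$X),
    length(unique(na.omit(labs$zone[feats$valid])))))
}
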