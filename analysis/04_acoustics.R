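#!/usr/bin/env Rscript
# Acoustic side of the survey: ambient-noise summary, whistle-contour
# feature extraction, and pairing of whistles with behavioural context and
# the 2-s pre-whistle noise window.

source(file.path("analysis", "00_config.R"))

sv <- load_survey()

obl_cols <- grep("^obl_", names(sv$noise), value = TRUE)
noise_summary <- data.frame(
  metric = c("nl_bb", obl_cols),
  mean_db = c(mean(sv$noise$nl_bb), colMeans(sv$noise[obl_cols])),
  sd_db = c(sd(sv$noise$nl_bb),
            apply(sv$noise[obl_cols], 2, sd))
)
write_result(noise_summary, "04_noise_levels")

feats <- extract_features_all(sv$contours, sv$whistles)
pr <- pair_whistles(sv$whistles, sv$samples, sv$noise)

feat_cols <- c("duration", "freq_min", "freq_max", "freq_delta",
               "freq_start", "freq_end", "inflections", "extrema",
               "breaks", "saddles", "harmonics")
feature_summary <- do.call(rbind, lapply(feat_cols, function(f) data.frame(
  characteristic = f,
  mean = mean(feats[[f]]),
  sd = sd(feats[[f]]),
  n_nonzero = sum(feats[[f]] > 0))))
write_result(feature_summary, "04_whistle_features")

pairing <- data.frame(
  n_whistles = nrow(sv$whistles),
  n_paired = if (is.null(pr$records)) 0L else nrow(pr$records),
  n_excluded = nrow(pr$excluded)
)
write_result(pairing, "04_pairing")
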