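#!/usr/bin/env Rscript
# Convert theodolite fixes to positions, compute per-sample swimming speeds,
# and compare them across activity states and vessel densities.

source(file.path("analysis", "00_config.R"))

sv <- load_survey()

tab <- speed_sample_table(sv$fixes, sv$samples, survey_station,
                          cutoff = survey_config$cutoff)

speed_by_state <- do.call(rbind, lapply(split(tab, tab$activity_state),
  function(d) data.frame(
    activity_state = d$activity_state[1],
    n = sum(is.finite(d$mean_speed)),
    mean_speed = mean(d$mean_speed, na.rm = TRUE),
    sd_speed = sd(d$mean_speed, na.rm = TRUE),
    median_speed = median(d$mean_speed, na.rm = TRUE))))
write_result(speed_by_state, "02_speed_by_state")

report <- speed_comparison_report(tab)
write_result(report, "02_speed_tests")
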