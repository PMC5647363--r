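#!/usr/bin/env Rscript
# Simulate the survey and summarise its observational record: sampling
# effort, vessel traffic, group composition and behavioural states.

source(file.path("analysis", "00_config.R"))

sv <- load_survey()

effort <- data.frame(
  n_samples = nrow(sv$samples),
  n_theodolite_fixes = nrow(sv$fixes),
  n_whistles = nrow(sv$whistles),
  median_vessel_count = median(sv$samples$vessel_count),
  mean_vessel_count = mean(sv$samples$vessel_count),
  mean_group_size = mean(sv$samples$group_size),
  calf_fraction = mean(sv$samples$calf_present),
  ambient_level_mean_db = mean(sv$noise$nl_bb)
)
write_result(effort, "01_survey_effort")

state_tab <- as.data.frame(table(activity_state = sv$samples$activity_state),
                           responseName = "n_samples")
state_tab$fraction <- state_tab$n_samples / sum(state_tab$n_samples)
write_result(state_tab, "01_activity_states")

vc <- sv$samples$vessel_count
traffic <- data.frame(
  vessel_count = sort(unique(vc)),
  n_samples = as.integer(table(vc))
)
write_result(traffic, "01_vessel_counts")
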