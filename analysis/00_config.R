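# Shared configuration for the analysis scripts.
#
# One synthetic survey stands in for a field season: 2 000 five-minute
# samples of a single focal community tracked from a 32-m vantage point,
# with concurrent vessel counts and an acoustic logger. All scripts
# re-derive the survey from this seed, so every table in results/ is
# reproducible by running the scripts in order.

library(tursiops)

survey_seed <- 42
survey_config <- synth_config(seed = survey_seed, n_samples = 2000)
survey_station <- station_geometry(32)

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

load_survey <- function() {
  simulate_survey(survey_config, station = survey_station)
}

write_result <- function(df, name) {
  path <- file.path(results_dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  message("wrote ", path, " (", nrow(df), " rows)")
}
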