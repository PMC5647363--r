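#!/usr/bin/env Rscript
# Context-conditioned behavioural transition analysis: transition counts,
# per-context transition matrices, stationary behavioural budgets, and
# proportion tests of each non-baseline context against Low traffic.

source(file.path("analysis", "00_config.R"))

sv <- load_survey()

ma <- markov_analysis(sv$samples, cutoff = survey_config$cutoff)

per_context <- data.frame(
  context = dimnames(ma$counts)[[3]],
  n_transitions = as.integer(apply(ma$counts, 3, sum))
)
per_context <- rbind(per_context,
                     data.frame(context = "total",
                                n_transitions = sum(per_context$n_transitions)))
write_result(per_context, "03_transition_totals")

budget_tab <- do.call(rbind, lapply(names(ma$budgets), function(cx) {
  data.frame(context = cx, state = names(ma$budgets[[cx]]),
             budget = as.numeric(ma$budgets[[cx]]))
}))
write_result(budget_tab, "03_behavioural_budgets")

write_result(ma$budget_tests, "03_budget_tests")
write_result(ma$transition_tests, "03_transition_cell_tests")
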