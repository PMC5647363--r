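#!/usr/bin/env Rscript
# GAMs of whistle characteristics against broadband noise and behavioural
# context: all-subsets AICc selection per characteristic, overdispersion,
# activity contrasts where activity is retained, and residual
# semivariograms as an autocorrelation check.

source(file.path("analysis", "00_config.R"))

sv <- load_survey()
feats <- extract_features_all(sv$contours, sv$whistles)
pr <- pair_whistles(sv$whistles, sv$samples, sv$noise)
ctx <- pr$records[, setdiff(names(pr$records), c("harmonics", "start_time"))]
rec <- merge(feats, ctx, by = "whistle_id")

fits <- fit_whistle_gams(rec)

summary_rows <- list()
selection_rows <- list()
posthoc_rows <- list()
for (resp in names(fits$results)) {
  r <- fits$results[[resp]]
  if (!is.null(r$skipped) && !is.na(r$skipped) && is.null(r$model)) {
    summary_rows[[resp]] <- data.frame(
      response = resp, modelled = FALSE, reason = r$skipped,
      n_modelled = NA, n_outliers = NA, best_terms = NA,
      best_weight = NA, overdispersion = NA)
    next
  }
  best <- r$selection[which.max(r$selection$weight), ]
  summary_rows[[resp]] <- data.frame(
    response = resp, modelled = TRUE, reason = "",
    n_modelled = r$n_modelled, n_outliers = r$n_outliers,
    best_terms = paste(r$best_terms, collapse = "+"),
    best_weight = best$weight, overdispersion = r$overdispersion)
  sel <- r$selection
  sel$response <- resp
  selection_rows[[resp]] <- sel
  if (!is.null(r$posthoc)) {
    ph <- r$posthoc
    ph$response <- resp
    posthoc_rows[[resp]] <- ph
  }
}
write_result(do.call(rbind, summary_rows), "05_gam_summary")
write_result(do.call(rbind, selection_rows), "05_gam_selection")
if (length(posthoc_rows)) {
  write_result(do.call(rbind, posthoc_rows), "05_activity_contrasts")
}

# noise-effect direction for the modelled continuous characteristics:
# linear-predictor change from quiet (10th percentile) to loud (90th)
nd <- rec[rep(1, 2), ]
nd$calf_present <- factor(as.integer(nd$calf_present), levels = c(0, 1))
nd$nl_bb <- as.numeric(quantile(rec$nl_bb, c(0.1, 0.9)))
eff <- do.call(rbind, lapply(names(fits$results), function(resp) {
  r <- fits$results[[resp]]
  if (is.null(r$model) || !"noise" %in% r$best_terms) return(NULL)
  lp <- predict(r$model, newdata = nd, type = "link")
  data.frame(response = resp,
             lp_quiet = as.numeric(lp[1]), lp_loud = as.numeric(lp[2]),
             noise_effect = as.numeric(lp[2] - lp[1]))
}))
if (!is.null(eff)) write_result(eff, "05_noise_effects")

# residual autocorrelation check for whistle duration
dur <- fits$results$duration
if (!is.null(dur$model)) {
  res <- residuals(dur$model, type = "pearson")
  used <- as.integer(rownames(dur$model$model))
  sv_tab <- residual_semivariogram(res, rec$start_time[used])
  write_result(sv_tab, "05_duration_semivariogram")
}
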