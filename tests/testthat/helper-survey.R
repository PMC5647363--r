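# Shared synthetic fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# a moderate survey exercising the full pipeline
cached_survey <- function() {
  if (is.null(.fixture_cache$survey)) {
    .fixture_cache$survey <- simulate_survey(synth_config(seed = 301,
                                                          n_samples = 500))
  }
  .fixture_cache$survey
}

# whistle records from the cached survey (features + context + noise)
cached_records <- function() {
  if (is.null(.fixture_cache$records)) {
    sv <- cached_survey()
    feats <- extract_features_all(sv$contours, sv$whistles)
    pr <- pair_whistles(sv$whistles, sv$samples, sv$noise)
    ctx <- pr$records[, setdiff(names(pr$records), c("harmonics", "start_time"))]
    .fixture_cache$records <- merge(feats, ctx, by = "whistle_id")
  }
  .fixture_cache$records
}
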