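# Families, collinearity screening, information-theoretic model selection,
# post-hoc contrasts and residual diagnostics for the whistle models.

test_that("each response maps to its error family", {
  expect_equal(family_for("duration")$family, "Gamma")
  expect_equal(family_for("duration")$link, "log")
  expect_equal(family_for("freq_min")$family, "Gamma")
  expect_equal(family_for("inflections")$family, "poisson")
  expect_equal(family_for("breaks")$family, "poisson")
  expect_equal(family_for("harmonics")$family, "binomial")
  expect_equal(family_for("harmonics")$link, "logit")
  expect_error(family_for("not_a_response"), "unknown")
})

test_that("variance inflation factors follow the 1/(1-R^2) identity", {
  set.seed(91)
  n <- 400
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  sc <- screen_collinearity(x)
  expect_true(all(abs(sc$vif - 1) < 0.1))
  expect_setequal(sc$retained, c("a", "b", "c"))
  expect_length(sc$dropped, 0)

  # correlation 0.9 gives VIF = 1/(1 - 0.81) = 5.263, above the gate of 5
  S <- matrix(c(1, 0.9, 0.9, 1), 2)
  z <- MASS::mvrnorm(n, c(0, 0), S, empirical = TRUE)
  x2 <- data.frame(u = z[, 1], v = z[, 2], w = rnorm(n))
  before <- screen_collinearity(x2[c("u", "v")], threshold = Inf)
  expect_equal(max(before$vif), 1 / (1 - 0.81), tolerance = 1e-6)
  sc2 <- screen_collinearity(x2)
  expect_length(sc2$dropped, 1)
  expect_true(sc2$dropped %in% c("u", "v"))
  expect_true(all(sc2$vif < 5))

  # a duplicated column is perfectly collinear and one copy must go
  x3 <- data.frame(p = rnorm(n))
  x3$q <- x3$p
  expect_length(suppressWarnings(screen_collinearity(x3))$retained, 1)

  expect_error(screen_collinearity(x3["p"]), "at least 2")
})

test_that("Akaike weights follow the closed form", {
  w <- akaike_weights(c(0, 2))
  expect_equal(unname(w), exp(-c(0, 2) / 2) / sum(exp(-c(0, 2) / 2)),
               tolerance = 1e-12)
  expect_equal(unname(w[1]), 0.7311, tolerance = 5e-4)
  expect_equal(sum(akaike_weights(c(3, 0, 7, 1))), 1, tolerance = 1e-12)
  expect_equal(unname(akaike_weights(c(5, 5))), c(0.5, 0.5))
})

test_that("AICc applies the small-sample correction to the log-likelihood", {
  set.seed(92)
  d <- data.frame(y = rgamma(60, 5, 2), x = rnorm(60))
  m <- mgcv::gam(y ~ x, family = Gamma(link = "log"), data = d,
                 method = "GCV.Cp")
  k <- attr(logLik(m), "df")
  n <- nrow(d)
  expect_equal(aicc(m),
               -2 * as.numeric(logLik(m)) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-10)
  expect_gt(aicc(m), AIC(m))  # correction is strictly positive
})

test_that("all-subsets selection finds strong configured effects", {
  set.seed(93)
  n <- 400
  rec <- data.frame(
    activity_state = sample(activity_states, n, replace = TRUE),
    calf_present = sample(c(TRUE, FALSE), n, replace = TRUE),
    group_size = sample(1:5, n, replace = TRUE),
    nl_bb = runif(n, 95, 125)
  )
  mu <- exp(-0.4 - 0.03 * (rec$nl_bb - 110) +
              0.35 * (rec$activity_state == "socialising"))
  rec$duration <- rgamma(n, shape = 8, rate = 8 / mu)
  sel <- select_model(rec, "duration")
  expect_equal(nrow(sel$table), 16)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-10)
  expect_equal(min(sel$table$delta), 0)
  expect_true(all(c("activity", "noise") %in% sel$best_terms))
  expect_false("calf" %in% sel$best_terms)
  expect_s3_class(sel$best, "gam")
})

test_that("overdispersion is near 1 for Poisson data and scales with variance", {
  set.seed(94)
  n <- 500
  x <- rnorm(n)
  mu <- exp(0.5 + 0.3 * x)
  d1 <- data.frame(y = rpois(n, mu), x = x)
  m1 <- mgcv::gam(y ~ x, family = poisson, data = d1, method = "GCV.Cp")
  expect_lt(abs(overdispersion(m1) - 1), 0.15)

  # the alternative reading of the denominator is sum(r^2)/n - k
  r <- residuals(m1, type = "pearson")
  k <- attr(logLik(m1), "df")
  expect_equal(overdispersion(m1, "n_minus_k_alt"), sum(r^2) / n - k,
               tolerance = 1e-12)

  # negative-binomial data with Var = mu + mu^2/theta is overdispersed
  d2 <- data.frame(y = MASS::rnegbin(n, mu, theta = 0.6), x = x)
  m2 <- mgcv::gam(y ~ x, family = poisson, data = d2, method = "GCV.Cp")
  expect_gt(overdispersion(m2), 1.5)
})

test_that("post-hoc activity contrasts cover all state pairs", {
  set.seed(95)
  n <- 600
  rec <- data.frame(
    activity_state = factor(sample(activity_states, n, replace = TRUE)),
    nl_bb = runif(n, 95, 125)
  )
  mu <- exp(-0.4 + 0.5 * (rec$activity_state == "travelling"))
  rec$duration <- rgamma(n, shape = 8, rate = 8 / mu)
  m <- mgcv::gam(duration ~ activity_state + s(nl_bb, k = 5),
                 family = Gamma(link = "log"), data = rec, method = "GCV.Cp")
  ph <- posthoc_activity(m)
  expect_equal(nrow(ph), choose(5, 2))
  trav <- grepl("travelling", ph$contrast)
  expect_true(all(ph$p_adjusted[trav] < 0.01))
  expect_true(all(ph$p_adjusted[!trav] > 0.01))
  expect_equal(attr(ph, "adjustment"), "single-step")
})

test_that("simultaneous contrasts hold the family-wise error rate", {
  set.seed(96)
  reps <- 300
  n <- 150
  any_sig <- 0
  for (r in 1:reps) {
    d <- data.frame(activity_state = factor(rep(activity_states, each = n / 5)),
                    y = rnorm(n))
    m <- glm(y ~ activity_state, data = d)
    ph <- posthoc_activity(m)
    if (any(ph$p_adjusted < 0.05)) any_sig <- any_sig + 1
  }
  # under the global null the family-wise rate should sit near 5 %
  expect_lt(any_sig / reps, 0.09)
  expect_gt(any_sig / reps, 0.015)
})

test_that("residual semivariogram is flat for white noise", {
  set.seed(97)
  n <- 800
  ts <- sort(runif(n, 0, 40000))
  r <- rnorm(n, 0, 2)
  sv <- residual_semivariogram(r, ts)
  # expectation for iid noise is sigma^2 = 4 at every lag
  expect_true(all(abs(sv$semivariance - 4) < 1.2))
  expect_equal(sum(sv$n_pairs), choose(n, 2))

  const <- residual_semivariogram(rep(3, 50), seq_len(50) * 10)
  expect_true(all(const$semivariance == 0))
})

test_that("semivariogram bins match a double loop on small input", {
  set.seed(98)
  ts <- cumsum(runif(30, 1, 50))
  r <- rnorm(30)
  h <- abs(outer(ts, ts, "-"))
  edges <- seq(0, max(h), length.out = 6)
  sv <- residual_semivariogram(r, ts, breaks = edges)
  g <- outer(r, r, "-")^2 / 2
  up <- upper.tri(h)
  for (b in seq_len(nrow(sv))) {
    in_bin <- if (b == 1) h >= edges[1] & h <= edges[2] else
      h > edges[b] & h <= edges[b + 1]
    expect_equal(sv$n_pairs[b], sum(in_bin & up))
    if (sv$n_pairs[b] > 0) {
      expect_equal(sv$semivariance[b], mean(g[in_bin & up]), tolerance = 1e-10)
    }
  }
})

test_that("the full modelling pass keeps honest bookkeeping", {
  rec <- cached_records()
  fits <- fit_whistle_gams(rec, responses = c("duration", "freq_delta",
                                              "breaks"))
  expect_equal(fits$n_records, nrow(rec))
  dur <- fits$results$duration
  expect_equal(dur$n_modelled, fits$n_records - dur$n_outliers)
  expect_true(is.na(dur$skipped))
  expect_s3_class(dur$model, "gam")
  expect_equal(nrow(dur$selection), 16)
  # contour breaks are rare in this survey and must be excluded, not forced
  expect_lt(sum(rec$breaks > 0), 20)
  expect_match(fits$results$breaks$skipped, "fewer than")
  expect_null(fits$results$breaks$model)
  expect_equal(fits$n_outliers_total,
               dur$n_outliers + fits$results$freq_delta$n_outliers)
})

test_that("the configured noise effect on duration is recovered", {
  rec <- cached_records()
  full <- fit_candidate(rec, "duration",
                        c("activity", "calf", "group_size", "noise"))
  expect_s3_class(full, "gam")
  nd <- rec[rep(1, 2), ]
  nd$activity_state <- factor(nd$activity_state,
                              levels = sort(unique(rec$activity_state)))
  nd$calf_present <- factor(as.integer(nd$calf_present), levels = c(0, 1))
  nd$nl_bb <- as.numeric(quantile(rec$nl_bb, c(0.1, 0.9)))
  lp <- predict(full, newdata = nd, type = "link")
  expect_lt(lp[2], lp[1])  # whistles shorten as broadband noise rises
})
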