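# Vessel-context classification, transition tables, stationary budgets and
# proportion tests.

test_that("vessel context follows the preceding/succeeding rule", {
  expect_equal(as.character(classify_context(2, 2)), "Low")
  expect_equal(as.character(classify_context(2, 5)), "Increasing")
  expect_equal(as.character(classify_context(5, 2)), "Decreasing")
  expect_equal(as.character(classify_context(5, 5)), "High")
  # the cutoff itself is low: 0-3 versus 4+
  expect_equal(as.character(classify_context(3, 4)), "Increasing")
  expect_error(classify_context(-1, 2), "non-negative")
})

test_that("cutoff re-estimation returns the sample median", {
  expect_equal(estimate_cutoff(c(0, 1, 3, 3, 5, 7, 9)), 3)
  expect_equal(estimate_cutoff(c(2, 2, 4, 4)), 2)  # ties at the median low
})

test_that("transitions require strict 5-min adjacency within a group", {
  samples <- data.frame(
    sample_start = c(36000, 36300, 36900),  # 10:00, 10:05, 10:15
    group_id = "g1",
    activity_state = c("travelling", "milling", "milling"),
    vessel_count = c(1, 2, 2))
  tr <- extract_transitions(samples)
  expect_equal(nrow(tr), 1)
  expect_equal(as.character(tr$from), "travelling")
  expect_equal(as.character(tr$to), "milling")

  k <- 7
  run <- data.frame(sample_start = (0:(k - 1)) * 300, group_id = "g1",
                    activity_state = "foraging", vessel_count = 0)
  tr2 <- extract_transitions(run)
  expect_equal(nrow(tr2), k - 1)
  expect_true(all(tr2$from == "foraging" & tr2$to == "foraging"))

  # a group change breaks the chain even on adjacent samples
  run$group_id <- c(rep("g1", 3), rep("g2", 4))
  expect_equal(nrow(extract_transitions(run)), 5)
})

test_that("extracted transition count matches a brute-force pair scan", {
  sv <- cached_survey()
  tr <- extract_transitions(sv$samples)
  s <- sv$samples
  brute <- 0
  for (i in seq_len(nrow(s) - 1)) {
    if (s$sample_start[i + 1] - s$sample_start[i] == 300 &&
        s$group_id[i + 1] == s$group_id[i]) brute <- brute + 1
  }
  expect_equal(nrow(tr), brute)
  # conservation: the three-way table preserves every transition
  expect_equal(sum(transition_counts(tr)), nrow(tr))
})

test_that("transition probabilities are forced by row normalisation", {
  a <- matrix(0, 5, 5, dimnames = list(activity_states, activity_states))
  a[1, ] <- c(2, 0, 0, 0, 3)
  p <- transition_probabilities(a)
  expect_equal(unname(p[1, ]), c(0.4, 0, 0, 0, 0.6))
  expect_true(all(is.na(p[2, ])))
  expect_setequal(attr(p, "undefined_rows"), activity_states[2:5])

  u <- matrix(7, 5, 5, dimnames = list(activity_states, activity_states))
  expect_true(all(transition_probabilities(u) == 0.2))

  set.seed(71)
  for (i in 1:10) {
    a <- matrix(rpois(25, 4), 5, 5, dimnames = list(activity_states,
                                                    activity_states))
    p <- transition_probabilities(a)
    # independent normaliser: explicit double loop
    for (r in 1:5) for (c in 1:5) {
      expect_equal(p[r, c], a[r, c] / sum(a[r, ]), tolerance = 1e-14)
    }
  }
})

test_that("budgets are dominant left eigenvectors", {
  # doubly stochastic: uniform budget
  P <- matrix(0.13, 5, 5); diag(P) <- 0.48
  b <- behavioural_budget(P)
  expect_equal(unname(as.numeric(b)), rep(0.2, 5), tolerance = 1e-12)

  # two-state closed form: P(T->F) = 0.3, P(F->T) = 0.4 -> (4/7, 3/7)
  P2 <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  b2 <- behavioural_budget(P2)
  expect_equal(unname(as.numeric(b2)), c(4 / 7, 3 / 7), tolerance = 1e-12)

  # fixed point and simplex invariants on random ergodic matrices
  set.seed(72)
  for (i in 1:10) {
    M <- matrix(rgamma(25, 1), 5, 5)
    M <- sweep(M, 1, rowSums(M), "/")
    b <- behavioural_budget(M)
    expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_true(all(b >= 0))
    expect_lt(max(abs(as.numeric(b %*% M) - as.numeric(b))), 1e-10)
  }
})

test_that("budget matches long-run occupancy of a simulated chain", {
  P <- default_context_matrices()$High
  b <- behavioural_budget(P)
  set.seed(73)
  n <- 200000
  s <- integer(n)
  s[1] <- 1L
  cum <- t(apply(P, 1, cumsum))
  u <- runif(n - 1)
  for (t in seq_len(n - 1)) {
    s[t + 1] <- findInterval(u[t], cum[s[t], ]) + 1L
  }
  occ <- tabulate(s, 5) / n
  expect_lt(max(abs(occ - as.numeric(b))), 0.01)
})

test_that("reducible chains are damped with a warning", {
  P <- diag(5)  # absorbing everywhere: no unique stationary vector
  expect_warning(b <- behavioural_budget(P), "reducible|periodic")
  expect_equal(sum(b), 1, tolerance = 1e-12)
  expect_true(attr(b, "damped"))
})

test_that("two-proportion Z-test matches the uncorrected chi-square", {
  z0 <- two_proportion_z_test(30, 100, 30, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p_value, 1)

  zt <- two_proportion_z_test(30, 100, 15, 100)
  expect_equal(zt$z, 2.540, tolerance = 5e-4)
  cs <- suppressWarnings(chisq.test(matrix(c(30, 70, 15, 85), 2, byrow = TRUE),
                                    correct = FALSE))
  expect_equal(zt$z^2, unname(cs$statistic), tolerance = 1e-10)

  degen <- two_proportion_z_test(0, 50, 0, 60)
  expect_true(degen$degenerate)
  expect_equal(degen$z, 0)
})

test_that("sparse cells are gated out of transition comparisons", {
  a <- array(0L, c(5, 5, 4), dimnames = list(activity_states, activity_states,
                                             vessel_contexts))
  a[, , "Low"] <- 20L
  a[, , "High"] <- 5L  # at the gate, not above it
  res <- compare_transitions(a)
  expect_false(any(res$testable[res$context == "High"]))
  a[1, 1, "High"] <- 6L
  res2 <- compare_transitions(a)
  expect_equal(sum(res2$testable[res2$context == "High"]), 1)
})

test_that("an inflated travelling persistence is detected against Low", {
  # synthetic counts: 1000 transitions per context, travelling->travelling
  # probability 0.55 in Increasing versus 0.20 in Low
  set.seed(74)
  detected <- 0
  for (rep in 1:20) {
    a <- array(0L, c(5, 5, 4), dimnames = list(activity_states,
                                               activity_states,
                                               vessel_contexts))
    for (cx in vessel_contexts) {
      p_tt <- if (cx == "Increasing") 0.55 else 0.20
      row_p <- matrix(0.2, 5, 5)
      row_p[5, ] <- c((1 - p_tt) / 4, (1 - p_tt) / 4, (1 - p_tt) / 4,
                      (1 - p_tt) / 4, p_tt)
      for (i in 1:5) {
        a[i, , cx] <- as.integer(rmultinom(1, 200, row_p[i, ]))
      }
    }
    res <- compare_transitions(a)
    hit <- res[res$context == "Increasing" & res$from == "travelling" &
                 res$to == "travelling", ]
    if (isTRUE(hit$testable) && !is.na(hit$p_value) && hit$p_value < 0.05) {
      detected <- detected + 1
    }
  }
  expect_gte(detected / 20, 0.8)
})

test_that("budget comparisons recover configured directions", {
  b_low <- c(foraging = 0.2, milling = 0.2, resting = 0.2,
             socialising = 0.2, travelling = 0.2)
  res0 <- compare_budgets(list(Low = b_low, High = b_low),
                          list(Low = 400, High = 150))
  expect_true(all(res0$z == 0))

  ma <- markov_analysis(cached_survey()$samples)
  soc <- ma$budget_tests[ma$budget_tests$context == "High" &
                           ma$budget_tests$state == "socialising", ]
  expect_lt(soc$pi_cmp, soc$pi_base)  # socialising reduced under High traffic
  few <- compare_budgets(list(Low = b_low, High = b_low),
                         list(Low = 400, High = 10))
  expect_true(all(few$low_n))
})

test_that("pipeline recovers generator transition probabilities", {
  cfg <- synth_config(seed = 75, n_samples = 2000, gap_prob = 0)
  set.seed(75)
  counts <- simulate_vessel_counts(cfg, seed = NULL)
  states <- simulate_behaviour_sequence(counts, cfg, seed = NULL)
  samples <- data.frame(sample_start = (seq_along(counts) - 1) * 300,
                        group_id = "g1", activity_state = states,
                        vessel_count = counts)
  ma <- markov_analysis(samples)
  ok <- 0; tot <- 0
  for (cx in vessel_contexts) {
    n_row <- rowSums(ma$counts[, , cx])
    for (i in 1:5) {
      if (n_row[i] == 0) next
      for (j in 1:5) {
        tot <- tot + 1
        pt <- cfg$context_matrices[[cx]][i, j]
        se <- sqrt(pt * (1 - pt) / n_row[i])
        if (abs(ma$matrices[[cx]][i, j] - pt) <= 1.96 * se + 1e-12) ok <- ok + 1
      }
    }
  }
  expect_gte(ok / tot, 0.93)
})
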