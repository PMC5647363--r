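# Context-conditioned first-order Markov chains of activity states:
# vessel-context classification, transition tables, stationary behavioural
# budgets, and two-proportion Z-tests between contexts.

#' The five activity states
#'
#' Mutually exclusive surface activity states assigned to each 5-min sample,
#' in the fixed order used by all transition tables.
#' @export
activity_states <- c("foraging", "milling", "resting", "socialising", "travelling")

#' The four vessel-traffic contexts
#' @export
vessel_contexts <- c("Low", "High", "Increasing", "Decreasing")

#' Classify the vessel context of a transition
#'
#' A transition between two adjacent 5-min samples is classed by the vessel
#' counts of its preceding and succeeding samples against a cutoff (the
#' study-wide median count, 3 by default): low/low -> Low, high/high -> High,
#' low/high -> Increasing, high/low -> Decreasing, where "low" means
#' `count <= cutoff`.
#'
#' @param preceding,succeeding Non-negative integer vessel counts (vectorised).
#' @param cutoff Density cutoff; counts at or below it are "low".
#' @return Factor with levels `Low`, `High`, `Increasing`, `Decreasing`.
#' @export
classify_context <- function(preceding, succeeding, cutoff = 3) {
  if (any(preceding < 0) || any(succeeding < 0)) {
    stop("vessel counts must be non-negative", call. = FALSE)
  }
  pre_high <- preceding > cutoff
  suc_high <- succeeding > cutoff
  ctx <- ifelse(pre_high,
                ifelse(suc_high, "High", "Decreasing"),
                ifelse(suc_high, "Increasing", "Low"))
  factor(ctx, levels = vessel_contexts)
}

#' Re-estimate the density cutoff from a vessel-count series
#'
#' The operational cutoff is the median count across all 5-min samples; ties
#' at the median are classed low (median 3 gives low = 0-3, high = 4+).
#'
#' @param counts Integer vessel counts per 5-min sample.
#' @return The median count (type-1 quantile, an observed value).
#' @export
estimate_cutoff <- function(counts) {
  as.numeric(stats::quantile(counts, 0.5, type = 1))
}

#' Extract activity-state transitions from ordered 5-min samples
#'
#' A transition is one pair of strictly adjacent 5-min samples of the same
#' group; a gap in the sampling grid or a change of group breaks the chain.
#' Each transition carries the vessel context derived from the two samples'
#' counts.
#'
#' @param samples Data frame with `sample_start` (seconds, on the 5-min
#'   grid), `group_id`, `activity_state` and `vessel_count`.
#' @param cutoff Vessel-density cutoff passed to [classify_context()], or
#'   `"median"` to re-estimate it from `samples$vessel_count`.
#' @param interval Sample spacing in seconds.
#' @return Data frame with `from`, `to` (factors over the five states),
#'   `context`, and `t` (start time of the preceding sample).
#' @export
extract_transitions <- function(samples, cutoff = 3, interval = 300) {
  if (identical(cutoff, "median")) cutoff <- estimate_cutoff(samples$vessel_count)
  samples <- samples[order(samples$group_id, samples$sample_start), ]
  n <- nrow(samples)
  if (n < 2) {
    return(data.frame(from = factor(character(), levels = activity_states),
                      to = factor(character(), levels = activity_states),
                      context = factor(character(), levels = vessel_contexts),
                      t = numeric()))
  }
  i <- seq_len(n - 1)
  adjacent <- (samples$sample_start[i + 1] - samples$sample_start[i]) == interval &
    samples$group_id[i + 1] == samples$group_id[i]
  keep <- which(adjacent)
  data.frame(
    from = factor(samples$activity_state[keep], levels = activity_states),
    to = factor(samples$activity_state[keep + 1], levels = activity_states),
    context = classify_context(samples$vessel_count[keep],
                               samples$vessel_count[keep + 1], cutoff),
    t = samples$sample_start[keep]
  )
}

#' Three-way transition contingency table
#'
#' Counts `a[i, j, c]` of transitions from preceding state i to succeeding
#' state j under vessel context c.
#'
#' @param transitions Data frame from [extract_transitions()].
#' @return A 5 x 5 x 4 integer array with dimnames (from, to, context).
#' @export
transition_counts <- function(transitions) {
  tab <- table(from = factor(transitions$from, levels = activity_states),
               to = factor(transitions$to, levels = activity_states),
               context = factor(transitions$context, levels = vessel_contexts))
  a <- array(as.integer(tab), dim = dim(tab), dimnames = dimnames(tab))
  a
}

#' Row-normalised transition probabilities
#'
#' `p_ij = a_ij / sum_j a_ij` per context. Rows whose preceding state was
#' never observed have no defined probabilities and are returned as `NA` with
#' the row flagged.
#'
#' @param counts Either a 5 x 5 matrix of counts or the 5 x 5 x 4 array from
#'   [transition_counts()].
#' @return For a matrix input, a matrix with attribute `undefined_rows`; for
#'   an array, a named list of such matrices (one per context).
#' @export
transition_probabilities <- function(counts) {
  normalise <- function(a) {
    rs <- rowSums(a)
    p <- sweep(a, 1, rs, "/")
    p[rs == 0, ] <- NA_real_
    attr(p, "undefined_rows") <- rownames(a)[rs == 0]
    p
  }
  if (length(dim(counts)) == 3) {
    out <- lapply(dimnames(counts)[[3]], function(cx) normalise(counts[, , cx]))
    names(out) <- dimnames(counts)[[3]]
    out
  } else {
    normalise(counts)
  }
}

# reachability of every state from every state on the directed graph P > 0
.is_irreducible <- function(P) {
  n <- nrow(P)
  adj <- P > 0
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach) > 0
  }
  all(reach)
}

#' Stationary behavioural budget of a transition matrix
#'
#' The budget is the left eigenvector of the dominant eigenvalue (1 for a
#' row-stochastic matrix), normalised to sum to one: the long-run proportion
#' of time spent in each activity state implied by the chain.
#'
#' Undefined rows (preceding state never observed) are replaced by a uniform
#' row with a warning. Reducible or periodic chains have no unique/limiting
#' stationary vector; these are handled by damping
#' (`P <- 0.999 P + 0.001 U`, `U` uniform) with a warning. Tiny negative
#' entries from the eigendecomposition (< 1e-10 in magnitude) are clamped to
#' zero before renormalising, and the result is polished by power iteration
#' to satisfy `pi P = pi` to 1e-12.
#'
#' @param P Row-stochastic square matrix (rows may be `NA` if undefined).
#' @return Named numeric vector summing to 1 with attribute `damped`.
#' @export
behavioural_budget <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (ncol(P) != n) stop("transition matrix must be square", call. = FALSE)
  undef <- apply(P, 1, function(r) any(!is.finite(r)))
  if (any(undef)) {
    warning("rows with no observed transitions replaced by uniform: ",
            paste(rownames(P)[undef], collapse = ", "))
    P[undef, ] <- 1 / n
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("matrix is not row-stochastic", call. = FALSE)
  }
  damped <- FALSE
  ev <- eigen(t(P))
  # periodic chains have a second eigenvalue on the unit circle
  mods <- Mod(ev$values)
  if (!.is_irreducible(P) || sum(mods > 1 - 1e-9) > 1) {
    warning("reducible or periodic chain: budget computed on damped matrix")
    P <- 0.999 * P + 0.001 / n
    ev <- eigen(t(P))
    damped <- TRUE
  }
  k <- which.min(abs(ev$values - 1))
  pi0 <- Re(ev$vectors[, k])
  if (sum(pi0) < 0) pi0 <- -pi0
  pi0[abs(pi0) < 1e-10] <- 0
  if (any(pi0 < 0)) pi0[pi0 < 0] <- 0
  pi0 <- pi0 / sum(pi0)
  # power-iteration polish to the fixed point
  for (iter in 1:200) {
    pi1 <- as.numeric(pi0 %*% P)
    pi1 <- pi1 / sum(pi1)
    if (max(abs(pi1 - pi0)) < 1e-14) { pi0 <- pi1; break }
    pi0 <- pi1
  }
  names(pi0) <- rownames(P)
  attr(pi0, "damped") <- damped
  pi0
}

#' Two-proportion Z-test (pooled variance, no continuity correction)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion; two-sided p-value from the standard normal. Equivalent to the
#' square root of the 2x2 chi-square statistic without continuity correction.
#'
#' @param x1,x2 Success counts.
#' @param n1,n2 Trial counts (positive).
#' @return List with `z`, `p_value`, the two proportions and a `degenerate`
#'   flag (pooled proportion 0 or 1, where `z` is defined as 0).
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive", call. = FALSE)
  p1 <- x1 / n1
  p2 <- x2 / n2
  prop_z_test(p1, n1, p2, n2)
}

#' Two-proportion Z-test from proportions
#'
#' Variant of [two_proportion_z_test()] taking proportions directly; used for
#' behavioural-budget comparisons, where the budget is a proportion and the
#' effective n is the number of transitions observed in the context.
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @param n1,n2 Effective sample sizes.
#' @return See [two_proportion_z_test()].
#' @export
prop_z_test <- function(p1, n1, p2, n2) {
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    return(list(z = 0, p_value = 1, p1 = p1, p2 = p2, degenerate = TRUE))
  }
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2,
       degenerate = FALSE)
}

#' Compare transition probabilities between the Low context and the others
#'
#' For every transition cell (i, j) and each non-baseline context, a
#' two-proportion Z-test compares `p_ij` between the contexts, with successes
#' `a_ij` and trials the row total of preceding state i. A cell is testable
#' only when `a_ij` exceeds `min_cell` in both contexts (sparse cells give
#' unstable proportions and are reported as untestable).
#'
#' @param counts 5 x 5 x 4 array from [transition_counts()].
#' @param baseline Baseline context name (default `"Low"`).
#' @param min_cell Cells must have counts strictly greater than this in both
#'   contexts to be tested (default 5).
#' @param p_adjust Multiplicity adjustment applied to the testable cells,
#'   as in [stats::p.adjust()]; `"none"` (default) mirrors uncorrected
#'   reporting, `"holm"` is available.
#' @return Data frame with one row per (context, from, to): counts, row
#'   totals, `testable`, `z`, `p_value` (`NA` when untestable) and
#'   `p_adjusted`.
#' @export
compare_transitions <- function(counts, baseline = "Low", min_cell = 5,
                                p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  contexts <- setdiff(dimnames(counts)[[3]], baseline)
  base <- counts[, , baseline]
  rows_base <- rowSums(base)
  out <- do.call(rbind, lapply(contexts, function(cx) {
    cmp <- counts[, , cx]
    rows_cmp <- rowSums(cmp)
    grid <- expand.grid(from = activity_states, to = activity_states,
                        stringsAsFactors = FALSE)
    grid$context <- cx
    grid$a_base <- base[cbind(grid$from, grid$to)]
    grid$n_base <- rows_base[grid$from]
    grid$a_cmp <- cmp[cbind(grid$from, grid$to)]
    grid$n_cmp <- rows_cmp[grid$from]
    grid$testable <- grid$a_base > min_cell & grid$a_cmp > min_cell
    grid$z <- NA_real_
    grid$p_value <- NA_real_
    for (r in which(grid$testable)) {
      zt <- two_proportion_z_test(grid$a_cmp[r], grid$n_cmp[r],
                                  grid$a_base[r], grid$n_base[r])
      grid$z[r] <- zt$z
      grid$p_value[r] <- zt$p_value
    }
    grid
  }))
  out$p_adjusted <- out$p_value
  if (p_adjust != "none") {
    idx <- !is.na(out$p_value)
    out$p_adjusted[idx] <- stats::p.adjust(out$p_value[idx], method = p_adjust)
  }
  rownames(out) <- NULL
  out[, c("context", "from", "to", "a_base", "n_base", "a_cmp", "n_cmp",
          "testable", "z", "p_value", "p_adjusted")]
}

#' Compare behavioural budgets between the Low context and the others
#'
#' Per state and non-baseline context, a two-proportion Z-test of the budget
#' proportion against the baseline budget. The effective n for each context
#' is the number of transitions observed in it, the information that
#' actually entered the budget estimate; contexts with few transitions are
#' flagged `low_n`.
#'
#' @param budgets Named list of budget vectors (one per context), as from
#'   [behavioural_budget()].
#' @param n_per_context Named integer vector: transitions observed per
#'   context.
#' @param baseline Baseline context (default `"Low"`).
#' @param low_n_threshold Contexts with fewer transitions than this are
#'   flagged (default 30).
#' @return Data frame with `context`, `state`, `pi_base`, `pi_cmp`, `n_base`,
#'   `n_cmp`, `z`, `p_value`, `low_n`.
#' @export
compare_budgets <- function(budgets, n_per_context, baseline = "Low",
                            low_n_threshold = 30) {
  contexts <- setdiff(names(budgets), baseline)
  pb <- budgets[[baseline]]
  nb <- n_per_context[[baseline]]
  out <- do.call(rbind, lapply(contexts, function(cx) {
    pc <- budgets[[cx]]
    nc <- n_per_context[[cx]]
    res <- lapply(names(pb), function(st) {
      zt <- prop_z_test(pc[[st]], nc, pb[[st]], nb)
      data.frame(context = cx, state = st, pi_base = pb[[st]],
                 pi_cmp = pc[[st]], n_base = nb, n_cmp = nc,
                 z = zt$z, p_value = zt$p_value,
                 low_n = nc < low_n_threshold | nb < low_n_threshold)
    })
    do.call(rbind, res)
  }))
  rownames(out) <- NULL
  out
}

#' Full Markov-chain behavioural analysis of a 5-min sample table
#'
#' Convenience pipeline: extract transitions, tabulate by context, compute
#' transition matrices and stationary budgets, and run the Z-test comparisons
#' of transition probabilities and budgets against the Low context.
#'
#' @inheritParams extract_transitions
#' @param min_cell Passed to [compare_transitions()].
#' @return List with `transitions`, `counts`, `matrices`, `budgets`,
#'   `n_per_context`, `transition_tests`, `budget_tests`, `cutoff`.
#' @export
markov_analysis <- function(samples, cutoff = 3, interval = 300, min_cell = 5) {
  if (identical(cutoff, "median")) cutoff <- estimate_cutoff(samples$vessel_count)
  tr <- extract_transitions(samples, cutoff = cutoff, interval = interval)
  a <- transition_counts(tr)
  mats <- transition_probabilities(a)
  n_ctx <- vapply(vessel_contexts, function(cx) sum(a[, , cx]), numeric(1))
  budgets <- lapply(mats, function(P) suppressWarnings(behavioural_budget(P)))
  list(transitions = tr, counts = a, matrices = mats, budgets = budgets,
       n_per_context = n_ctx,
       transition_tests = compare_transitions(a),
       budget_tests = compare_budgets(budgets, as.list(n_ctx)),
       cutoff = cutoff)
}
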