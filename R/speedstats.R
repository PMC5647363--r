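# Rank-based comparison of 5-min average movement speeds across activity
# states and between low/high vessel densities.

#' Kruskal-Wallis rank test across groups
#'
#' Wrapper around [stats::kruskal.test()] returning the tie-corrected H
#' statistic, its degrees of freedom (k - 1) and the chi-square upper-tail
#' p-value. When every value in every group is identical the statistic is
#' defined as 0 (p = 1).
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  x <- unlist(groups)
  if (length(x) < 3) stop("need total n >= 3", call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1) {
    return(list(H = 0, df = length(groups) - 1, p_value = 1, n = length(x)))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(x))
}

#' Mann-Whitney U test (two-sided)
#'
#' Computes `U = min(U_x, U_y)` from midranks (ties count one half) and the
#' two-sided p-value via [stats::wilcox.test()]: exact by enumeration when
#' `n_x * n_y <= 400` and there are no ties, otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) p-value;
#'   `NULL` (default) applies the rule above.
#' @return List with `U`, `U_x`, `U_y`, `p_value`, `exact`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- (nx * ny <= 400) && !ties
  if (exact && ties) exact <- FALSE  # exact null invalid under ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = min(ux, uy), U_x = ux, U_y = uy, p_value = wt$p.value,
       exact = exact)
}

#' Speed comparison report across activity states and vessel densities
#'
#' Runs (1) the omnibus Kruskal-Wallis test of mean 5-min speed across
#' activity states, (2) pairwise Mann-Whitney tests between states, and
#' (3) per-state Mann-Whitney tests of low versus high vessel density. All
#' tests are two-sided and uncorrected by default (a Holm adjustment is
#' available); cells with a minimum n at or below `caution_n` carry a
#' small-sample caution flag, and comparisons with fewer than 2 observations
#' in a cell are flagged untestable rather than tested.
#'
#' @param samples Data frame with `activity_state`,
#'   `vessel_density_class` (`"low"`/`"high"`) and `mean_speed` (> 0 m/s).
#' @param p_adjust `"none"` (default) or `"holm"`, applied within each test
#'   family.
#' @param caution_n Cells with n at or below this are flagged (default 10).
#' @return Data frame with columns `test` (`omnibus`, `state_pair`,
#'   `density_within_state`), `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `df`, `p_value`, `p_adjusted`, `tested`, `caution`.
#' @export
speed_comparison_report <- function(samples, p_adjust = c("none", "holm"),
                                    caution_n = 10) {
  p_adjust <- match.arg(p_adjust)
  samples <- samples[is.finite(samples$mean_speed), ]
  states <- intersect(activity_states, unique(samples$activity_state))
  rows <- list()
  # omnibus across states
  if (length(states) >= 2) {
    grp <- split(samples$mean_speed, factor(samples$activity_state, states))
    kw <- kruskal_wallis(grp)
    rows[[length(rows) + 1]] <- data.frame(
      test = "omnibus", group1 = "all_states", group2 = "",
      n1 = kw$n, n2 = NA_real_, statistic = kw$H, df = kw$df,
      p_value = kw$p_value, tested = TRUE,
      caution = min(lengths(grp)) <= caution_n)
  } else {
    rows[[length(rows) + 1]] <- data.frame(
      test = "omnibus", group1 = "all_states", group2 = "",
      n1 = nrow(samples), n2 = NA_real_, statistic = NA_real_, df = NA_real_,
      p_value = NA_real_, tested = FALSE, caution = TRUE)
  }
  # pairwise between states
  if (length(states) >= 2) {
    prs <- utils::combn(states, 2)
    for (k in seq_len(ncol(prs))) {
      a <- samples$mean_speed[samples$activity_state == prs[1, k]]
      b <- samples$mean_speed[samples$activity_state == prs[2, k]]
      tested <- length(a) >= 2 && length(b) >= 2
      mw <- if (tested) mann_whitney_u(a, b) else NULL
      rows[[length(rows) + 1]] <- data.frame(
        test = "state_pair", group1 = prs[1, k], group2 = prs[2, k],
        n1 = length(a), n2 = length(b),
        statistic = if (tested) mw$U else NA_real_, df = NA_real_,
        p_value = if (tested) mw$p_value else NA_real_, tested = tested,
        caution = min(length(a), length(b)) <= caution_n)
    }
  }
  # low vs high vessel density within each state
  for (st in states) {
    a <- samples$mean_speed[samples$activity_state == st &
                              samples$vessel_density_class == "low"]
    b <- samples$mean_speed[samples$activity_state == st &
                              samples$vessel_density_class == "high"]
    tested <- length(a) >= 2 && length(b) >= 2
    mw <- if (tested) mann_whitney_u(a, b) else NULL
    rows[[length(rows) + 1]] <- data.frame(
      test = "density_within_state", group1 = paste0(st, ":low"),
      group2 = paste0(st, ":high"), n1 = length(a), n2 = length(b),
      statistic = if (tested) mw$U else NA_real_, df = NA_real_,
      p_value = if (tested) mw$p_value else NA_real_, tested = tested,
      caution = min(length(a), length(b)) <= caution_n)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- out$p_value
  if (p_adjust != "none") {
    for (fam in unique(out$test)) {
      idx <- out$test == fam & !is.na(out$p_value)
      out$p_adjusted[idx] <- stats::p.adjust(out$p_value[idx], method = p_adjust)
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify vessel density of speed samples
#'
#' Maps vessel counts to the `low`/`high` classes with the operational
#' cutoff (low: 0 to cutoff; high: above the cutoff).
#'
#' @param counts Integer vessel counts.
#' @param cutoff Density cutoff (default 3).
#' @return Character vector `"low"`/`"high"`.
#' @export
vessel_density_class <- function(counts, cutoff = 3) {
  ifelse(counts > cutoff, "high", "low")
}
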