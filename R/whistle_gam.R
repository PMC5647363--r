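# Per-characteristic GAMs for whistle responses: family assignment, VIF
# screening of noise covariates, all-subsets AICc/wAICc selection,
# overdispersion and semivariogram diagnostics, Tukey activity contrasts.

#' The eleven whistle characteristics
#'
#' Six continuous measures (duration and five frequency characteristics),
#' four shape counts, and the presence of harmonics.
#' @export
whistle_characteristics <- c(
  "duration", "freq_min", "freq_max", "freq_delta", "freq_start", "freq_end",
  "inflections", "extrema", "breaks", "saddles", "harmonics"
)

#' Error family for a whistle characteristic
#'
#' Harmonics presence/absence is modelled with a logit-link binomial; the
#' shape counts (inflection points, extrema, breaks, saddles) with a
#' log-link Poisson; the continuous duration and frequency measures with a
#' log-link gamma.
#'
#' @param response One of [whistle_characteristics].
#' @return A [stats::family] object.
#' @export
family_for <- function(response) {
  if (!response %in% whistle_characteristics) {
    stop("unknown whistle characteristic: ", response, call. = FALSE)
  }
  if (response == "harmonics") return(stats::binomial(link = "logit"))
  if (response %in% c("inflections", "extrema", "breaks", "saddles")) {
    return(stats::poisson(link = "log"))
  }
  stats::Gamma(link = "log")
}

#' Screen covariates for collinearity by iterative VIF removal
#'
#' The variance inflation factor of covariate j is `1 / (1 - R2_j)` where
#' `R2_j` is from the linear regression of j on the other covariates.
#' The covariate with the highest VIF is removed repeatedly until all VIFs
#' fall below the threshold (5, the conventional concurvity screen for noise
#' covariates). Constant covariates are removed first with a warning.
#'
#' @param covariates Data frame of numeric covariates (>= 2 columns).
#' @param threshold VIF threshold (default 5).
#' @return List with `retained` (column names), `dropped`, and `vif`
#'   (final VIFs of the retained set).
#' @export
screen_collinearity <- function(covariates, threshold = 5) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least 2 covariates", call. = FALSE)
  const <- vapply(covariates, function(x) stats::var(x) == 0, logical(1))
  if (any(const)) {
    warning("constant covariates removed: ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  dropped <- character(0)
  vifs_of <- function(X) {
    vapply(seq_len(ncol(X)), function(j) {
      r2 <- summary(stats::lm(X[[j]] ~ ., data = X[, -j, drop = FALSE]))$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  while (ncol(covariates) >= 2) {
    v <- vifs_of(covariates)
    names(v) <- names(covariates)
    if (max(v) < threshold) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    covariates <- covariates[, setdiff(names(covariates), worst), drop = FALSE]
  }
  v <- if (ncol(covariates) >= 2) {
    stats::setNames(vifs_of(covariates), names(covariates))
  } else {
    stats::setNames(rep(1, ncol(covariates)), names(covariates))
  }
  list(retained = names(covariates), dropped = dropped, vif = v)
}

# build a gam formula from a term subset
.gam_formula <- function(response, terms, noise_var, k = 5) {
  rhs <- character(0)
  if ("activity" %in% terms) rhs <- c(rhs, "activity_state")
  if ("calf" %in% terms) rhs <- c(rhs, "calf_present")
  if ("group_size" %in% terms) rhs <- c(rhs, "group_size")
  if ("noise" %in% terms) rhs <- c(rhs, sprintf("s(%s, k = %d)", noise_var, k))
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit one candidate GAM for a whistle characteristic
#'
#' Penalised-spline smooth for the noise term (thin-plate basis, dimension 5,
#' smoothing parameter by GCV), activity state and calf presence as factors,
#' group size linear. Non-convergence returns `NULL`.
#'
#' @param records Whistle records (one row per whistle) with the response
#'   column, `activity_state`, `calf_present`, `group_size` and the noise
#'   covariate.
#' @param response One of [whistle_characteristics].
#' @param terms Character subset of
#'   `c("activity", "calf", "group_size", "noise")`.
#' @param noise_var Name of the noise covariate column (default `"nl_bb"`).
#' @param k Smooth basis dimension.
#' @return A fitted `mgcv::gam` object, or `NULL` on failure.
#' @export
fit_candidate <- function(records, response, terms, noise_var = "nl_bb",
                          k = 5) {
  records <- as.data.frame(records)
  records$activity_state <- factor(records$activity_state)
  records$calf_present <- factor(as.integer(records$calf_present))
  fam <- family_for(response)
  if (fam$family == "Gamma" && any(records[[response]] <= 0)) {
    stop("gamma-family response must be strictly positive", call. = FALSE)
  }
  fml <- .gam_formula(response, terms, noise_var, k)
  fit <- try(mgcv::gam(fml, family = fam, data = records, method = "GCV.Cp"),
             silent = TRUE)
  if (inherits(fit, "try-error") || !fit$converged) return(NULL)
  fit
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)` with `k` the parameter count
#' including the effective degrees of freedom of any smooths. Returns `Inf`
#' when `n <= k + 1`.
#'
#' @param model A fitted model with [stats::logLik()] support.
#' @return Numeric AICc.
#' @export
aicc <- function(model) {
  ll <- stats::logLik(model)
  k <- attr(ll, "df")
  n <- stats::nobs(model)
  if (n - k - 1 <= 0) return(Inf)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights for a set of AICc scores
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values Numeric vector of AICc scores.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' All-subsets AICc model selection for one whistle characteristic
#'
#' Fits the 16 candidates formed by all subsets of
#' {activity, calf, group_size, s(noise)}, scores each by AICc, computes
#' Akaike weights, and returns the maximum-weight model (several candidates
#' within 2 AICc units of the best are equally plausible; the weight breaks
#' the tie, and an exact weight tie goes to the model with fewer
#' parameters).
#'
#' @inheritParams fit_candidate
#' @return List with `table` (terms, df, logLik, AICc, delta, weight,
#'   converged), `best` (the chosen fitted model), `best_terms`.
#' @export
select_model <- function(records, response, noise_var = "nl_bb", k = 5) {
  all_terms <- c("activity", "calf", "group_size", "noise")
  subsets <- lapply(0:15, function(m) all_terms[bitwAnd(m, 2^(0:3)) > 0])
  fits <- lapply(subsets, function(tm) {
    fit_candidate(records, response, tm, noise_var, k)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no candidate model converged", call. = FALSE)
  tab <- data.frame(
    terms = vapply(subsets, function(tm) paste(tm, collapse = "+"), character(1)),
    df = NA_real_, logLik = NA_real_, AICc = Inf, converged = ok
  )
  tab$terms[tab$terms == ""] <- "(intercept)"
  for (i in which(ok)) {
    ll <- stats::logLik(fits[[i]])
    tab$df[i] <- attr(ll, "df")
    tab$logLik[i] <- as.numeric(ll)
    tab$AICc[i] <- aicc(fits[[i]])
  }
  tab$delta <- tab$AICc - min(tab$AICc[ok])
  tab$weight <- 0
  tab$weight[ok] <- akaike_weights(tab$AICc[ok])
  best_w <- max(tab$weight)
  cand <- which(tab$weight > best_w - 1e-9)
  best <- cand[which.min(tab$df[cand])]  # weight tie -> fewer parameters
  list(table = tab, best = fits[[best]], best_terms = subsets[[best]])
}

#' Overdispersion statistic of a fitted model
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom `n - k` (k including effective df of smooths). Values near 1
#' indicate the assumed mean-variance relation holds.
#'
#' @param model Fitted `gam`/`glm`.
#' @param denominator `"residual_df"` (default, `n - k`) or `"n_minus_k_alt"`
#'   for the reading `sum(r^2)/n - k`.
#' @return Numeric ratio (`NA` with a warning if `n <= k`).
#' @export
overdispersion <- function(model, denominator = c("residual_df", "n_minus_k_alt")) {
  denominator <- match.arg(denominator)
  r <- stats::residuals(model, type = "pearson")
  n <- length(r)
  k <- attr(stats::logLik(model), "df")
  if (denominator == "n_minus_k_alt") return(sum(r^2) / n - k)
  if (n <= k) {
    warning("no residual degrees of freedom; overdispersion undefined")
    return(NA_real_)
  }
  sum(r^2) / (n - k)
}

#' Tukey-style pairwise activity-state contrasts from a fitted model
#'
#' All pairwise differences of activity-state effects on the linear-predictor
#' scale, with single-step (max-modulus) multiplicity-adjusted p-values via
#' \pkg{multcomp}; falls back to Bonferroni if the simultaneous computation
#' fails.
#'
#' @param model Fitted model containing `activity_state` as a factor term.
#' @return Data frame with `contrast`, `estimate`, `se`, `z`, `p_adjusted`,
#'   and attribute `adjustment`.
#' @export
posthoc_activity <- function(model) {
  cf <- stats::coef(model)
  lev <- levels(model$model$activity_state)
  if (is.null(lev) || length(lev) < 2) {
    stop("model does not contain activity_state as a factor with >= 2 levels",
         call. = FALSE)
  }
  eff_name <- function(l) paste0("activity_state", l)
  pairs <- utils::combn(lev, 2)
  K <- matrix(0, ncol(pairs), length(cf),
              dimnames = list(paste(pairs[2, ], "-", pairs[1, ]), names(cf)))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (eff_name(b) %in% names(cf)) K[j, eff_name(b)] <- 1
    if (eff_name(a) %in% names(cf)) K[j, eff_name(a)] <- -1
  }
  est <- as.numeric(K %*% cf)
  V <- stats::vcov(model)
  se <- sqrt(diag(K %*% V %*% t(K)))
  z <- est / se
  adj <- "single-step"
  p <- tryCatch({
    g <- multcomp::glht(model, linfct = K)
    summary(g)$test$pvalues
  }, error = function(e) {
    adj <<- "bonferroni"
    pmin(1, 2 * stats::pnorm(-abs(z)) * length(z))
  })
  out <- data.frame(contrast = rownames(K), estimate = est, se = se, z = z,
                    p_adjusted = as.numeric(p))
  rownames(out) <- NULL
  attr(out, "adjustment") <- adj
  out
}

#' Empirical semivariogram of residuals over time
#'
#' `gamma(h) = sum_{pairs in bin h} (r_i - r_j)^2 / (2 N(h))`; a flat
#' semivariogram at the residual variance indicates no temporal
#' autocorrelation.
#'
#' @param residuals Numeric residuals (standardised or Pearson).
#' @param timestamps Observation times, seconds.
#' @param breaks Lag-bin boundaries in seconds, or a number of equal-width
#'   bins (default 10).
#' @return Data frame with `lag` (bin midpoint), `semivariance`, `n_pairs`
#'   (0 for empty bins, `NA` semivariance).
#' @export
residual_semivariogram <- function(residuals, timestamps, breaks = 10) {
  n <- length(residuals)
  if (n < 10) stop("need at least 10 residuals", call. = FALSE)
  stopifnot(length(timestamps) == n)
  dmat <- abs(outer(timestamps, timestamps, "-"))
  sq <- outer(residuals, residuals, "-")^2
  h <- dmat[upper.tri(dmat)]
  s <- sq[upper.tri(sq)]
  if (length(breaks) == 1) breaks <- seq(0, max(h), length.out = breaks + 1)
  bin <- cut(h, breaks, include.lowest = TRUE)
  npairs <- as.integer(table(bin))
  gam <- as.numeric(tapply(s, bin, sum)) / (2 * npairs)
  gam[npairs == 0] <- NA_real_
  data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
             semivariance = gam, n_pairs = npairs)
}

#' Full GAM protocol for the whistle characteristics
#'
#' For each requested characteristic: skip count responses observed in fewer
#' than `min_count_n` whistles; remove outliers once (absolute Pearson
#' residual above `outlier_threshold` under the full candidate); run
#' all-subsets AICc selection; compute the overdispersion ratio; and, when
#' activity state is retained, the Tukey activity contrasts.
#'
#' @param records Whistle records (features joined to context and noise), as
#'   built from [extract_features_all()] and [pair_whistles()].
#' @param responses Character vector of characteristics, or `"all"`.
#' @param noise_var Noise covariate column to use as the smooth term
#'   (alternative noise representations are modelled separately, never
#'   together).
#' @param outlier_threshold Absolute Pearson residual cutoff (default 4).
#' @param min_count_n Minimum number of whistles exhibiting a count
#'   characteristic for it to be modelled (default 20).
#' @param k Smooth basis dimension.
#' @return List with per-response results (`selection`, `model`,
#'   `overdispersion`, `posthoc`, `n_outliers`, `skipped`) plus bookkeeping
#'   `n_records`, `n_outliers_total`.
#' @export
fit_whistle_gams <- function(records, responses = "all", noise_var = "nl_bb",
                             outlier_threshold = 4, min_count_n = 20, k = 5) {
  if (identical(responses, "all")) responses <- whistle_characteristics
  records <- as.data.frame(records)
  out <- list(n_records = nrow(records), results = list())
  n_outliers_total <- 0L
  for (resp in responses) {
    if (!resp %in% names(records)) {
      out$results[[resp]] <- list(skipped = "response_missing")
      next
    }
    fam <- family_for(resp)
    if (fam$family == "poisson" && sum(records[[resp]] > 0) < min_count_n) {
      out$results[[resp]] <- list(
        skipped = sprintf("fewer than %d whistles exhibit this count", min_count_n))
      next
    }
    dat <- records
    full <- fit_candidate(dat, resp, c("activity", "calf", "group_size", "noise"),
                          noise_var, k)
    n_out <- 0L
    if (!is.null(full)) {
      pr <- stats::residuals(full, type = "pearson")
      drop <- abs(pr) > outlier_threshold
      n_out <- sum(drop)
      if (n_out > 0) dat <- dat[!drop, ]
    }
    sel <- select_model(dat, resp, noise_var, k)
    ph <- if ("activity" %in% sel$best_terms) {
      tryCatch(posthoc_activity(sel$best), error = function(e) NULL)
    }
    out$results[[resp]] <- list(
      selection = sel$table, model = sel$best, best_terms = sel$best_terms,
      overdispersion = overdispersion(sel$best), posthoc = ph,
      n_outliers = n_out, n_modelled = nrow(dat), skipped = NA_character_)
    n_outliers_total <- n_outliers_total + n_out
  }
  out$n_outliers_total <- n_outliers_total
  out
}
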