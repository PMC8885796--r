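# Cohort association and survival statistics.
#
# Conventions follow the SPSS defaults used in the clinical literature this
# package targets: Pearson chi-square without continuity correction,
# Mann-Whitney normal z with tie-corrected variance and no continuity
# correction, Breslow = generalized-Wilcoxon weights n_i, Tarone-Ware
# weights sqrt(n_i), all tests two-sided. Standard engines (stats::,
# survival::) sit behind the module API; the weighted log-rank family and
# the trend chi-square are computed here because no installed engine
# exposes those exact weights.

.test_result <- function(statistic, df, p_value, method, ...) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method, ...),
            class = "til_test")
}

#' @export
print.til_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 6),
      if (!is.null(x$df) && !is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

.check_table <- function(tab, min_dim = 2L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) < min_dim || ncol(tab) < min_dim)
    stop("contingency table must be at least ", min_dim, "x", min_dim)
  if (sum(tab) == 0) stop("degenerate-table: grand total is zero")
  tab
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; p-value from the chi-square upper tail.
#'
#' @param tab contingency table (matrix of counts, at least 2x2).
#' @return a `til_test` with `statistic`, `df`, `p_value`, and `expected`.
#' @export
pearson_chi_square <- function(tab) {
  tab <- .check_table(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate-table: zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .test_result(ct$statistic, ct$parameter, ct$p.value,
               "Pearson chi-square", expected = ct$expected)
}

#' Chi-square test for trend (linear-by-linear association)
#'
#' For a 2 x k table with ordinal column scores: statistic = (N - 1) r^2,
#' where r is the Pearson correlation between the row indicator and the
#' column score over the N underlying observations; df = 1.
#'
#' @param tab 2 x k table of counts.
#' @param scores numeric column scores (default `1:k`).
#' @return a `til_test`.
#' @export
chi_square_trend <- function(tab, scores = seq_len(ncol(tab))) {
  tab <- .check_table(tab)
  if (nrow(tab) != 2L) stop("trend test expects a 2 x k table")
  if (length(scores) != ncol(tab)) stop("need one score per column")
  if (length(unique(scores)) < 2L) stop("column scores must not be constant")
  n <- sum(tab)
  col_tot <- colSums(tab)
  row1 <- tab[2L, ]                     # indicator: membership of row 2
  # moments of (indicator, score) over the N observations
  p1 <- sum(row1) / n
  mean_s <- sum(col_tot * scores) / n
  var_s <- sum(col_tot * (scores - mean_s)^2) / n
  var_i <- p1 * (1 - p1)
  cov_is <- sum(row1 * scores) / n - p1 * mean_s
  if (var_s == 0 || var_i == 0) {
    stat <- 0
  } else {
    stat <- (n - 1) * cov_is^2 / (var_i * var_s)
  }
  .test_result(stat, 1L, stats::pchisq(stat, 1L, lower.tail = FALSE),
               "Chi-square test for trend (linear-by-linear)")
}

#' Fisher's exact test
#'
#' Two-sided. 2x2 tables are evaluated exactly (sum of hypergeometric
#' probabilities of tables no more probable than the observed one); larger
#' tables fall back from exact network evaluation to seeded Monte-Carlo
#' (1e5 tables) when the exact computation is infeasible.
#'
#' @param tab contingency table of counts.
#' @param B Monte-Carlo replicates for large tables.
#' @param seed RNG seed for the Monte-Carlo path (ignored otherwise).
#' @return a `til_test` (df is `NA`; the statistic slot carries the
#'   two-sided p-value's complement-free observed-table probability is not
#'   reported, statistic is `NA` as is conventional for exact tests).
#' @export
fisher_exact <- function(tab, B = 1e5, seed = NULL) {
  tab <- .check_table(tab)
  res <- tryCatch(
    stats::fisher.test(tab, workspace = 2e7),
    error = function(e) {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(seed)
      }
      stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
    })
  .test_result(NA_real_, NA_integer_, res$p.value, res$method)
}

#' Kruskal-Wallis H test
#'
#' Rank-based k-sample test with tie correction; df = k - 1.
#'
#' @param samples list of k >= 2 numeric vectors, all non-empty.
#' @return a `til_test`.
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) stop("need a list of >= 2 groups")
  if (any(vapply(samples, length, integer(1)) == 0L)) stop("empty-group: all groups must be non-empty")
  if (sum(lengths(samples)) < 3L) stop("need at least 3 observations in total")
  x <- unlist(samples, use.names = FALSE)
  if (length(unique(x)) == 1L)               # all ties: no separation possible
    return(.test_result(0, length(samples) - 1L, 1, "Kruskal-Wallis H"))
  kt <- stats::kruskal.test(samples)
  .test_result(kt$statistic, kt$parameter, kt$p.value, "Kruskal-Wallis H")
}

#' Mann-Whitney U test with normal z
#'
#' Reports U for the first sample, the tie-corrected normal-approximation z
#' without continuity correction (the convention under which published z
#' values such as -3.455 are computed), and the two-sided p. The sign of z
#' follows the rank sum of `a` relative to `b`.
#'
#' @param a,b numeric samples (non-empty).
#' @return a `til_test` with extra elements `u` and `z`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    return(.test_result(u, NA_integer_, 1, "Mann-Whitney U",
                        u = u, z = NA_real_, undefined_z = TRUE))
  }
  z <- (u - n1 * n2 / 2) / sqrt(v)
  .test_result(u, NA_integer_, 2 * stats::pnorm(-abs(z)), "Mann-Whitney U",
               u = u, z = z, undefined_z = FALSE)
}

# ---- survival ---------------------------------------------------------------

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times in months (> 0).
#' @param event event indicator (1/TRUE = relapse or progression).
#' @return object of class `km_estimate`: data.frame `table` (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`), `median` (first time with
#'   S(t) <= 0.5, `NA` when never reached), and `surv_fn`, a right-
#'   continuous step function S(t) with S(0) = 1.
#' @export
km_estimator <- function(time, event) {
  if (any(time <= 0) || anyNA(time)) stop("times must be positive")
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  med <- tab$time[tab$surv <= 0.5][1L]
  sfun <- stats::stepfun(tab$time, c(1, tab$surv), right = FALSE)
  structure(list(table = tab, median = if (length(med)) med else NA_real_,
                 surv_fn = sfun, n = length(time), n_events = sum(event)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Weighted log-rank family (log-rank, Breslow, Tarone-Ware)
#'
#' At each distinct event time the weight is 1 (log-rank), the total
#' at-risk count n_i (Breslow / generalized Wilcoxon) or sqrt(n_i)
#' (Tarone-Ware). The statistic is the quadratic form of the weighted
#' observed-minus-expected vector with the hypergeometric covariance;
#' df = number of groups - 1.
#'
#' @param time,event survival data (times > 0).
#' @param group group labels (>= 2 groups).
#' @param scheme one of `"logrank"`, `"breslow"`, `"tarone_ware"`.
#' @return a `til_test` with extra elements `observed`, `expected` (per
#'   group, unweighted counts).
#' @export
weighted_logrank <- function(time, event, group,
                             scheme = c("logrank", "breslow", "tarone_ware")) {
  scheme <- match.arg(scheme)
  if (any(time <= 0) || anyNA(time)) stop("times must be positive")
  event <- as.integer(as.logical(event))
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("need at least two groups")
  if (sum(event) == 0L) stop("need at least one event")

  ev_times <- sort(unique(time[event == 1L]))
  gmat <- outer(group, levels(group), `==`) * 1   # n x k indicator
  U <- numeric(k); E <- numeric(k); O <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- time >= t
    n_i <- sum(at_risk)
    n_gi <- colSums(gmat[at_risk, , drop = FALSE])
    dead <- at_risk & time == t & event == 1L
    d_i <- sum(dead)
    d_gi <- colSums(gmat[dead, , drop = FALSE])
    e_gi <- d_i * n_gi / n_i
    w <- switch(scheme, logrank = 1, breslow = n_i, tarone_ware = sqrt(n_i))
    O <- O + d_gi; E <- E + e_gi
    U <- U + w * (d_gi - e_gi)
    if (n_i > 1L) {
      p <- n_gi / n_i
      Vt <- d_i * (n_i - d_i) / (n_i - 1) * (diag(p, nrow = k) - tcrossprod(p))
      V <- V + w^2 * Vt
    }
  }
  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(
    drop(t(U[idx]) %*% solve(Vsub, U[idx])),
    error = function(e) 0)                 # singular variance: no information
  method <- c(logrank = "Log-rank (Mantel-Cox)",
              breslow = "Breslow (generalized Wilcoxon)",
              tarone_ware = "Tarone-Ware")[[scheme]]
  .test_result(stat, k - 1L, stats::pchisq(stat, k - 1L, lower.tail = FALSE),
               method, observed = setNames(O, levels(group)),
               expected = setNames(E, levels(group)))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling. Reports per-covariate
#' hazard ratios with Wald confidence intervals and the global score test,
#' which for a single two-level group factor coincides with the log-rank
#' statistic.
#'
#' @param time,event survival data (times > 0, >= 1 event).
#' @param covariates data.frame of covariates (factors and numerics).
#' @param conf_level Wald CI level.
#' @return list with `coef` (data.frame: term, beta, hr, se, ci_lower,
#'   ci_upper, wald_p), `score_statistic`, `score_p`, `n`, `n_events` and
#'   the underlying `fit`.
#' @export
cox_ph <- function(time, event, covariates, conf_level = 0.95) {
  if (any(time <= 0) || anyNA(time)) stop("times must be positive")
  event <- as.integer(as.logical(event))
  if (sum(event) == 0L) stop("need at least one event")
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations", conditionMessage(w)))
        stop("non-convergence: monotone partial likelihood (complete separation?)")
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15))
    stop("non-convergence: monotone partial likelihood (complete separation?)")
  s <- summary(fit, conf.int = conf_level)
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(coef = data.frame(term = names(beta), beta = unname(beta),
                         hr = exp(unname(beta)), se = unname(se),
                         ci_lower = exp(unname(beta) - zq * se),
                         ci_upper = exp(unname(beta) + zq * se),
                         wald_p = 2 * stats::pnorm(-abs(unname(beta) / se))),
       score_statistic = unname(s$sctest["test"]),
       score_p = unname(s$sctest["pvalue"]),
       n = fit$n, n_events = fit$nevent, fit = fit)
}

#' Median follow-up time
#'
#' The cohort-level follow-up summary: by default the plain median of the
#' observed times regardless of event status; optionally the reverse
#' Kaplan-Meier median (censoring-distribution median).
#'
#' @param time observed times.
#' @param event event indicator (used only by the reverse-KM method).
#' @param reverse_km use the reverse Kaplan-Meier estimator.
#' @return list with `median` and `iqr` (25th/75th percentiles; plain
#'   method only, `NA` otherwise).
#' @export
median_followup <- function(time, event = NULL, reverse_km = FALSE) {
  if (reverse_km) {
    if (is.null(event)) stop("reverse-KM needs the event indicator")
    km <- km_estimator(time, 1L - as.integer(as.logical(event)))
    return(list(median = km$median, iqr = c(NA_real_, NA_real_)))
  }
  q <- stats::quantile(time, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2L], iqr = q[c(1L, 3L)])
}

#' Optional Holm adjustment for a set of p-values
#'
#' Raw p-values are reported by default throughout the package; this helper
#' applies the Holm step-down correction when multiplicity control is
#' wanted on reuse.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
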