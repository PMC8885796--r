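test_that("Pearson chi-square matches hand computation", {
  expect_equal(pearson_chi_square(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(pearson_chi_square(matrix(c(10, 10, 10, 10), 2))$p_value, 1)
  # all expected counts are 10, |O-E| = 5 in each cell: 4 * 25/10 = 10
  r <- pearson_chi_square(matrix(c(5, 15, 15, 5), 2))
  expect_equal(r$statistic, 10.0)
  expect_equal(r$df, 1L)
  # invariant to row/column permutation
  tab <- matrix(c(3, 9, 5, 14, 2, 8), 2)
  expect_equal(pearson_chi_square(tab)$statistic,
               pearson_chi_square(tab[2:1, c(2, 3, 1)])$statistic)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("trend chi-square equals the expansion oracle", {
  tab <- rbind(c(1, 5, 9), c(9, 5, 1))
  # expand to 30 observations and compute (N-1) * cor^2 directly
  scores <- c(1, 2, 3)
  row_ind <- rep(rep(c(0, 1), each = 3), times = as.vector(t(tab)))
  col_sc <- rep(rep(scores, 2), times = as.vector(t(tab)))
  expected <- (30 - 1) * cor(row_ind, col_sc)^2
  expect_equal(chi_square_trend(tab, scores)$statistic, expected)
  # no trend in a homogeneous table
  expect_equal(chi_square_trend(rbind(c(10, 10, 10), c(10, 10, 10)))$statistic, 0)
  # reflection of the score order leaves the statistic unchanged
  expect_equal(chi_square_trend(tab[, 3:1], scores)$statistic,
               chi_square_trend(tab, scores)$statistic)
  expect_error(chi_square_trend(tab, c(2, 2, 2)), "constant")
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(0, 10, 10, 0), 2))$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # enumeration oracle: sum of P(table) over tables with P <= P(observed)
  tab <- matrix(c(2, 4, 6, 1), 2)
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(max(0, k - n2):min(k, m), m, n2, k)
  oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
  expect_equal(fisher_exact(tab)$p_value, oracle, tolerance = 1e-9)
  # hypergeometric pmf over all admissible tables sums to 1
  expect_equal(sum(probs), 1, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches the rank-sum hand computation", {
  expect_equal(kruskal_wallis(list(1:3, 4:6, 7:9))$statistic, 7.2)
  expect_equal(kruskal_wallis(list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))$statistic, 0)
  # two-group H equals the squared tie-corrected Mann-Whitney z
  set.seed(31)
  a <- round(rnorm(12, 5), 1); b <- round(rnorm(15, 6), 1)
  h <- kruskal_wallis(list(a, b))$statistic
  z <- mann_whitney(a, b)$z
  expect_equal(h, z^2, tolerance = 1e-9)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty-group")
})

test_that("Mann-Whitney z follows the SPSS convention", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$z, -4.5 / sqrt(5.25), tolerance = 1e-9)
  expect_equal(r$p_value, 2 * pnorm(-abs(r$z)))
  # symmetric samples give z = 0; swapping samples negates z
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$z, 0)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$z, -r$z)
  # all values identical: undefined z, p = 1
  deg <- mann_whitney(c(2, 2), c(2, 2, 2))
  expect_true(deg$undefined_z)
  expect_equal(deg$p_value, 1)
})

test_that("Kaplan-Meier estimate matches the product-limit hand computation", {
  km <- km_estimator(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv_fn(0.5), 1)
  expect_equal(km$surv_fn(1), 2 / 3)
  expect_equal(km$surv_fn(2.5), 2 / 3)   # censoring does not drop S
  expect_equal(km$surv_fn(3), 0)
  expect_equal(km$median, 3)
  # all censored: S identically 1, median undefined
  km2 <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$table$surv == 1))
  expect_true(is.na(km2$median))
  # no censoring: S equals the empirical survival fraction
  tt <- c(2, 4, 6, 8)
  km3 <- km_estimator(tt, rep(1, 4))
  expect_equal(km3$table$surv, 1 - seq(0.25, 1, 0.25))
  expect_error(km_estimator(c(0, 1), c(1, 1)), "positive")
})

test_that("weighted log-rank family matches the risk-table oracle", {
  # identical groups: zero for every scheme
  t0 <- rep(c(1, 2, 3, 4), 2); e0 <- rep(1, 8); g0 <- rep(c("A", "B"), each = 4)
  for (s in c("logrank", "breslow", "tarone_ware"))
    expect_equal(weighted_logrank(t0, e0, g0, s)$statistic, 0, tolerance = 1e-12)
  # worked two-group example: O-E = 7/6, V = 17/36
  t1 <- c(1, 2, 3, 4); e1 <- rep(1, 4); g1 <- c("A", "A", "B", "B")
  lr <- weighted_logrank(t1, e1, g1, "logrank")
  expect_equal(lr$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-9)
  expect_equal(lr$statistic, 2.882, tolerance = 1e-3)
  # independent engine agreement for the log-rank member
  sd <- survival::survdiff(survival::Surv(t1, e1) ~ g1)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
  # risk-table oracle for the weighted members
  oracle <- function(w) {
    # event times 1..4, group A at risk: 2,1,0,0; totals 4,3,2,1
    nA <- c(2, 1, 0, 0); n <- c(4, 3, 2, 1); dA <- c(1, 1, 0, 0)
    u <- sum(w * (dA - nA / n))
    v <- sum(w^2 * (nA / n) * (1 - nA / n))  # d_i = 1 at each time
    u^2 / v
  }
  br <- weighted_logrank(t1, e1, g1, "breslow")
  tw <- weighted_logrank(t1, e1, g1, "tarone_ware")
  expect_equal(br$statistic, oracle(c(4, 3, 2, 1)), tolerance = 1e-9)
  expect_equal(tw$statistic, oracle(sqrt(c(4, 3, 2, 1))), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(br$statistic, lr$statistic)))
  expect_false(isTRUE(all.equal(br$statistic, tw$statistic)))
  # single event time: all three schemes coincide
  t2 <- c(5, 5, 5, 5); e2 <- c(1, 0, 0, 0); g2 <- c("A", "A", "B", "B")
  stats <- sapply(c("logrank", "breslow", "tarone_ware"), function(s)
    weighted_logrank(t2, e2, g2, s)$statistic)
  expect_equal(max(stats) - min(stats), 0, tolerance = 1e-12)
  expect_error(weighted_logrank(t1, e1, rep("A", 4)), "two groups")
})

test_that("three-group weighted log-rank agrees with survdiff", {
  set.seed(41)
  tt <- rexp(60, rate = rep(c(0.1, 0.15, 0.2), each = 20))
  ee <- rbinom(60, 1, 0.8)
  gg <- rep(c("A", "B", "C"), each = 20)
  lr <- weighted_logrank(tt, ee, gg, "logrank")
  sd <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  expect_equal(lr$df, 2L)
})

test_that("Cox model recovers hazard ratios and reproduces the log-rank score", {
  # null effect
  t0 <- rep(c(1, 2, 3, 4, 5), 2); e0 <- rep(1, 10)
  g0 <- rep(c("A", "B"), each = 5)
  fit0 <- cox_ph(t0, e0, data.frame(group = g0))
  expect_lt(abs(fit0$coef$beta), 1e-8)
  expect_equal(fit0$coef$hr, 1, tolerance = 1e-6)
  # score test at beta = 0 equals the log-rank statistic
  set.seed(51)
  tt <- rexp(80, rate = rep(c(0.1, 0.2), each = 40))
  ee <- rbinom(80, 1, 0.7); gg <- rep(c("A", "B"), each = 40)
  keep <- tapply(ee, gg, sum) > 0
  fit <- cox_ph(tt, ee, data.frame(group = gg))
  lr <- weighted_logrank(tt, ee, gg, "logrank")
  expect_equal(fit$score_statistic, lr$statistic, tolerance = 1e-6)
  # parameter recovery: exponential data with true HR 2, ~50% events
  set.seed(61)
  n <- 2000
  x <- rep(0:1, each = n / 2)
  t_ev <- rexp(n, rate = 0.05 * 2^x)
  cens <- rexp(n, rate = 0.05)
  tt2 <- pmin(t_ev, cens); ee2 <- as.integer(t_ev <= cens)
  fit2 <- cox_ph(tt2, ee2, data.frame(x = x))
  expect_gt(fit2$coef$hr, 1.8)
  expect_lt(fit2$coef$hr, 2.2)
  # complete separation aborts
  expect_error(cox_ph(c(1, 2, 3, 10, 11, 12), rep(1, 6),
                      data.frame(x = rep(c(1, 0), each = 3))),
               "non-convergence")
})

test_that("median follow-up summarizes observed times", {
  mf <- median_followup(c(10, 20, 30, 40, 50))
  expect_equal(mf$median, 30)
  expect_equal(mf$iqr, c(20, 40))
  rk <- median_followup(c(10, 20, 30, 40, 50), event = c(1, 1, 0, 0, 0),
                        reverse_km = TRUE)
  expect_equal(rk$median, 40)  # censoring-distribution median
})

test_that("Holm adjustment is monotone and conservative", {
  p <- c(0.01, 0.04, 0.03, 0.2)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"))
  expect_true(all(holm_adjust(p) >= p))
})
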