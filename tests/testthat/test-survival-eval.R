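test_that("concordance index handles perfect, tied and censored data", {
  d <- surv_data(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(concordance_index(c(4, 3, 2, 1), d), 1)
  expect_equal(concordance_index(rep(2, 4), d), 0.5)

  # fixed 6-patient instance with 2 censored vs exhaustive pair count
  t6 <- c(5, 8, 8, 12, 20, 25)
  e6 <- c(1, 1, 0, 1, 0, 1)
  s6 <- c(3.1, 2.0, 2.0, 1.4, 0.9, 0.5)
  d6 <- surv_data(t6, e6)
  expect_equal(concordance_index(s6, d6), brute_cindex(s6, t6, e6))

  expect_error(concordance_index(c(1, 2), surv_data(c(3, 4), c(0, 0))),
               "comparable")
})

test_that("concordance index is invariant to monotone score transforms", {
  set.seed(42)
  n <- 60
  tm <- rexp(n); ev <- rbinom(n, 1, 0.7); sc <- rnorm(n)
  d <- surv_data(tm, ev)
  base <- concordance_index(sc, d)
  expect_equal(concordance_index(exp(sc), d), base)
  expect_equal(concordance_index(5 * sc - 3, d), base)
  expect_equal(concordance_index(rank(sc), d), base)
})

test_that("concordance index matches the survival package", {
  skip_if_not_installed("survival")
  set.seed(7)
  n <- 100
  tm <- rexp(n); ev <- rbinom(n, 1, 0.6); sc <- rnorm(n)
  ours <- concordance_index(sc, surv_data(tm, ev))
  ref <- survival::concordance(survival::Surv(tm, ev) ~ sc,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  # one event among four
  km <- kaplan_meier(surv_data(c(1, 2, 3, 4), c(1, 0, 0, 0)))
  expect_equal(km$surv[1], 0.75)

  # all censored: flat at 1
  km2 <- kaplan_meier(surv_data(c(2, 4, 6), c(0, 0, 0)))
  expect_true(all(km2$surv == 1))

  # events at 2 and 4, censoring at 3 and 5:
  # S = 4/5, then 4/5*3/4 = 3/5, flat, then 3/5*1/2 = 3/10, flat
  km3 <- kaplan_meier(surv_data(c(1, 2, 3, 4, 5), c(1, 1, 0, 1, 0)))
  expect_equal(km3$surv, c(0.8, 0.6, 0.6, 0.3, 0.3))
  expect_true(all(diff(km3$surv) <= 0))

  # without censoring the curve is the empirical survival function
  set.seed(1)
  tm <- sort(sample(1:50, 12))
  km4 <- kaplan_meier(surv_data(tm, rep(1, 12)))
  expect_equal(km4$surv, 1 - seq_along(tm) / 12)
})

test_that("log-rank test: identical groups, hand computation, invariance", {
  d <- surv_data(c(2, 4, 6, 8), c(1, 1, 0, 1))
  same <- log_rank_test(d, d)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # hand-computed 2x4 toy: O, E and V accumulated over event times
  a <- surv_data(c(1, 3, 5, 7), c(1, 1, 0, 1))
  b <- surv_data(c(2, 4, 6, 8), c(0, 1, 1, 0))
  lr <- log_rank_test(a, b)
  # event times are 1, 3, 4, 6, 7; walking them by hand:
  # t=1: n=8,n_a=4,d=1,d_a=1: E+=0.5, V+=0.25
  # t=3: n=6,n_a=3,d=1,d_a=1: E+=0.5, V+=0.25
  # t=4: n=5,n_a=2,d=1,d_a=0: E+=0.4, V+=0.24
  # t=6: n=3,n_a=1,d=1,d_a=0: E+=1/3, V+=2/9
  # t=7: n=2,n_a=1,d=1,d_a=1: E+=0.5, V+=0.25
  expect_equal(lr$observed, 3)
  expect_equal(lr$expected, 0.5 + 0.5 + 0.4 + 1 / 3 + 0.5)
  expect_equal(lr$variance, 0.25 + 0.25 + 0.24 + 2 / 9 + 0.25)
  expect_equal(lr$statistic, (3 - lr$expected)^2 / lr$variance)

  # rank invariance under time scaling
  a2 <- surv_data(a$time * 7.3, a$event)
  b2 <- surv_data(b$time * 7.3, b$event)
  expect_equal(log_rank_test(a2, b2)$statistic, lr$statistic)

  expect_error(log_rank_test(surv_data(1, 0), surv_data(2, 0)), "events")
})

test_that("log-rank agrees with survdiff and with the normal deviate", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 50
  tma <- rexp(n); tmb <- rexp(n, 1.6)
  eva <- rbinom(n, 1, 0.8); evb <- rbinom(n, 1, 0.8)
  lr <- log_rank_test(surv_data(tma, eva), surv_data(tmb, evb))
  ref <- survival::survdiff(
    survival::Surv(c(tma, tmb), c(eva, evb)) ~ rep(0:1, each = n))
  expect_equal(lr$statistic, ref$chisq, tolerance = 1e-10)
  # chi-square(1) p equals the two-sided normal p of the z statistic
  expect_equal(lr$p_value, 2 * pnorm(-abs(lr$z)))
})

test_that("cox_fit maximizes the partial likelihood and reports Wald stats", {
  # binary covariate toy instance against a 1-D grid/optimize oracle
  tm <- c(2, 3, 5, 7, 11, 13, 17, 19)
  ev <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  d <- surv_data(tm, ev)
  fit <- cox_fit(x, d)
  oracle <- optimize(function(b) brute_cox_loglik(b, x, tm, ev),
                     c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(unname(fit$coefficients[1]), oracle, tolerance = 1e-4)
  expect_true(fit$converged)

  # definitional identities
  expect_equal(fit$hazard_ratios, exp(fit$coefficients))
  expect_equal(unname(fit$ci95[, 1]),
               unname(exp(fit$coefficients - 1.96 * fit$se)))
  expect_equal(unname(fit$ci95[, 2]),
               unname(exp(fit$coefficients + 1.96 * fit$se)))

  # null covariate: no signal, moderate z
  set.seed(5)
  n <- 150
  d2 <- surv_data(rexp(n), rbinom(n, 1, 0.7))
  f2 <- cox_fit(rnorm(n), d2)
  expect_lt(abs(f2$z[1]), 3)

  expect_error(cox_fit(rep(1, n), d2), "zero-variance")
})

test_that("cox_fit matches coxph with Breslow ties on multivariate data", {
  skip_if_not_installed("survival")
  set.seed(9)
  n <- 120
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tm <- rexp(n, exp(0.7 * X[, 1] - 0.5 * X[, 2]))
  tm <- round(tm, 2) + 0.01    # force some ties
  ev <- rbinom(n, 1, 0.75)
  fit <- cox_fit(X, surv_data(tm, ev))
  ref <- survival::coxph(survival::Surv(tm, ev) ~ X, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
})

test_that("time-dependent AUC equals exhaustive pair counting", {
  d <- surv_data(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(time_dependent_auc(c(9, 8, 1, 0), d, horizon = 2.5), 1)
  expect_equal(time_dependent_auc(rep(1, 4), d, horizon = 2.5), 0.5)

  # 8 patients, 2 censored (one before, one after the horizon)
  t8 <- c(3, 5, 7, 9, 12, 15, 20, 30)
  e8 <- c(1, 0, 1, 1, 0, 1, 1, 1)
  s8 <- c(2.5, 1.1, 2.0, 0.3, 0.8, 0.8, -0.2, -1.0)
  d8 <- surv_data(t8, e8)
  expect_equal(time_dependent_auc(s8, d8, horizon = 10),
               brute_tauc(s8, t8, e8, 10))

  # censored-before-horizon patients are excluded from both groups
  expect_error(time_dependent_auc(s8, d8, horizon = 40), "no controls")

  # beyond the last event, without censoring, this is the plain AUC of
  # event status -- all times <= horizon are cases, none are controls,
  # so check at a horizon separating events from survivors instead
  dd <- surv_data(c(1, 2, 3, 50, 60), c(1, 1, 1, 1, 1))
  sc <- c(3, 1, 2, 0.5, 0.1)
  expect_equal(time_dependent_auc(sc, dd, horizon = 10),
               brute_tauc(sc, dd$time, dd$event, 10))
})

test_that("optimal cutoff equals an exhaustive admissible scan", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 80
  sc <- rnorm(n)
  tm <- rexp(n, exp(1.5 * (sc > 0.3)))
  ev <- rbinom(n, 1, 0.8)
  d <- surv_data(tm, ev)
  res <- optimal_cutoff(sc, d, min_prop = 0.1)

  # independent scan using survdiff as the statistic engine
  us <- sort(unique(sc))
  cand <- (us[-1] + us[-length(us)]) / 2
  best <- -Inf; best_cut <- NA
  for (cc in cand) {
    lo <- sum(sc <= cc)
    if (lo < ceiling(0.1 * n) || n - lo < ceiling(0.1 * n)) next
    sd1 <- survival::survdiff(survival::Surv(tm, ev) ~ (sc <= cc))
    stat <- sqrt(sd1$chisq)
    if (stat > best + 1e-12) { best <- stat; best_cut <- cc }
  }
  expect_equal(res$cutoff, best_cut)
  expect_equal(res$statistic, best, tolerance = 1e-10)
})

test_that("optimal cutoff respects separation and group constraints", {
  # two well-separated score clusters with disjoint survival ranges:
  # the maximizing cutoff must fall strictly inside the score gap
  set.seed(4)
  sc <- c(rnorm(25, 0), rnorm(25, 10))
  tm <- c(10 + rexp(25, 1), rexp(25, 1))
  d <- surv_data(tm, rep(1, 50))
  res <- optimal_cutoff(sc, d)
  # maximally selected statistics can prefer a split off by one patient
  # from the clean gap; require cluster recovery up to one assignment
  truth <- rep(c(FALSE, TRUE), each = 25)
  expect_lte(sum((sc > res$cutoff) != truth), 1)
  expect_gt(res$cutoff, max(sc[1:25]))

  # min_prop = 0.5 with even n: only the median split is admissible
  sc2 <- 1:10
  d2 <- surv_data(c(5, 3, 8, 1, 9, 2, 7, 4, 10, 6), rep(1, 10))
  res2 <- optimal_cutoff(sc2, d2, min_prop = 0.5)
  expect_equal(res2$cutoff, 5.5)
  expect_equal(res2$n_low, 5)
})

test_that("decision curve matches direct TP/FP counting", {
  p10 <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  y10 <- c(1, 1, 0, 1, 0, 1, 0, 0, 0, 0)
  dc <- decision_curve(p10, y10, thresholds = c(0.25, 0.5, 0.75))
  # direct counting
  for (k in 1:3) {
    pt <- dc$threshold[k]
    tp <- sum(p10 >= pt & y10 == 1); fp <- sum(p10 >= pt & y10 == 0)
    expect_equal(dc$net_benefit[k], tp / 10 - fp / 10 * pt / (1 - pt))
  }
  expect_true(all(dc$treat_none == 0))
  prev <- mean(y10)
  expect_equal(dc$treat_all,
               prev - (1 - prev) * dc$threshold / (1 - dc$threshold))
  # net benefit never exceeds prevalence
  expect_true(all(dc$net_benefit <= prev + 1e-12))
  expect_error(decision_curve(p10, y10, thresholds = c(0, 0.5)), "strictly")
  expect_error(decision_curve(c(1.2, p10[-1]), y10), "probabilities")
})

test_that("event_probability is monotone in risk and properly bounded", {
  set.seed(13)
  n <- 60
  eta <- rnorm(n)
  tm <- rexp(n, exp(eta) / 20)
  d <- surv_data(tm, rbinom(n, 1, 0.8))
  p <- event_probability(eta, d, horizon = 15)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p[order(eta)]) >= 0))
})

test_that("cox_fit recovers a planted coefficient within its 95% CI", {
  hits <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n <- 2000
    x <- rnorm(n)
    tm <- rexp(n, exp(0.5 * x))
    cc <- rexp(n, 0.3)
    d <- surv_data(pmin(tm, cc), as.integer(tm <= cc))
    fit <- cox_fit(x, d)
    lo <- fit$coefficients[1] - 1.96 * fit$se[1]
    hi <- fit$coefficients[1] + 1.96 * fit$se[1]
    if (lo <= 0.5 && 0.5 <= hi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})
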