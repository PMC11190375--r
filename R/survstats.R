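#' Harrell's concordance index for right-censored data
#'
#' Fraction of comparable patient pairs in which the patient with the
#' higher risk score experiences the event earlier.  A pair is comparable
#' when the shorter follow-up time ends in an event (including a tie in
#' time between an event and a censoring).  Score ties count one half.
#' Convention: higher risk corresponds to shorter survival.
#'
#' @param scores Numeric risk scores, one per patient.
#' @param data A [surv_data] object (or data frame with `time`, `event`).
#' @return Concordance in `[0, 1]`.
#' @examples
#' d <- surv_data(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' concordance_index(c(4, 3, 2, 1), d)  # perfectly anti-ordered: 1
#' @export
concordance_index <- function(scores, data) {
  data <- as_surv_data(data)
  n <- nrow(data)
  if (length(scores) != n) stop("`scores` length must match data")
  if (!all(is.finite(scores))) stop("scores must be finite")
  t <- data$time; d <- data$event
  conc <- 0; npairs <- 0
  for (i in seq_len(n)) {
    if (d[i] != 1L) next
    # pairs where i is the (strictly) earlier event, plus time-tied
    # event-vs-censored pairs where the censored patient outlives i
    comp <- (t > t[i]) | (t == t[i] & d == 0L)
    if (!any(comp)) next
    si <- scores[i]; sj <- scores[comp]
    conc <- conc + sum(si > sj) + 0.5 * sum(si == sj)
    npairs <- npairs + sum(comp)
  }
  if (npairs == 0) stop("no comparable pairs")
  conc / npairs
}

#' Kaplan-Meier product-limit estimator
#'
#' @param data A [surv_data] object.
#' @return A `survival_curve`: data frame with one row per distinct
#'   follow-up time — `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#'   `surv` is non-increasing and starts from S(0) = 1; censored-only
#'   times reduce the risk set without a step.
#' @examples
#' kaplan_meier(surv_data(c(1, 2, 3, 4), c(1, 0, 1, 0)))
#' @export
kaplan_meier <- function(data) {
  data <- as_surv_data(data)
  ut <- sort(unique(data$time))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at <- data$time == ut[k]
    n_risk[k] <- sum(data$time >= ut[k])
    n_event[k] <- sum(at & data$event == 1L)
    n_censor[k] <- sum(at & data$event == 0L)
    if (n_event[k] > 0) s <- s * (1 - n_event[k] / n_risk[k])
    surv[k] <- s
  }
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival curves:
#' observed minus expected events summed over distinct event times, with
#' the hypergeometric variance; the squared standardized statistic is
#' referred to a chi-square distribution with one degree of freedom.
#'
#' @param group_a,group_b [surv_data] objects for the two groups.
#' @return List with `observed` (group a), `expected`, `variance`,
#'   `statistic` (chi-square), `z` (signed standardized statistic for
#'   group a) and `p_value`.
#' @export
log_rank_test <- function(group_a, group_b) {
  group_a <- as_surv_data(group_a); group_b <- as_surv_data(group_b)
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  grp <- rep(c(0L, 1L), c(nrow(group_a), nrow(group_b)))
  if (sum(event) == 0L) stop("no events in either group")
  et <- sort(unique(time[event == 1L]))
  O <- E <- V <- 0
  for (tt in et) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 0L)
    d <- sum(time == tt & event == 1L)
    d1 <- sum(time == tt & event == 1L & grp == 0L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    z <- 0; chisq <- 0; p <- 1
  } else {
    z <- (O - E) / sqrt(V)
    chisq <- z^2
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  list(observed = O, expected = E, variance = V,
       statistic = chisq, z = z, p_value = p)
}

# ---- Cox proportional hazards (Breslow partial likelihood) ------------

# log partial likelihood, gradient and Hessian at beta.
# x: n x p matrix sorted however; internally sorted by time.
cox_pl_parts <- function(beta, x, time, event) {
  n <- nrow(x); p <- ncol(x)
  ord <- order(time, decreasing = TRUE)  # walk from largest time down
  xo <- x[ord, , drop = FALSE]
  to <- time[ord]; do <- event[ord]
  eta <- drop(xo %*% beta)
  # guard against overflow
  eta <- eta - max(eta)
  w <- exp(eta)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1
  while (i <= n) {
    # accumulate everyone with time >= current tied block into risk set
    j <- i
    while (j <= n && to[j] == to[i]) j <- j + 1
    for (k in i:(j - 1)) {
      S0 <- S0 + w[k]
      S1 <- S1 + w[k] * xo[k, ]
      S2 <- S2 + w[k] * tcrossprod(xo[k, ])
    }
    # Breslow: each event in the tied block uses the same denominator
    for (k in i:(j - 1)) {
      if (do[k] == 1L) {
        ll <- ll + eta[k] - log(S0)
        mu <- S1 / S0
        grad <- grad + xo[k, ] - mu
        hess <- hess - (S2 / S0 - tcrossprod(mu))
      }
    }
    i <- j
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the Breslow partial likelihood, with
#' step-halving.  Standard errors come from the inverse observed
#' information; Wald confidence intervals and p-values are reported on
#' the hazard-ratio scale.  Convergence when the largest coefficient
#' update falls below `tol` (default 1e-8) or after `max_iter`
#' iterations.
#'
#' @param covariates Numeric matrix (patients x covariates) or vector.
#' @param data A [surv_data] object aligned with the covariate rows.
#' @param tol Convergence tolerance on `max(abs(delta beta))`.
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `cox_fit`: list with `coefficients`,
#'   `se`, `hazard_ratios`, `ci95` (2-column matrix, exp scale),
#'   `z`, `p_values`, `loglik`, `converged`, `n_iter`, `n`, `n_events`.
#' @examples
#' d <- surv_data(c(2, 4, 6, 8, 10, 12), c(1, 1, 0, 1, 0, 1))
#' cox_fit(c(1, 1, 0, 0, 1, 0), d)
#' @export
cox_fit <- function(covariates, data, tol = 1e-8, max_iter = 100L) {
  data <- as_surv_data(data)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (nrow(x) != nrow(data)) stop("covariate rows must match data")
  if (!all(is.finite(x))) stop("covariates must be finite")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0)) stop("zero-variance covariate")
  nev <- sum(data$event)
  if (nev < 1L) stop("no events")
  if (nev < ncol(x)) stop("fewer events than covariates")

  p <- ncol(x)
  beta <- numeric(p)
  parts <- cox_pl_parts(beta, x, data$time, data$event)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(-parts$hessian, parts$gradient),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # step-halving to guarantee ascent
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + step / 2^h
      pc <- cox_pl_parts(cand, x, data$time, data$event)
      if (is.finite(pc$loglik) && pc$loglik >= parts$loglik - 1e-12) {
        ok <- TRUE
        delta <- max(abs(cand - beta))
        beta <- cand; parts <- pc
        break
      }
    }
    if (!ok) break
    if (delta < tol) { converged <- TRUE; break }
  }
  info <- -parts$hessian
  vcv <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcv))
  z <- beta / se
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  names(beta) <- names(se) <- names(z) <- cn
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- cn
  out <- list(coefficients = beta, se = se,
              hazard_ratios = exp(beta), ci95 = ci, z = z,
              p_values = 2 * stats::pnorm(-abs(z)),
              loglik = parts$loglik, vcov = vcv,
              converged = converged, n_iter = it,
              n = nrow(data), n_events = nev)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  cat(sprintf("  n = %d, events = %d, converged = %s (%d iterations)\n",
              x$n, x$n_events, x$converged, x$n_iter))
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    lower95 = x$ci95[, 1], upper95 = x$ci95[, 2],
                    se = x$se, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Cumulative/dynamic time-dependent AUC
#'
#' Cases are patients with an observed event by the horizon; controls
#' are patients still event-free past the horizon; patients censored
#' before the horizon are excluded.  The AUC is the probability that a
#' random case scores above a random control, ties counting one half.
#'
#' @param scores Risk scores (higher = higher risk).
#' @param data A [surv_data] object.
#' @param horizon Evaluation horizon in months.
#' @return AUC in `[0, 1]`.
#' @export
time_dependent_auc <- function(scores, data, horizon) {
  data <- as_surv_data(data)
  if (length(scores) != nrow(data)) stop("scores must match data")
  case <- data$time <= horizon & data$event == 1L
  control <- data$time > horizon
  if (!any(case)) stop(sprintf("no cases at horizon %g", horizon))
  if (!any(control)) stop(sprintf("no controls at horizon %g", horizon))
  sc <- scores[case]; sn <- scores[control]
  cmp <- outer(sc, sn, ">") + 0.5 * outer(sc, sn, "==")
  mean(cmp)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic at every
#' admissible cutoff (midpoints between adjacent distinct sorted scores)
#' subject to each group holding at least `min_prop` of the cohort, and
#' returns the cutoff maximizing the absolute standardized statistic.
#' Ties favour the smaller cutoff.
#'
#' @param scores Numeric scores to dichotomize.
#' @param data A [surv_data] object.
#' @param min_prop Minimum proportion of patients in each group
#'   (default 0.1).
#' @return List with `cutoff`, `statistic` (absolute standardized
#'   log-rank), `n_low`, `n_high`, and the full candidate `table`.
#' @export
optimal_cutoff <- function(scores, data, min_prop = 0.1) {
  data <- as_surv_data(data)
  n <- nrow(data)
  if (length(scores) != n) stop("scores must match data")
  us <- sort(unique(scores))
  if (length(us) < 2L) stop("no admissible cutoff: scores are constant")
  cand <- (us[-1] + us[-length(us)]) / 2
  nmin <- ceiling(min_prop * n)
  stat <- rep(NA_real_, length(cand))
  nlow <- nhigh <- integer(length(cand))
  for (k in seq_along(cand)) {
    low <- scores <= cand[k]
    nlow[k] <- sum(low); nhigh[k] <- n - nlow[k]
    if (nlow[k] < nmin || nhigh[k] < nmin) next
    lr <- tryCatch(
      log_rank_test(data[low, , drop = FALSE], data[!low, , drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(lr)) stat[k] <- abs(lr$z)
  }
  if (all(is.na(stat))) stop("no admissible cutoff under min_prop")
  best <- which(stat == max(stat, na.rm = TRUE))[1L]  # ties: smaller cutoff
  list(cutoff = cand[best], statistic = stat[best],
       n_low = nlow[best], n_high = nhigh[best],
       table = data.frame(cutoff = cand, statistic = stat,
                          n_low = nlow, n_high = nhigh))
}

#' Decision-curve analysis
#'
#' Net benefit of acting on predicted event probabilities at each
#' threshold probability, against treat-all and treat-none policies:
#' `NB(pt) = TP/N - FP/N * pt / (1 - pt)`, classifying positive when
#' the predicted probability is at least `pt`.
#'
#' @param probabilities Predicted event probabilities in `[0, 1]`.
#' @param outcomes Observed binary outcomes (0/1).
#' @param thresholds Threshold grid, strictly inside `(0, 1)`.
#' @return A `net_benefit_curve` data frame: `threshold`, `net_benefit`,
#'   `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probabilities, outcomes,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  outcomes <- as.integer(outcomes)
  if (!all(outcomes %in% c(0L, 1L))) stop("outcomes must be 0/1")
  if (length(probabilities) != length(outcomes)) {
    stop("probabilities and outcomes must align")
  }
  n <- length(outcomes)
  prev <- mean(outcomes)
  nb <- ta <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    pt <- thresholds[k]
    pos <- probabilities >= pt
    tp <- sum(pos & outcomes == 1L)
    fp <- sum(pos & outcomes == 0L)
    odds <- pt / (1 - pt)
    nb[k] <- tp / n - fp / n * odds
    ta[k] <- prev - (1 - prev) * odds
  }
  out <- data.frame(threshold = thresholds, net_benefit = nb,
                    treat_all = ta, treat_none = 0)
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Breslow baseline survival and horizon event probabilities
#'
#' Converts linear-predictor risk scores into event probabilities at a
#' fixed horizon via the Breslow baseline cumulative hazard computed at
#' the mean-centred risks: `P(event by h) = 1 - S0(h)^exp(eta - mean(eta))`.
#'
#' @param risks Linear-predictor risk scores (log-hazard scale).
#' @param data A [surv_data] object.
#' @param horizon Horizon in months.
#' @return Vector of event probabilities in `[0, 1]`.
#' @export
event_probability <- function(risks, data, horizon) {
  data <- as_surv_data(data)
  if (length(risks) != nrow(data)) stop("risks must match data")
  eta <- risks - mean(risks)
  w <- exp(eta)
  et <- sort(unique(data$time[data$event == 1L & data$time <= horizon]))
  ch0 <- 0
  for (tt in et) {
    d <- sum(data$time == tt & data$event == 1L)
    ch0 <- ch0 + d / sum(w[data$time >= tt])
  }
  1 - exp(-ch0 * w)
}
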