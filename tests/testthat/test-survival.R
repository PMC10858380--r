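sim_ph_data <- function(n, beta, seed = 1, censor_rate = 0.02) {
  set.seed(seed)
  x <- rnorm(n)
  t <- rexp(n, 0.02 * exp(beta * x))
  c_ <- rexp(n, censor_rate)
  data.frame(x = x, time = pmin(t, c_), event = as.integer(t <= c_))
}

test_that("pearson matrix is symmetric with unit diagonal", {
  x <- c(1, 2, 3); y <- c(2, 4, 6.1)
  m <- pearson_matrix(data.frame(x = x, y = y, neg = -x))
  expect_equal(diag(m), c(x = 1, y = 1, neg = 1))
  expect_equal(m, t(m))
  expect_equal(m["x", "neg"], -1)
  # textbook formula by hand
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m["x", "y"], r_hand, tolerance = 1e-12)
  expect_error(pearson_matrix(data.frame(a = 1:5, b = rep(2, 5))),
               "zero-variance")
  expect_error(pearson_matrix(data.frame(a = 1:2, b = 2:1)), "at least 3")
})

test_that("median and fixed cutoff rules behave as stated", {
  expect_equal(select_cutoff(1:9, rule = cutoff_rule("m", "median")), 5)
  expect_equal(select_cutoff(1:9, rule = cutoff_rule("tmtv", "fixed",
                                                     value = 220)), 220)
  expect_error(cutoff_rule("tmtv", "fixed"), "explicit value")
  expect_error(select_cutoff(rep(3, 10), rule = cutoff_rule("m", "median")),
               "distinct")
})

test_that("youden cutoff separates a perfectly separating marker", {
  # events by the horizon all have marker > 10, non-events all <= 10
  times <- c(5, 8, 6, 9, 60, 70, 80, 90)
  events <- c(1, 1, 1, 1, 0, 0, 0, 0)
  marker <- c(12, 13, 14, 15, 3, 4, 5, 10)
  cut <- select_cutoff(marker, times, events,
                       cutoff_rule("m", "youden", horizon = 48))
  expect_gte(cut, 10)
  expect_lt(cut, 12)
})

test_that("youden cutoff matches an exhaustive uncensored scan", {
  set.seed(5)
  n <- 150
  marker <- rnorm(n)
  prob <- plogis(1.8 * marker - 0.4)
  event_by_h <- rbinom(n, 1, prob)
  # no censoring before horizon: event times < 48 for cases, > 48 otherwise
  times <- ifelse(event_by_h == 1, runif(n, 1, 40), runif(n, 50, 100))
  events <- event_by_h
  cut <- select_cutoff(marker, times, events,
                       cutoff_rule("m", "youden", horizon = 48))
  # independent scan: plain sens/spec on the binary outcome
  cand <- sort(unique(marker))
  j <- sapply(cand, function(cc) {
    mean(marker[event_by_h == 1] > cc) + mean(marker[event_by_h == 0] <= cc) - 1
  })
  best <- cand[which.max(j)]
  expect_equal(cut, best, tolerance = 1e-12)
})

test_that("kaplan-meier steps match the hand product-limit computation", {
  times <- c(1, 2, 3, 4, 4, 5)
  events <- c(1, 0, 1, 1, 0, 1)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  # hand: S(1)=5/6, S(3)=5/6*3/4, S(4)=...*2/3, S(5)=0
  expect_equal(summary(fit, times = c(1, 3, 4, 5))$surv,
               c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)

  grp <- factor(c("a", "a", "a", "b", "b", "b"))
  res <- km_logrank(times, events, grp)
  expect_s3_class(res$fit, "survfit")
  expect_equal(res$df, 1L)

  # identical groups -> chi-square 0, p = 1
  t2 <- rep(c(3, 5, 8, 10), 2)
  e2 <- rep(c(1, 0, 1, 1), 2)
  g2 <- rep(c("a", "b"), each = 4)
  res2 <- km_logrank(t2, e2, g2)
  expect_equal(res2$chisq, 0, tolerance = 1e-9)
  expect_equal(res2$p_value, 1, tolerance = 1e-9)

  # no events anywhere -> NA, not an error
  res3 <- km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_true(is.na(res3$p_value))
  expect_error(km_logrank(times, events, rep("a", 6)), "at least 2")
})

test_that("cox model maximizes the hand-written partial likelihood", {
  times <- c(1, 2, 3, 4); events <- c(1, 1, 0, 1); x <- c(0, 1, 0, 1)
  m <- cox_model(data.frame(x = x), times, events)
  # independent: untied data, so the partial likelihood is
  # e^{b x(1)}/sum_{R1} + ... written out explicitly
  nll <- function(b) {
    -((0 - log(2 + 2 * exp(b))) + (b - log(1 + 2 * exp(b))) + (b - b))
  }
  bhat <- optimize(nll, c(-5, 5))$minimum
  expect_equal(unname(m$coef), bhat, tolerance = 1e-4)
  expect_true(m$converged)
})

test_that("cox recovers a known hazard ratio and is null-calibrated", {
  d <- sim_ph_data(1000, beta = log(2), seed = 3)
  m <- cox_model(d["x"], d$time, d$event)
  expect_lt(abs(unname(m$hr) - 2) / 2, 0.10)

  d0 <- sim_ph_data(500, beta = 0, seed = 4)
  m0 <- cox_model(d0["x"], d0$time, d0$event)
  expect_lt(abs(unname(m0$coef)) / unname(m0$se), 3)

  expect_error(cox_model(data.frame(x = rep(1, 10)), 1:10, rep(1, 10)),
               "constant")
  expect_error(cox_model(data.frame(x = rnorm(10), y = rnorm(10)),
                         1:10, c(1, rep(0, 9))), "fewer events")
})

test_that("harrell c matches exhaustive pair enumeration", {
  # perfect ranking: risk = -time, no censoring
  tt <- c(3, 1, 9, 5, 7)
  expect_equal(harrell_c(-tt, tt, rep(1, 5)), 1)

  set.seed(9)
  for (i in 1:20) {
    n <- 12
    times <- sample(1:100, n)  # untied
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) events[1] <- 1
    risk <- sample(1:6, n, replace = TRUE)  # risk ties exercise the 1/2 rule
    expect_equal(harrell_c(risk, times, events),
                 oracle_concordance(risk, times, events), tolerance = 1e-12)
  }

  # null: random risk near 0.5
  set.seed(10)
  n <- 4000
  tt <- rexp(n); ee <- rbinom(n, 1, 0.8); rr <- rnorm(n)
  expect_lt(abs(harrell_c(rr, tt, ee) - 0.5), 0.03)
  # negation symmetry without ties
  rr2 <- rnorm(200); tt2 <- rexp(200); ee2 <- rbinom(200, 1, 0.7)
  expect_equal(harrell_c(rr2, tt2, ee2) + harrell_c(-rr2, tt2, ee2), 1,
               tolerance = 1e-12)
})

test_that("bootstrap CI matches the closed-form SE for a sample mean", {
  d <- data.frame(v = 1:100)
  b <- bootstrap_ci(function(x) mean(x$v), d, n_resamples = 4000, seed = 1)
  se <- sd(d$v) * sqrt(99 / 100) / sqrt(100)  # bootstrap uses the n-divisor
  expect_equal(unname(b$point), 50.5)
  expect_equal(unname(b$lower), 50.5 - 1.96 * se, tolerance = 0.35)
  expect_equal(unname(b$upper), 50.5 + 1.96 * se, tolerance = 0.35)

  const <- bootstrap_ci(function(x) 7, d, n_resamples = 200, seed = 1)
  expect_equal(unname(const$lower), 7)
  expect_equal(unname(const$upper), 7)

  b2 <- bootstrap_ci(function(x) mean(x$v), d, n_resamples = 500, seed = 42)
  b3 <- bootstrap_ci(function(x) mean(x$v), d, n_resamples = 500, seed = 42)
  expect_identical(b2[c("point", "lower", "upper")],
                   b3[c("point", "lower", "upper")])

  fragile <- function(x) { if (runif(1) < 0.2) stop("boom"); mean(x$v) }
  set.seed(1)
  expect_error(bootstrap_ci(fragile, d, n_resamples = 200), "resamples")
})

test_that("time-dependent AUC is calibrated at the null and the optimum", {
  set.seed(2)
  n <- 2000
  tt <- rexp(n, 0.02); ee <- rbinom(n, 1, 0.85); mm <- rnorm(n)
  expect_lt(abs(time_dependent_auc(mm, tt, ee, 48) - 0.5), 0.05)

  # marker = event-time rank, no censoring: perfect discrimination
  t2 <- sort(rexp(300, 0.02))
  expect_equal(time_dependent_auc(-rank(t2), t2, rep(1, 300), 48), 1)
  expect_error(time_dependent_auc(mm, tt + 1000, ee, 48), "no events")
})

test_that("three-group stratification combines burden and dissemination", {
  g <- stratify_3groups(tmtv = c(100, 300, 300), feature = c(20, 20, 40),
                        tmtv_cutoff = 220, feature_cutoff = 32.43)
  expect_equal(as.integer(g), c(0L, 1L, 2L))
  expect_equal(attr(g, "n_groups"), 3L)
  expect_message(
    g2 <- stratify_3groups(c(100, NA), c(20, 30), 220, 25),
    "excluded")
  expect_true(is.na(g2[2]))
})

test_that("concordance gain test flags true signal and not identity", {
  sp <- cohort_spec(n_patients = 250, betas = c(tmtv = 0.6, d_ref = 0.8),
                    seed = 21)
  tab <- merge(simulate_cohort(sp)$features,
               simulate_cohort(sp)$clinical, by = "patient_id")
  res <- c_index_gain_test(tab, base = "tmtv_cm3",
                           extended = c("tmtv_cm3", "d_ref_cm"),
                           n_resamples = 200, seed = 5)
  expect_gt(res$delta_c, 0)
  expect_lt(res$p_value, 0.05)
  expect_true(res$ci[1] <= res$delta_c && res$delta_c <= res$ci[2])

  same <- c_index_gain_test(tab, base = "tmtv_cm3", extended = "tmtv_cm3",
                            n_resamples = 200, seed = 5)
  expect_equal(same$delta_c, 0)
  expect_equal(same$p_value, 1)
  expect_error(c_index_gain_test(tab, base = "d_ref_cm",
                                 extended = "tmtv_cm3"), "must contain")
})

test_that("survival report assembles univariate and multivariate results", {
  sp <- cohort_spec(n_patients = 150, seed = 31)
  co <- simulate_cohort(sp)
  tab <- merge(co$features, co$clinical, by = "patient_id")
  rep <- fit_survival_report(tab, covariates = c("tmtv_cm3", "d_ref_cm"),
                             n_resamples = 200, seed = 2)
  expect_s3_class(rep, "survival_report")
  expect_equal(nrow(rep$univariate), 2L)
  u <- rep$univariate
  expect_true(all(u$hr_lower <= u$hr & u$hr <= u$hr_upper))
  expect_true(all(u$c_lower <= u$c_index & u$c_index <= u$c_upper))
  expect_true(all(u$c_index >= 0.5 & u$c_index <= 1))
  expect_true(all(u$td_auc >= 0 & u$td_auc <= 1))
  expect_equal(rep$multivariate$c_index,
               cox_model(tab[, c("tmtv_cm3", "d_ref_cm")], tab$pfs_months,
                         tab$pfs_event)$c_index, tolerance = 1e-9)
})

test_that("subgroup reruns respect size guards and filters", {
  sp <- cohort_spec(n_patients = 150, seed = 33)
  co <- simulate_cohort(sp)
  tab <- merge(co$features, co$clinical, by = "patient_id")
  full <- fit_survival_report(tab, covariates = "d_ref_cm",
                              n_resamples = 200, seed = 3)
  all_in <- subgroup_run(tab, rep(TRUE, nrow(tab)), "all patients",
                         covariates = "d_ref_cm", n_resamples = 200,
                         seed = 3)
  expect_equal(all_in$univariate$hr, full$univariate$hr)
  expect_identical(all_in$filter, "all patients")

  no_inv <- subgroup_run(tab, !tab$invasion, "no splenic invasion",
                         covariates = "d_ref_cm", n_resamples = 200,
                         seed = 3)
  # effect is invasion-independent in the generator: direction preserved
  expect_gt(no_inv$univariate$hr, 1)

  expect_error(subgroup_run(tab, seq_len(nrow(tab)) <= 3, "tiny",
                            covariates = "d_ref_cm"), "too small")
})
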