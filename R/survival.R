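#' Pearson correlation matrix of biomarkers
#'
#' Pairwise Pearson correlations between feature columns, used to check that
#' the spleen-referenced features carry information independent of tumor
#' burden (TMTV) and clinical score (IPI).
#'
#' @param features data.frame or matrix of numeric columns, >= 3 complete
#'   rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(features) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 complete patients")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  stats::cor(x, method = "pearson")
}

# Kaplan-Meier estimator of the censoring distribution G(t), returned as an
# evaluator g(t, minus) with right-continuous steps; g(t, minus = TRUE)
# gives the left limit G(t-). Used for inverse-probability-of-censoring
# weights in the time-dependent ROC machinery.
censoring_survival <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  tt <- fit$time
  ss <- fit$surv
  function(t, minus = FALSE) {
    vapply(t, function(ti) {
      k <- if (minus) sum(tt < ti - 1e-12) else sum(tt <= ti + 1e-12)
      if (k == 0L) 1 else ss[k]
    }, numeric(1))
  }
}

# Cases/controls and IPCW weights for a cumulative/dynamic ROC at `horizon`:
# cases experienced the event by the horizon, controls are still event-free
# past it; censored-before-horizon patients contribute through the weights.
cd_roc_data <- function(marker, times, events, horizon) {
  stopifnot(length(marker) == length(times), length(times) == length(events))
  keep <- is.finite(marker) & is.finite(times)
  marker <- marker[keep]; times <- times[keep]; events <- events[keep]
  case <- times <= horizon & events == 1
  control <- times > horizon
  if (!any(case)) stop("no events before the horizon")
  if (!any(control)) stop("no event-free patients past the horizon")
  G <- censoring_survival(times, events)
  w_case <- 1 / G(times[case], minus = TRUE)
  g_h <- G(horizon)
  if (g_h <= 0) stop("censoring survival is zero at the horizon")
  list(m_case = marker[case], w_case = w_case,
       m_ctrl = marker[control], w_ctrl = rep(1 / g_h, sum(control)))
}

#' Time-dependent AUC (cumulative/dynamic, censoring-weighted)
#'
#' Discrimination of a marker for events occurring by `horizon`: the
#' probability that a randomly chosen patient with an event by the horizon
#' has a higher marker value than a randomly chosen patient still event-free
#' past it, with inverse-probability-of-censoring weighting (the
#' cumulative/dynamic estimator). Ties count 1/2.
#'
#' @param marker numeric risk marker (higher = higher risk).
#' @param times,events right-censored endpoint.
#' @param horizon evaluation time (same unit as `times`; months by package
#'   convention).
#' @return AUC in \[0, 1\].
#' @export
time_dependent_auc <- function(marker, times, events, horizon) {
  d <- cd_roc_data(marker, times, events, horizon)
  cmp <- outer(d$m_case, d$m_ctrl,
               function(a, b) (a > b) + 0.5 * (a == b))
  ww <- outer(d$w_case, d$w_ctrl)
  sum(ww * cmp) / sum(ww)
}

#' Define a cutoff rule
#' @param feature feature name the rule applies to.
#' @param method `"median"`, `"youden"` or `"fixed"`.
#' @param value required cutoff for `"fixed"` (e.g. 220 cm^3 for TMTV).
#' @param horizon ROC horizon in months for `"youden"`.
#' @return a `cutoff_rule` list.
#' @export
cutoff_rule <- function(feature, method = c("median", "youden", "fixed"),
                        value = NULL, horizon = 48) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(value))
    stop("fixed cutoff rule requires an explicit value")
  structure(list(feature = feature, method = method, value = value,
                 horizon = horizon), class = "cutoff_rule")
}

#' Select a dichotomization cutoff for a marker
#'
#' `median` uses the sample median. `youden` scans every observed marker
#' value as a candidate threshold (classification: marker > cutoff is
#' high-risk) and picks the one maximizing the Youden index
#' (sensitivity + specificity - 1) of the censoring-weighted
#' cumulative/dynamic ROC at the rule's horizon; ties resolve to the lowest
#' qualifying threshold, so the result is deterministic. `fixed` returns the
#' rule's value.
#'
#' @param values marker values.
#' @param times,events endpoint (required for `youden`).
#' @param rule a [cutoff_rule].
#' @return the cutoff value, in marker units.
#' @export
select_cutoff <- function(values, times = NULL, events = NULL,
                          rule = cutoff_rule("marker", "median")) {
  stopifnot(inherits(rule, "cutoff_rule"))
  if (rule$method == "fixed") return(rule$value)
  vals <- values[is.finite(values)]
  if (length(unique(vals)) < 2L)
    stop("cannot select a cutoff: fewer than 2 distinct marker values")
  if (rule$method == "median") return(stats::median(vals))
  if (is.null(times) || is.null(events))
    stop("youden cutoff needs times and events")
  d <- cd_roc_data(values, times, events, rule$horizon)
  cand <- sort(unique(vals))
  j <- vapply(cand, function(cc) {
    sens <- sum(d$w_case * (d$m_case > cc)) / sum(d$w_case)
    spec <- sum(d$w_ctrl * (d$m_ctrl <= cc)) / sum(d$w_ctrl)
    sens + spec - 1
  }, numeric(1))
  cand[which(j >= max(j) - 1e-12)[1]]
}

#' Kaplan-Meier curves and log-rank test across risk groups
#'
#' Product-limit survival estimate per group plus the k-group log-rank
#' chi-square test. With no events anywhere the log-rank statistic is
#' undefined and reported as NA.
#'
#' @param times,events right-censored endpoint.
#' @param group group labels (factor or coercible); every level must be
#'   non-empty.
#' @return list with `fit` (a [survival::survfit] object), `chisq`, `df`,
#'   `p_value` and `n_groups`.
#' @export
km_logrank <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) == 0L)) stop("every group must contain patients")
  df0 <- data.frame(t = times, e = events, g = group)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df0)
  if (sum(events) == 0) {
    return(list(fit = fit, chisq = NA_real_, df = nlevels(group) - 1L,
                p_value = NA_real_, n_groups = nlevels(group)))
  }
  sd0 <- survival::survdiff(survival::Surv(t, e) ~ g, data = df0)
  df_ <- length(sd0$n) - 1L
  list(fit = fit, chisq = sd0$chisq, df = df_,
       p_value = stats::pchisq(sd0$chisq, df_, lower.tail = FALSE),
       n_groups = nlevels(group))
}

#' Cox proportional hazards model
#'
#' Maximum partial likelihood with Efron tie handling. Hazard ratios are
#' exp(coefficient). Non-convergence is reported in the result, never
#' silently ignored.
#'
#' @param covariates data.frame of numeric covariates (no constant columns).
#' @param times,events right-censored endpoint; at least as many events as
#'   covariates.
#' @return a `cox_result`: list with `fit`, `coef` (log-HR), `hr`, `se`,
#'   `p`, `c_index` (concordance of the fitted linear predictor) and
#'   `converged`.
#' @export
cox_model <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  sds <- vapply(covariates, function(v) stats::sd(as.numeric(v)), numeric(1))
  if (any(is.na(sds) | sds == 0))
    stop("constant or non-numeric covariate(s): ",
         paste(names(covariates)[is.na(sds) | sds == 0], collapse = ", "))
  if (sum(events) < ncol(covariates))
    stop("fewer events (", sum(events), ") than covariates (",
         ncol(covariates), ")")
  dat <- cbind(covariates, .t = times, .e = events)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.t, .e) ~ ., data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w),
                ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  list(fit = fit,
       coef = stats::coef(fit),
       hr = exp(stats::coef(fit)),
       se = s$coefficients[, "se(coef)"],
       p = s$coefficients[, "Pr(>|z|)"],
       c_index = as.numeric(fit$concordance["concordance"]),
       converged = converged)
}

#' Harrell concordance index
#'
#' Fraction of comparable patient pairs whose risk ordering matches their
#' outcome ordering, ties counted 1/2; comparability respects censoring
#' (a censored patient is only comparable to patients with an earlier
#' event). Higher risk scores are expected to go with shorter survival.
#'
#' @param risk numeric risk scores (higher = higher risk).
#' @param times,events right-censored endpoint.
#' @return concordance in \[0, 1\].
#' @export
harrell_c <- function(risk, times, events) {
  cc <- survival::concordance(survival::Surv(times, events) ~ risk,
                              reverse = TRUE)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no comparable pairs")
  as.numeric(cc$concordance)
}

#' Patient-level bootstrap with empirical percentile CI
#'
#' Resamples patients (table rows) with replacement, applies `statistic` to
#' each resample and reports the empirical 2.5/97.5 percentiles. The
#' published protocol this mirrors uses 5,000 resamples; the count is
#' configurable for scaled-down runs. Seeded runs are exactly reproducible.
#' If the statistic fails (error or all-NA) on more than 5% of resamples the
#' bootstrap aborts with a diagnostic rather than report a biased CI.
#'
#' @param statistic function(data.frame) -> numeric vector (possibly named).
#' @param data patient table; rows are the resampling unit.
#' @param n_resamples number of bootstrap resamples (>= 100).
#' @param seed optional integer seed.
#' @param conf_level CI level (default 0.95).
#' @param keep_samples keep the resample-by-resample statistics?
#' @return a `bootstrap_ci`: list with `point`, `lower`, `upper`,
#'   `n_resamples`, `n_failed`, `seed`, `conf_level` and optionally
#'   `samples`.
#' @export
bootstrap_ci <- function(statistic, data, n_resamples = 5000, seed = NULL,
                         conf_level = 0.95, keep_samples = FALSE) {
  stopifnot(n_resamples >= 100)
  point <- statistic(data)
  k <- length(point)
  n <- nrow(data)
  samples <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_resamples, ncol = k)
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                      error = function(e) rep(NA_real_, k))
      if (length(val) == k) out[b, ] <- as.numeric(val)
    }
    out
  })
  failed <- apply(samples, 1, function(r) all(is.na(r)))
  if (mean(failed) > 0.05)
    stop(sprintf("statistic failed on %.1f%% of resamples (> 5%%)",
                 100 * mean(failed)))
  alpha <- (1 - conf_level) / 2
  lower <- apply(samples, 2, stats::quantile, probs = alpha, na.rm = TRUE,
                 names = FALSE)
  upper <- apply(samples, 2, stats::quantile, probs = 1 - alpha,
                 na.rm = TRUE, names = FALSE)
  names(lower) <- names(upper) <- names(point)
  structure(list(point = point, lower = lower, upper = upper,
                 n_resamples = n_resamples, n_failed = sum(failed),
                 seed = seed, conf_level = conf_level,
                 samples = if (keep_samples) samples else NULL),
            class = "bootstrap_ci")
}

#' Three-group risk stratification by TMTV plus a dissemination feature
#'
#' Combines tumor burden with a dissemination feature: group 0 = both below
#' their cutoffs, group 1 = exactly one above, group 2 = both above. The
#' TMTV cutoff defaults to the published 220 cm^3; the feature cutoff
#' defaults to its sample median. Patients missing either value are
#' excluded (returned as NA) with a message, never silently dropped.
#'
#' @param tmtv TMTV values (cm^3).
#' @param feature dissemination feature values (e.g. Dspleen, cm).
#' @param tmtv_cutoff cutoff for TMTV (default 220).
#' @param feature_cutoff cutoff for the feature (default: median of the
#'   non-missing values).
#' @return integer vector of groups 0/1/2 (NA = excluded), with attributes
#'   `n_groups` and `definition`.
#' @export
stratify_3groups <- function(tmtv, feature, tmtv_cutoff = 220,
                             feature_cutoff = NULL) {
  stopifnot(length(tmtv) == length(feature))
  if (is.null(feature_cutoff))
    feature_cutoff <- stats::median(feature, na.rm = TRUE)
  miss <- !is.finite(tmtv) | !is.finite(feature)
  if (any(miss))
    message(sum(miss), " patient(s) excluded from stratification ",
            "(missing TMTV or feature value)")
  g <- as.integer((tmtv > tmtv_cutoff) + (feature > feature_cutoff))
  g[miss] <- NA_integer_
  structure(g, n_groups = 3L,
            definition = sprintf("TMTV > %g + feature > %g",
                                 tmtv_cutoff, feature_cutoff))
}

#' Concordance gain from adding covariates to a Cox model
#'
#' Tests whether an extended covariate set improves Harrell concordance over
#' a base set, via a paired patient-level bootstrap: both models are refit
#' on each resample and the difference of their concordances is recorded.
#' The two-sided p-value is proportion-based on the bootstrap distribution
#' of the difference (with a +1 continuity correction), the CI is the
#' empirical 95% band.
#'
#' @param data patient table containing all covariates plus the endpoint.
#' @param base,extended character vectors of covariate column names;
#'   `extended` must strictly contain `base`.
#' @param time_col,event_col endpoint column names.
#' @param n_resamples bootstrap resamples.
#' @param seed optional integer seed.
#' @return list with `delta_c` (point estimate C_extended - C_base),
#'   `c_base`, `c_extended`, `ci` (length-2), `p_value`, `n_resamples`,
#'   `seed`.
#' @export
c_index_gain_test <- function(data, base, extended, time_col = "pfs_months",
                              event_col = "pfs_event", n_resamples = 1000,
                              seed = NULL) {
  if (!all(base %in% extended))
    stop("`extended` must contain every base covariate")
  fit_c <- function(d, covs) {
    m <- cox_model(d[, covs, drop = FALSE], d[[time_col]], d[[event_col]])
    m$c_index
  }
  c_base <- fit_c(data, base)
  if (setequal(base, extended)) {
    return(list(delta_c = 0, c_base = c_base, c_extended = c_base,
                ci = c(0, 0), p_value = 1, n_resamples = 0L, seed = seed))
  }
  c_ext <- fit_c(data, extended)
  deltas <- with_seed(seed, {
    n <- nrow(data)
    vapply(seq_len(n_resamples), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- data[idx, , drop = FALSE]
      tryCatch(fit_c(d, extended) - fit_c(d, base),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- deltas[is.finite(deltas)]
  if (length(ok) < 0.95 * n_resamples)
    stop("concordance-gain bootstrap failed on > 5% of resamples")
  B <- length(ok)
  p <- 2 * min((sum(ok <= 0) + 1) / (B + 1), (sum(ok >= 0) + 1) / (B + 1))
  list(delta_c = c_ext - c_base, c_base = c_base, c_extended = c_ext,
       ci = unname(stats::quantile(ok, c(0.025, 0.975))),
       p_value = min(1, p), n_resamples = n_resamples, seed = seed)
}

#' Full univariate + multivariate survival report for one endpoint
#'
#' The standard analysis applied to a feature table: per covariate, a
#' univariate Cox model (hazard ratio, concordance, time-dependent AUC at
#' the horizon, all with patient-level bootstrap CIs) and a Kaplan-Meier
#' split at the covariate's cutoff with a log-rank p-value; plus one
#' multivariate Cox model over all covariates with its concordance.
#'
#' @param data patient table with covariates and the endpoint columns.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col endpoint column names.
#' @param endpoint label stored in the report (`"PFS"` or `"OS"`).
#' @param horizon AUC horizon, months.
#' @param cutoff_rules optional named list of [cutoff_rule]s per covariate;
#'   default is the median rule.
#' @param n_resamples bootstrap resamples (published protocol: 5000).
#' @param seed optional integer seed.
#' @return a `survival_report` list: `endpoint`, `n`, `n_events`,
#'   `univariate` (data.frame), `multivariate` (list), `horizon`,
#'   `n_resamples`, `seed`, `filter`.
#' @export
fit_survival_report <- function(data, covariates,
                                time_col = "pfs_months",
                                event_col = "pfs_event",
                                endpoint = "PFS", horizon = 48,
                                cutoff_rules = NULL, n_resamples = 5000,
                                seed = NULL) {
  stopifnot(all(covariates %in% names(data)),
            time_col %in% names(data), event_col %in% names(data))
  keep <- stats::complete.cases(data[, c(covariates, time_col, event_col)])
  data <- data[keep, , drop = FALSE]
  tt <- data[[time_col]]; ee <- data[[event_col]]

  stat <- function(d) {
    out <- numeric(0)
    for (cv in covariates) {
      m <- tryCatch(cox_model(d[, cv, drop = FALSE], d[[time_col]],
                              d[[event_col]]), error = function(e) NULL)
      hr <- if (is.null(m)) NA_real_ else unname(m$hr[1])
      ci <- if (is.null(m)) NA_real_ else m$c_index
      auc <- tryCatch(time_dependent_auc(d[[cv]], d[[time_col]],
                                         d[[event_col]], horizon),
                      error = function(e) NA_real_)
      v <- c(hr, ci, auc)
      names(v) <- paste(cv, c("hr", "c", "auc"), sep = ".")
      out <- c(out, v)
    }
    out
  }
  boot <- bootstrap_ci(stat, data, n_resamples = n_resamples, seed = seed)

  uni <- do.call(rbind, lapply(covariates, function(cv) {
    rule <- cutoff_rules[[cv]] %||% cutoff_rule(cv, "median")
    cut <- select_cutoff(data[[cv]], tt, ee, rule)
    grp <- factor(ifelse(data[[cv]] > cut, "high", "low"),
                  levels = c("low", "high"))
    lr <- if (nlevels(droplevels(grp)) == 2L)
      km_logrank(tt, ee, grp)$p_value else NA_real_
    nm <- function(s) paste(cv, s, sep = ".")
    data.frame(
      feature = cv,
      hr = unname(boot$point[nm("hr")]),
      hr_lower = unname(boot$lower[nm("hr")]),
      hr_upper = unname(boot$upper[nm("hr")]),
      c_index = unname(boot$point[nm("c")]),
      c_lower = unname(boot$lower[nm("c")]),
      c_upper = unname(boot$upper[nm("c")]),
      td_auc = unname(boot$point[nm("auc")]),
      auc_lower = unname(boot$lower[nm("auc")]),
      auc_upper = unname(boot$upper[nm("auc")]),
      cutoff = cut,
      cutoff_method = rule$method,
      logrank_p = lr,
      stringsAsFactors = FALSE
    )
  }))
  rownames(uni) <- NULL

  multi <- if (length(covariates) >= 2L) {
    m <- cox_model(data[, covariates, drop = FALSE], tt, ee)
    list(hr = m$hr, coef = m$coef, p = m$p, c_index = m$c_index,
         converged = m$converged)
  } else NULL

  structure(list(endpoint = endpoint, n = nrow(data), n_events = sum(ee),
                 univariate = uni, multivariate = multi, horizon = horizon,
                 n_resamples = n_resamples, seed = seed, filter = "all"),
            class = "survival_report")
}

#' Re-run the survival analysis on a patient subgroup
#'
#' Applies a filter (e.g. patients without splenic invasion) and reruns
#' [fit_survival_report] on the subset. Refuses to run on subgroups too
#' small to support the models.
#'
#' @param data patient table.
#' @param filter logical vector over rows, or function(data) -> logical.
#' @param filter_label text recorded in the report.
#' @param min_patients,min_events minimal subgroup size (defaults 20 / 5).
#' @param ... passed to [fit_survival_report].
#' @return a `survival_report` with the filter recorded.
#' @export
subgroup_run <- function(data, filter, filter_label = "subgroup",
                         min_patients = 20, min_events = 5, ...) {
  sel <- if (is.function(filter)) filter(data) else as.logical(filter)
  stopifnot(length(sel) == nrow(data))
  sel[is.na(sel)] <- FALSE
  sub <- data[sel, , drop = FALSE]
  args <- list(...)
  event_col <- args$event_col %||% "pfs_event"
  if (nrow(sub) < min_patients)
    stop("subgroup too small: ", nrow(sub), " patients (need >= ",
         min_patients, ")")
  if (sum(sub[[event_col]]) < min_events)
    stop("subgroup has too few events: ", sum(sub[[event_col]]),
         " (need >= ", min_events, ")")
  rep <- do.call(fit_survival_report, c(list(data = sub), args))
  rep$filter <- filter_label
  rep
}
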