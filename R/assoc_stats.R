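#' Association result row
#'
#' One-row data.frame used by every estimator in the association battery:
#' measure (RFD / OR / HR), point estimate, Wald 95% CI, p-value, index
#' and referent labels, adjustment set, cell sizes, and a flag column for
#' fallbacks (zero cells, non-convergence). RFDs are reported in
#' percentage points.
#'
#' @keywords internal
assoc_result <- function(measure, estimate, ci_low, ci_high, p_value,
                         variable = NA_character_, index_level = NA_character_,
                         referent_level = NA_character_,
                         adjustment = "unadjusted",
                         n_index = NA_integer_, n_referent = NA_integer_,
                         flag = "") {
  structure(data.frame(measure = measure, variable = variable,
                       index_level = index_level,
                       referent_level = referent_level,
                       adjustment = adjustment,
                       estimate = estimate, ci_low = ci_low,
                       ci_high = ci_high, p_value = p_value,
                       n_index = n_index, n_referent = n_referent,
                       flag = flag, stringsAsFactors = FALSE),
            class = c("assoc_result", "data.frame"))
}

# closed-form difference of proportions with Wald CI (percentage points)
rfd_closed_form <- function(y_hom, n_hom, y_het, n_het) {
  p1 <- y_hom / n_hom
  p0 <- y_het / n_het
  se <- sqrt(p1 * (1 - p1) / n_hom + p0 * (1 - p0) / n_het)
  est <- p1 - p0
  z <- est / se
  c(estimate = 100 * est, ci_low = 100 * (est - 1.96 * se),
    ci_high = 100 * (est + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)))
}

#' Relative frequency difference between visual-ITH groups
#'
#' Estimates the RFD (difference, in percentage points, of the prevalence
#' of `index_level` in the homogeneous vs the heterogeneous group;
#' referent = heterogeneous) via an identity-link binomial GLM, so that
#' adjustment covariates enter additively. Unadjusted, the GLM coefficient
#' equals the closed-form difference of within-group proportions. If the
#' identity-link fit fails or leaves fitted probabilities outside [0, 1],
#' the unadjusted path falls back to the closed form (flagged) and the
#' adjusted path reports a flagged failure.
#'
#' @param records data.frame with the characteristic column and an
#'   `ith_group` factor (levels heterogeneous, homogeneous).
#' @param characteristic Column name of the characteristic.
#' @param index_level Level whose prevalence is compared.
#' @param referent_level Referent level of the characteristic; records at
#'   other levels (or missing) are excluded (complete-case).
#' @param adjust Character vector of covariate column names (e.g.
#'   `c("age_group", "race")` for the age/race adjustment set, or
#'   `c("grade", "er", "node", "size")`).
#' @return An [assoc_result] row.
#' @export
rfd <- function(records, characteristic, index_level, referent_level,
                adjust = NULL) {
  stopifnot("ith_group" %in% names(records),
            characteristic %in% names(records))
  v <- records[[characteristic]]
  keep <- v %in% c(index_level, referent_level) & !is.na(records$ith_group)
  if (!is.null(adjust)) {
    stopifnot(all(adjust %in% names(records)))
    keep <- keep & stats::complete.cases(records[adjust])
  }
  dat <- records[keep, , drop = FALSE]
  y <- as.integer(dat[[characteristic]] == index_level)
  hom <- as.integer(dat$ith_group == "homogeneous")
  n_hom <- sum(hom); n_het <- sum(1 - hom)
  if (n_hom == 0 || n_het == 0) {
    stop("both visual-ITH groups must be represented")
  }
  cf <- rfd_closed_form(sum(y[hom == 1]), n_hom, sum(y[hom == 0]), n_het)
  adj_label <- if (is.null(adjust)) "unadjusted" else paste(adjust, collapse = "+")

  if (is.null(adjust)) {
    p0 <- sum(y[hom == 0]) / n_het
    p1 <- sum(y[hom == 1]) / n_hom
    fit <- tryCatch(
      stats::glm(y ~ hom, family = stats::binomial(link = "identity"),
                 start = c(p0, p1 - p0)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !fit$converged ||
        any(fit$fitted.values < 0 | fit$fitted.values > 1)) {
      return(assoc_result("RFD", cf[["estimate"]], cf[["ci_low"]],
                          cf[["ci_high"]], cf[["p_value"]],
                          characteristic, index_level, referent_level,
                          adj_label, n_hom, n_het, flag = "closed-form fallback"))
    }
    est <- stats::coef(fit)[["hom"]]
    se <- sqrt(stats::vcov(fit)["hom", "hom"])
  } else {
    X <- dat[adjust]
    form <- stats::as.formula(paste("y ~ hom +", paste(adjust, collapse = "+")))
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, data = cbind(y = y, hom = hom, X),
                                  family = stats::binomial(link = "identity"),
                                  start = c(mean(y), rep(0, length(
                                    stats::model.matrix(form, cbind(y = y, hom = hom, X))[1, ]) - 1)))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        any(fit$fitted.values < -1e-8 | fit$fitted.values > 1 + 1e-8)) {
      return(assoc_result("RFD", NA_real_, NA_real_, NA_real_, NA_real_,
                          characteristic, index_level, referent_level,
                          adj_label, n_hom, n_het,
                          flag = "identity-link fit failed"))
    }
    est <- stats::coef(fit)[["hom"]]
    se <- sqrt(stats::vcov(fit)["hom", "hom"])
  }
  z <- est / se
  assoc_result("RFD", 100 * est, 100 * (est - 1.96 * se),
               100 * (est + 1.96 * se), 2 * stats::pnorm(-abs(z)),
               characteristic, index_level, referent_level, adj_label,
               n_hom, n_het)
}

#' Expand grouped counts into patient-level records
#'
#' Utility for re-analysing published contingency tables: takes counts per
#' (ith_group, level) cell and returns one row per patient.
#'
#' @param counts data.frame with columns `ith_group`, `level`, `n`.
#' @param characteristic Name to give the level column.
#' @return data.frame with `ith_group` (factor) and the characteristic.
#' @export
expand_counts <- function(counts, characteristic = "level") {
  stopifnot(all(c("ith_group", "level", "n") %in% names(counts)))
  idx <- rep(seq_len(nrow(counts)), counts$n)
  out <- data.frame(
    ith_group = factor(counts$ith_group[idx],
                       levels = c("heterogeneous", "homogeneous")),
    level = counts$level[idx], stringsAsFactors = FALSE)
  names(out)[2] <- characteristic
  out
}

#' Odds ratio between low visual ITH and a binary outcome
#'
#' Exposure is the low-visual-ITH (homogeneous) group, referent the
#' heterogeneous group. Unadjusted estimates use the 2x2 cross-product
#' ratio with a Woolf 95% CI; zero cells receive the Haldane-Anscombe 0.5
#' correction (flagged). With `adjust` covariates (or
#' `method = "logistic"`) a logistic regression is fitted instead; on the
#' same unadjusted 2x2 the two routes agree to numerical precision.
#'
#' @param records data.frame with `ith_group` and the outcome column, or
#'   NULL when `counts` is given.
#' @param outcome Outcome column name.
#' @param outcome_level Level counted as a positive outcome.
#' @param adjust Optional covariate names (forces the logistic path).
#' @param counts Optional 2x2 matrix `rbind(homogeneous = c(yes, no),
#'   heterogeneous = c(yes, no))` used instead of records.
#' @param method `"crossprod"` (default unadjusted) or `"logistic"`.
#' @return An [assoc_result] row.
#' @export
odds_ratio <- function(records = NULL, outcome = NULL, outcome_level = NULL,
                       adjust = NULL, counts = NULL,
                       method = c("crossprod", "logistic")) {
  method <- match.arg(method)
  if (is.null(outcome)) outcome <- NA_character_
  if (is.null(outcome_level)) outcome_level <- NA_character_
  if (is.null(counts)) {
    stopifnot(!is.null(records), "ith_group" %in% names(records),
              outcome %in% names(records))
    keep <- !is.na(records[[outcome]]) & !is.na(records$ith_group)
    if (!is.null(adjust)) keep <- keep & stats::complete.cases(records[adjust])
    dat <- records[keep, , drop = FALSE]
    y <- as.integer(dat[[outcome]] == outcome_level)
    hom <- as.integer(dat$ith_group == "homogeneous")
    counts <- rbind(homogeneous = c(sum(y[hom == 1]), sum(hom) - sum(y[hom == 1])),
                    heterogeneous = c(sum(y[hom == 0]), sum(1 - hom) - sum(y[hom == 0])))
  } else {
    stopifnot(is.matrix(counts), all(dim(counts) == c(2, 2)))
    dat <- NULL
  }
  a <- counts[1, 1]; b <- counts[1, 2]  # exposed (homogeneous): yes / no
  cc <- counts[2, 1]; d <- counts[2, 2] # unexposed (heterogeneous)
  flag <- ""
  if (!is.null(adjust) || method == "logistic") {
    if (is.null(dat)) stop("logistic path needs patient-level records")
    form <- if (is.null(adjust)) y ~ hom else
      stats::as.formula(paste("y ~ hom +", paste(adjust, collapse = "+")))
    fit <- stats::glm(form, data = cbind(y = y, hom = hom, dat),
                      family = stats::binomial())
    est <- exp(stats::coef(fit)[["hom"]])
    se <- sqrt(stats::vcov(fit)["hom", "hom"])
    lo <- est * exp(-1.96 * se); hi <- est * exp(1.96 * se)
    p <- 2 * stats::pnorm(-abs(log(est) / se))
    adj_label <- if (is.null(adjust)) "unadjusted" else paste(adjust, collapse = "+")
  } else {
    if (any(counts == 0)) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
      flag <- "Haldane-Anscombe 0.5 correction"
    }
    est <- (a * d) / (b * cc)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)  # Woolf, log scale
    lo <- exp(log(est) - 1.96 * se); hi <- exp(log(est) + 1.96 * se)
    p <- 2 * stats::pnorm(-abs(log(est) / se))
    adj_label <- "unadjusted"
  }
  assoc_result("OR", est, lo, hi, p, variable = outcome,
               index_level = outcome_level, referent_level = "heterogeneous",
               adjustment = adj_label,
               n_index = sum(counts[1, ]), n_referent = sum(counts[2, ]),
               flag = flag)
}

#' Kaplan-Meier recurrence-free survival by visual-ITH group
#'
#' Product-limit curves per group with a yearly risk table over the
#' horizon and the log-rank test. Records with missing time, event or
#' group are excluded and counted.
#'
#' @param records data.frame with `time` (years), `event` (1 = recurrence)
#'   and `ith_group`.
#' @param horizon Risk-table horizon in years (default 5).
#' @return List of class `km_curve`: `fit` (a `survfit`), `risk_table`,
#'   `logrank_chisq`, `logrank_p`, `n_excluded`, `flags`.
#' @export
km_curve <- function(records, horizon = 5) {
  stopifnot(all(c("time", "event", "ith_group") %in% names(records)))
  keep <- stats::complete.cases(records[c("time", "event", "ith_group")])
  dat <- records[keep, , drop = FALSE]
  n_excluded <- sum(!keep)
  fit <- survival::survfit(survival::Surv(time, event) ~ ith_group, data = dat)
  events <- tapply(dat$event, dat$ith_group, sum)
  flags <- character(0)
  if (any(events == 0, na.rm = TRUE)) {
    flags <- c(flags, paste("no events in group:",
                            paste(names(events)[which(events == 0)], collapse = ", ")))
  }
  sm <- summary(fit, times = 0:horizon, extend = TRUE)
  grp_col <- if (!is.null(sm$strata)) as.character(sm$strata) else
    rep(as.character(unique(dat$ith_group))[1], length(sm$time))
  risk_table <- data.frame(group = grp_col, time = sm$time,
                           n_risk = sm$n.risk, n_event = sm$n.event,
                           survival = sm$surv, stringsAsFactors = FALSE)
  lr <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ ith_group,
                                    data = dat),
                 error = function(e) NULL)
  chisq <- if (is.null(lr)) NA_real_ else lr$chisq
  p <- if (is.null(lr)) NA_real_ else
    stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  structure(list(fit = fit, risk_table = risk_table, logrank_chisq = chisq,
                 logrank_p = p, n_excluded = n_excluded, flags = flags),
            class = "km_curve")
}

#' Cox proportional-hazards ratio for low vs high visual ITH
#'
#' Partial-likelihood hazard ratio (homogeneous vs heterogeneous referent)
#' with Efron tie handling, Wald 95% CI and p-value, plus a
#' proportionality diagnostic from the scaled Schoenfeld-residual test.
#'
#' @param records data.frame with `time`, `event`, `ith_group`.
#' @param adjust Optional covariate column names.
#' @return An [assoc_result] row with attribute `"zph_p"` (proportionality
#'   test p-value).
#' @export
cox_hr <- function(records, adjust = NULL) {
  stopifnot(all(c("time", "event", "ith_group") %in% names(records)))
  keep <- stats::complete.cases(records[c("time", "event", "ith_group")])
  if (!is.null(adjust)) keep <- keep & stats::complete.cases(records[adjust])
  dat <- records[keep, , drop = FALSE]
  events <- tapply(dat$event, dat$ith_group, sum)
  if (any(is.na(events)) || any(events == 0)) {
    return(assoc_result("HR", NA_real_, NA_real_, NA_real_, NA_real_,
                        variable = "recurrence",
                        referent_level = "heterogeneous",
                        flag = "monotone likelihood: a group has no events"))
  }
  form <- if (is.null(adjust)) {
    survival::Surv(time, event) ~ ith_group
  } else {
    stats::as.formula(paste("survival::Surv(time, event) ~ ith_group +",
                            paste(adjust, collapse = "+")))
  }
  fit <- survival::coxph(form, data = dat, ties = "efron")
  cname <- grep("^ith_group", names(stats::coef(fit)), value = TRUE)[1]
  est <- exp(stats::coef(fit)[[cname]])
  se <- sqrt(stats::vcov(fit)[cname, cname])
  z <- log(est) / se
  zph_p <- tryCatch(survival::cox.zph(fit)$table[1, "p"],
                    error = function(e) NA_real_)
  out <- assoc_result("HR", est, est * exp(-1.96 * se), est * exp(1.96 * se),
                      2 * stats::pnorm(-abs(z)), variable = "recurrence",
                      index_level = "homogeneous",
                      referent_level = "heterogeneous",
                      adjustment = if (is.null(adjust)) "unadjusted" else
                        paste(adjust, collapse = "+"),
                      n_index = sum(dat$ith_group == "homogeneous"),
                      n_referent = sum(dat$ith_group == "heterogeneous"))
  attr(out, "zph_p") <- zph_p
  out
}

#' Default variable grid for the association battery
#'
#' @return data.frame with columns variable, index_level, referent_level
#'   matching the synthetic clinical dictionary.
#' @export
battery_variables <- function() {
  data.frame(
    variable = c("age_group", "race", "grade", "ror", "pam50", "er",
                 "node", "size", "immune_class"),
    index_level = c("<50", "Black", "high", "high", "Basal", "neg",
                    "pos", ">2cm", "high"),
    referent_level = c(">=50", "non-Black", "low", "low", "LumA", "pos",
                       "neg", "<=2cm", "low"),
    stringsAsFactors = FALSE)
}

#' Run the full association battery
#'
#' For every compartment variant's group assignment, computes the RFD of
#' each variable at each adjustment set, in one tidy table with cell
#' counts. Variables missing a required level are skipped with a message.
#'
#' @param records Clinical data.frame (one row per patient).
#' @param groups_by_variant Named list of [assign_groups()] tables.
#' @param variables Variable grid, see [battery_variables()].
#' @param adjustments Named list of adjustment sets (NULL = unadjusted).
#' @return data.frame of [assoc_result] rows with a `variant` column.
#' @export
association_battery <- function(records, groups_by_variant,
                                variables = battery_variables(),
                                adjustments = list(unadjusted = NULL)) {
  out <- list()
  for (variant in names(groups_by_variant)) {
    g <- groups_by_variant[[variant]]
    rec <- merge(records, g[c("patient_id", "ith_group")], by = "patient_id")
    for (i in seq_len(nrow(variables))) {
      v <- variables[i, ]
      lv <- unique(stats::na.omit(rec[[v$variable]]))
      if (!all(c(v$index_level, v$referent_level) %in% lv)) {
        message("skipping ", v$variable, " (", variant,
                "): required level absent")
        next
      }
      for (an in names(adjustments)) {
        row <- rfd(rec, v$variable, v$index_level, v$referent_level,
                   adjust = adjustments[[an]])
        row$adjustment <- an
        row$variant <- variant
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (length(out) == 0) {
    res <- assoc_result("RFD", NA_real_, NA_real_, NA_real_, NA_real_)
    res$variant <- NA_character_
    return(res[0, , drop = FALSE])
  }
  do.call(rbind, out)
}
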