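#' Relative expression from qPCR cycle thresholds
#'
#' Standard delta-Ct relative quantification on a log10 scale:
#' \code{log10(2^-dCt)} with \code{dCt = ct_mir - ct_ref}, i.e.
#' \code{-(ct_mir - ct_ref) * log10(2)}. A lower Ct than the reference
#' (earlier amplification) means higher expression, hence the negative
#' slope. Vectorized.
#'
#' @param ct_mir cycle threshold(s) of the assayed microRNA (triplicate
#'   wells averaged beforehand).
#' @param ct_ref cycle threshold(s) of the reference small RNA (U6b).
#' @return relative expression on the log10 scale.
#' @export
relative_expression <- function(ct_mir, ct_ref) {
  if (any(!is.finite(ct_mir)) || any(!is.finite(ct_ref)))
    stop("non-finite Ct value")
  -(ct_mir - ct_ref) * log10(2)
}

#' Two-sided pooled-variance t-test from summary statistics
#'
#' Computes the crude group comparison from group sizes, means and SDs
#' alone, as when reading numbers off a published table.
#'
#' @param n1,mean1,sd1 first group.
#' @param n2,mean2,sd2 second group.
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   pooled one.
#' @return list: \code{t}, \code{df}, \code{p}, \code{diff} (mean1 - mean2).
#' @export
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  d <- mean1 - mean2
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  if (se == 0) stop("constant response: zero pooled standard error")
  t <- d / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), diff = d)
}

#' Crude and covariate-adjusted two-group comparison
#'
#' The crude p-value is a two-sided pooled-variance t-test (Welch by flag).
#' When covariates are supplied, the adjusted p-value is the p-value of the
#' group term in the linear model \code{value ~ group + covariates}
#' (ANCOVA), with factors treated categorically. Covariates that are
#' constant or collinear with terms already in the model are dropped with a
#' warning.
#'
#' @param values numeric response (e.g. log10 relative expression).
#' @param groups two-level grouping (factor or character), >= 2 per group.
#' @param covariates optional data.frame of adjustment covariates (e.g.
#'   age, sex, stage), complete (no NA) and row-aligned with \code{values}.
#' @param welch use Welch's t-test for the crude comparison.
#' @return list: \code{crude_p}, \code{adjusted_p} (NA when no covariates),
#'   \code{group_means}, \code{group_sds}, \code{group_ns} (named by group
#'   level), \code{dropped_covariates}.
#' @export
compare_groups <- function(values, groups, covariates = NULL, welch = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly 2 levels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  if (any(!is.finite(values))) stop("non-finite response value")
  if (stats::var(values) == 0) stop("constant response")
  sp <- split(values, groups)
  stats_by <- function(f) vapply(sp, f, 0)
  crude <- ttest_from_summary(length(sp[[1L]]), mean(sp[[1L]]), stats::sd(sp[[1L]]),
                              length(sp[[2L]]), mean(sp[[2L]]), stats::sd(sp[[2L]]),
                              welch = welch)
  adjusted_p <- NA_real_
  dropped <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(values))
      stop("covariate table must have one row per sample")
    if (anyNA(covariates)) stop("covariate table must be complete when supplied")
    keep <- names(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (length(unique(v)) < 2L) {
        warning("dropping constant covariate: ", nm)
        keep <- setdiff(keep, nm)
      }
    }
    dat <- data.frame(.value = values, .group = groups,
                      covariates[keep], check.names = TRUE)
    fit <- stats::lm(.value ~ ., data = dat)
    alias <- stats::alias(fit)$Complete
    if (!is.null(alias)) {
      bad <- unique(sub("^`?([A-Za-z._][A-Za-z0-9._]*)`?.*$", "\\1",
                        rownames(alias)))
      bad <- intersect(bad, keep)
      if (length(bad)) {
        warning("dropping collinear covariate(s): ", paste(bad, collapse = ", "))
        keep <- setdiff(keep, bad)
        dat <- data.frame(.value = values, .group = groups,
                          covariates[keep], check.names = TRUE)
        fit <- stats::lm(.value ~ ., data = dat)
      }
    }
    dropped <- setdiff(names(covariates), keep)
    adjusted_p <- stats::anova(fit)[".group", "Pr(>F)"]
  }
  list(crude_p = crude$p, adjusted_p = adjusted_p,
       group_means = stats_by(mean), group_sds = stats_by(stats::sd),
       group_ns = stats_by(length), dropped_covariates = dropped)
}

#' Dichotomize a marker at its median
#'
#' Values strictly above the sample median are labeled \code{"high"},
#' values at or below it \code{"low"}; ties at the median (including the
#' median element itself at odd n) therefore go to the low group.
#'
#' @param values numeric vector (>= 2 finite values).
#' @return list: \code{labels} (factor high/low, aligned with
#'   \code{values}) and \code{median}.
#' @export
dichotomize_at_median <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to dichotomize")
  if (any(!is.finite(values))) stop("non-finite marker value")
  med <- stats::median(values)
  lab <- factor(ifelse(values > med, "high", "low"), levels = c("high", "low"))
  if (all(lab == "low"))
    warning("degenerate split: all values at or below the median")
  list(labels = lab, median = med)
}

#' Kaplan-Meier curves and log-rank test truncated at a horizon
#'
#' Implements the early-recurrence analysis: follow-up is administratively
#' censored at \code{horizon_months} (events after the horizon count as
#' censored at the horizon), the product-limit estimator is computed per
#' marker group, and the two groups are compared by the log-rank test
#' (chi-square, 1 df). With no event in either group the log-rank statistic
#' is undefined; the function then returns p = 1 with a warning.
#'
#' @param time_months follow-up time in months (> 0).
#' @param event 1 = recurrence observed, 0 = censored.
#' @param labels two-level group labels (e.g. from
#'   \code{\link{dichotomize_at_median}}); both groups non-empty.
#' @param horizon_months truncation horizon (default 12, the early-
#'   recurrence window).
#' @return list: \code{curves} (data.frame: group, time, n_risk, n_event,
#'   survival), \code{logrank_chi2}, \code{logrank_p}, \code{fit} (the
#'   underlying \code{survfit} object).
#' @export
km_logrank <- function(time_months, event, labels, horizon_months = 12) {
  stopifnot(length(time_months) == length(event),
            length(labels) == length(event))
  if (any(!is.finite(time_months)) || any(time_months <= 0))
    stop("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1")
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("need exactly 2 non-empty groups")
  over <- time_months > horizon_months
  event <- ifelse(over, 0, event)
  time_months <- pmin(time_months, horizon_months)
  dat <- data.frame(time = time_months, event = event, group = labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata <- if (is.null(fit$strata)) {
    rep(levels(labels)[1L], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, survival = fit$surv,
                       stringsAsFactors = FALSE)
  if (sum(event) == 0L) {
    warning("no event in either group; log-rank test undefined, returning p = 1")
    return(list(curves = curves, logrank_chi2 = 0, logrank_p = 1, fit = fit))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chi2 <- unname(sd$chisq)
  list(curves = curves, logrank_chi2 = chi2,
       logrank_p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       fit = fit)
}

#' Read a qPCR validation cohort from CSV
#'
#' Expected named columns: sample_id, ct_mir, ct_ref, group, age, sex,
#' stage, time_months, event. The relative expression
#' \code{log10(2^-dCt)} is appended as column \code{rel_expr}.
#'
#' @param path CSV file path.
#' @param exclude_stage1 drop stage-I patients (optional sensitivity
#'   analysis; default FALSE).
#' @return data.frame of class \code{qpcr_cohort}.
#' @export
read_qpcr_cohort <- function(path, exclude_stage1 = FALSE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "ct_mir", "ct_ref", "group", "age", "sex",
            "stage", "time_months", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tab$time_months <= 0)) stop("time_months must be positive")
  if (exclude_stage1) tab <- tab[tab$stage != "I" & tab$stage != 1, , drop = FALSE]
  tab$rel_expr <- relative_expression(tab$ct_mir, tab$ct_ref)
  class(tab) <- c("qpcr_cohort", "data.frame")
  tab
}
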