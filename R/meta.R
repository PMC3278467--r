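#' Inverse-variance pooling with Cochran's Q and DerSimonian-Laird tau^2
#'
#' Fixed effects: weights \code{w_i = 1/se_i^2}, pooled effect
#' \code{sum(w d)/sum(w)}, 95\% CI \code{pooled +/- 1.96/sqrt(sum(w))}.
#' Heterogeneity: \code{Q = sum(w (d - pooled_fixed)^2)} referred to a
#' chi-square with k-1 df (Q p-value is 1 when k = 1). Random effects use
#' the DerSimonian-Laird moment estimator
#' \code{tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))} and
#' weights \code{1/(se_i^2 + tau2)}. When Q <= k-1 the estimator gives
#' tau2 = 0 and the random-effects result coincides exactly with the fixed
#' one.
#'
#' @param effects numeric vector of per-study effect sizes.
#' @param ses positive standard errors, same length.
#' @param model \code{"fixed"} or \code{"random"}: which pooled estimate and
#'   CI to report in \code{pooled}/\code{ci95} (Q, its p-value and tau2 are
#'   always returned).
#' @return list: \code{pooled}, \code{ci95} (length-2), \code{q_stat},
#'   \code{q_pvalue}, \code{tau2}, \code{k}, \code{model}.
#' @export
pool_effects <- function(effects, ses, model = c("fixed", "random")) {
  model <- match.arg(model)
  k <- length(effects)
  if (k == 0L) stop("no studies to pool")
  if (length(ses) != k) stop("effects and ses must have the same length")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all standard errors must be positive")
  w <- 1 / ses^2
  pooled_f <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - pooled_f)^2)
  q_p <- if (k == 1L) 1 else stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  tau2 <- if (k == 1L) 0 else max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  if (model == "fixed") {
    pooled <- pooled_f
    se_pool <- 1 / sqrt(sum(w))
  } else {
    wr <- 1 / (ses^2 + tau2)
    pooled <- sum(wr * effects) / sum(wr)
    se_pool <- 1 / sqrt(sum(wr))
  }
  list(pooled = pooled,
       ci95 = c(pooled - 1.96 * se_pool, pooled + 1.96 * se_pool),
       q_stat = q, q_pvalue = q_p, tau2 = tau2, k = k, model = model)
}

#' Fisher's combination of p-values
#'
#' Under the global null, \code{-2 * sum(log(p_i))} over k independent
#' p-values follows a chi-square distribution with 2k degrees of freedom;
#' the combined p is its upper-tail probability. For k = 1 the method is
#' the identity.
#'
#' @param pvalues numeric vector of p-values, each in (0, 1]. Values
#'   outside that range are an error: no silent clamping.
#' @return list: \code{chi2}, \code{df} (= 2k), \code{combined_p}.
#' @export
fisher_combine <- function(pvalues) {
  k <- length(pvalues)
  if (k == 0L) stop("no p-values to combine")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(pvalues))
  list(chi2 = chi2, df = 2L * k,
       combined_p = stats::pchisq(chi2, df = 2L * k, lower.tail = FALSE))
}

#' Meta-analysis over all datasets for candidate microRNAs
#'
#' For each candidate, pools the per-dataset effect sizes by fixed and
#' random effects, tests heterogeneity with Cochran's Q, and combines the
#' per-dataset permutation p-values by Fisher's method. The significance
#' flag applies a genome-wide cutoff (default 5e-5, roughly 0.05 divided by
#' the number of microRNAs in a full target database).
#'
#' @param results association results data.frame covering every candidate
#'   in every dataset (\code{\link{associate_dataset}} rows concatenated).
#' @param mirnas candidates to pool; default: all microRNAs in
#'   \code{results}.
#' @param cutoff Fisher combined-p significance cutoff (default 5e-5).
#' @return data.frame sorted by \code{fisher_p} ascending (ties, e.g. at
#'   the permutation-p floor, broken by larger absolute pooled effect), one
#'   row per
#'   candidate: mirna_id, k, pooled_fixed, ci95 bounds, pooled_random, its
#'   CI bounds, q_stat, q_pvalue, tau2, fisher_chi2, fisher_df, fisher_p,
#'   significant.
#' @export
run_meta <- function(results, mirnas = NULL, cutoff = 5e-5) {
  if (is.null(mirnas)) mirnas <- sort(unique(results$mirna_id))
  datasets <- sort(unique(results$dataset_id))
  rows <- lapply(mirnas, function(m) {
    r <- results[results$mirna_id == m, , drop = FALSE]
    miss <- setdiff(datasets, r$dataset_id)
    if (length(miss))
      stop(sprintf("microRNA '%s' lacks results in dataset(s): %s",
                   m, paste(miss, collapse = ", ")))
    r <- r[match(datasets, r$dataset_id), , drop = FALSE]
    pf <- pool_effects(r$effect, r$se, model = "fixed")
    pr <- pool_effects(r$effect, r$se, model = "random")
    fc <- fisher_combine(r$p_perm)
    data.frame(mirna_id = m, k = pf$k,
               pooled_fixed = pf$pooled,
               ci95_fixed_low = pf$ci95[1L], ci95_fixed_high = pf$ci95[2L],
               pooled_random = pr$pooled,
               ci95_random_low = pr$ci95[1L], ci95_random_high = pr$ci95[2L],
               q_stat = pf$q_stat, q_pvalue = pf$q_pvalue, tau2 = pf$tau2,
               fisher_chi2 = fc$chi2, fisher_df = fc$df, fisher_p = fc$combined_p,
               significant = fc$combined_p <= cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # ties at the permutation-p floor are broken by effect magnitude
  out <- out[order(out$fisher_p, -abs(out$pooled_fixed), out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
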