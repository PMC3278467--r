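#' Effect size and standard error of a two-group score comparison
#'
#' The effect is the difference in mean activity score between recurrent
#' (label 1) and non-recurrent (label 0) samples; the standard error is the
#' usual unpooled SE of a difference in means,
#' \code{sqrt(s1^2/n1 + s0^2/n0)} with n-1 sample variances.
#'
#' @param scores numeric vector, one score per sample.
#' @param labels 0/1 vector of the same length (1 = recurrent).
#' @return list with \code{effect}, \code{se}, \code{n_rec}, \code{n_nonrec}.
#' @export
effect_and_se <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  g1 <- scores[labels == 1]; g0 <- scores[labels == 0]
  if (length(g1) < 2L || length(g0) < 2L)
    stop("each group needs at least 2 samples")
  list(effect = mean(g1) - mean(g0),
       se = sqrt(stats::var(g1) / length(g1) + stats::var(g0) / length(g0)),
       n_rec = length(g1), n_nonrec = length(g0))
}

#' Permutation p-value for a two-group mean difference
#'
#' Two-sided test on the absolute difference in group means. Monte-Carlo
#' mode draws \code{n_perm} random label permutations (group sizes fixed)
#' and applies add-one smoothing:
#' \code{p = (1 + #(|T*| >= |T_obs|)) / (1 + n_perm)}, which is a valid
#' p-value and never exactly 0. Exhaustive mode enumerates every label
#' assignment with the same group sizes and returns the exact exceedance
#' fraction (guarded to <= 20 samples).
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels 0/1 vector (1 = recurrent); each group >= 2.
#' @param n_perm number of Monte-Carlo permutations (default 1000).
#' @param seed optional integer; when supplied the draw is reproducible and
#'   independent of the caller's RNG state.
#' @param exhaustive enumerate all assignments instead of sampling.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(scores, labels, n_perm = 1000L, seed = NULL,
                               exhaustive = FALSE) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n <- length(scores)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  if (n1 < 2L || n0 < 2L) stop("each group needs at least 2 samples")
  total <- sum(scores)
  # |mean1 - mean0| as a function of the group-1 sum alone
  stat_from_s1 <- function(s1) abs(s1 * (1 / n1 + 1 / n0) - total / n0)
  t_obs <- stat_from_s1(sum(scores[labels == 1]))
  tol <- 1e-12 * (1 + abs(t_obs))  # ties in floating point count as exceedance
  if (exhaustive) {
    if (n > 20L) stop("exhaustive enumeration guarded to <= 20 samples")
    combs <- utils::combn(n, n1)
    s1 <- colSums(matrix(scores[combs], nrow = n1))
    return(mean(stat_from_s1(s1) >= t_obs - tol))
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    s1 <- sum(scores[sample.int(n, n1)])
    if (stat_from_s1(s1) >= t_obs - tol) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_perm)
}

# deterministic per-(mirna, dataset) seed derived from a global seed so that
# results do not depend on evaluation order; kept below 2^31
derive_seed <- function(global_seed, mirna_id, dataset_id) {
  key <- paste(mirna_id, dataset_id, sep = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + global_seed) %% 2147483629)
}

#' Per-dataset association of inferred activity with recurrence
#'
#' For every microRNA in an activity-score matrix, computes the effect size
#' (mean recurrent minus mean non-recurrent), its standard error, and a
#' two-sided permutation p-value. Each (microRNA, dataset) pair draws its
#' permutations from a seed derived from \code{seed}, so results are
#' reproducible and independent of row order.
#'
#' @param scores an \code{activity_scores} matrix from
#'   \code{\link{score_dataset}}.
#' @param n_perm permutations per microRNA (default 1000).
#' @param seed global integer seed.
#' @return data.frame with one row per microRNA: mirna_id, dataset_id,
#'   stage, effect, se, p_perm, n_rec, n_nonrec, n_perm.
#' @export
associate_dataset <- function(scores, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(scores, "activity_scores"))
  labels <- attr(scores, "phenotype")[colnames(scores)]
  ds <- attr(scores, "dataset_id")
  rows <- lapply(rownames(scores), function(m) {
    s <- scores[m, ]
    es <- effect_and_se(s, labels)
    p <- permutation_pvalue(s, labels, n_perm = n_perm,
                            seed = derive_seed(seed, m, ds))
    data.frame(mirna_id = m, dataset_id = ds, stage = attr(scores, "stage"),
               effect = es$effect, se = es$se, p_perm = p,
               n_rec = es$n_rec, n_nonrec = es$n_nonrec,
               n_perm = as.integer(n_perm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select candidate microRNAs consistent across datasets
#'
#' A microRNA is a stage-level candidate when its permutation p-value is
#' at or below \code{alpha} in every dataset of that stage and the sign of
#' its effect is the same across those datasets. Cross-stage candidates are
#' the intersection of the stage-level lists; they are the microRNAs the
#' meta-analysis step pools over all datasets.
#'
#' @param results data.frame of association results
#'   (\code{\link{associate_dataset}} rows, possibly concatenated over
#'   datasets); every (microRNA, dataset) pair must be present within each
#'   stage.
#' @param alpha screening cutoff (default 0.1, a liberal screen chosen to
#'   limit type-II error at this stage).
#' @return list with \code{per_stage} (named list stage -> character vector
#'   of candidate microRNAs) and \code{cross_stage} (character vector).
#' @export
select_candidates <- function(results, alpha = 0.1) {
  stopifnot(all(c("mirna_id", "dataset_id", "stage", "effect", "p_perm")
                %in% names(results)))
  per_stage <- lapply(split(results, results$stage), function(r) {
    tab <- table(r$mirna_id, r$dataset_id)
    if (any(tab != 1L)) {
      gap <- which(tab != 1L, arr.ind = TRUE)[1L, ]
      stop(sprintf("missing or duplicated result for microRNA '%s' in dataset '%s'",
                   rownames(tab)[gap[1L]], colnames(tab)[gap[2L]]))
    }
    by_mir <- split(r, r$mirna_id)
    hits <- vapply(by_mir, function(x) {
      all(x$p_perm <= alpha) &&
        (all(x$effect > 0) || all(x$effect < 0))
    }, NA)
    sort(names(by_mir)[hits])
  })
  list(per_stage = per_stage,
       cross_stage = sort(Reduce(intersect, per_stage)))
}
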