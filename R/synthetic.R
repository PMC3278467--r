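#' Configuration for the synthetic study generator
#'
#' Defaults mirror the scale of the six stage-specific colorectal-cancer
#' array datasets the method is designed for: three stage-II and three
#' stage-III datasets, per-group sample sizes drawn uniformly from 12-53
#' (dataset totals 24-106), 2,000 genes measured by 1-3 probes each, and a
#' target database of 200 microRNAs with 20-60 predicted targets apiece.
#' The planted signal implements the inverse-correlation assumption: target
#' genes of the planted microRNA(s) are shifted up by \code{target_shift_delta}
#' intensity units in recurrent samples only, which the scorer should read
#' as microRNA down-regulation in the recurrence group.
#'
#' @param n_genes number of genes.
#' @param n_mirnas number of microRNAs in the synthetic database.
#' @param targets_per_mirna length-2 integer range of target-set sizes.
#' @param probes_per_gene length-2 integer range of probes per gene.
#' @param n_datasets_stage2,n_datasets_stage3 datasets per stage.
#' @param samples_per_group length-2 range for each group's sample count.
#' @param planted_mirna_count how many microRNAs carry a planted signal.
#' @param target_shift_delta additive up-shift (intensity units) of planted
#'   targets in recurrent samples; 0 gives a null study.
#' @param noise_sd residual SD of the intensity model.
#' @param probe_noise_sd extra probe-level measurement SD.
#' @param missing_rate expected fraction of missing entries, in [0, 0.2].
#' @param unannotated_rate fraction of probes stripped of gene annotation.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the configuration including the seed.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L, n_mirnas = 200L,
                       targets_per_mirna = c(20L, 60L),
                       probes_per_gene = c(1L, 3L),
                       n_datasets_stage2 = 3L, n_datasets_stage3 = 3L,
                       samples_per_group = c(12L, 53L),
                       planted_mirna_count = 1L,
                       target_shift_delta = 3, noise_sd = 1,
                       probe_noise_sd = 0.25,
                       missing_rate = 0.02, unannotated_rate = 0.02,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              targets_per_mirna = as.integer(targets_per_mirna),
              probes_per_gene = as.integer(probes_per_gene),
              n_datasets_stage2 = as.integer(n_datasets_stage2),
              n_datasets_stage3 = as.integer(n_datasets_stage3),
              samples_per_group = as.integer(samples_per_group),
              planted_mirna_count = as.integer(planted_mirna_count),
              target_shift_delta = target_shift_delta, noise_sd = noise_sd,
              probe_noise_sd = probe_noise_sd,
              missing_rate = missing_rate,
              unannotated_rate = unannotated_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 10L, n_mirnas >= 1L,
              length(targets_per_mirna) == 2L,
              targets_per_mirna[1L] >= 1L,
              targets_per_mirna[1L] <= targets_per_mirna[2L],
              length(probes_per_gene) == 2L, probes_per_gene[1L] >= 1L,
              length(samples_per_group) == 2L, samples_per_group[1L] >= 2L,
              planted_mirna_count >= 0L, planted_mirna_count <= n_mirnas,
              noise_sd > 0, missing_rate >= 0, missing_rate <= 0.2)
    if (targets_per_mirna[2L] >= n_genes)
      stop("targets_per_mirna max must be smaller than n_genes")
    if (target_shift_delta < 0) stop("target_shift_delta must be >= 0")
  })
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))
# sample() treats a length-1 numeric x as 1:x; ranges like 3:3 must not
resample <- function(x, ...) x[sample.int(length(x), ...)]
sample_range <- function(range, n) resample(range[1L]:range[2L], n, replace = TRUE)
sim_mirna_ids <- function(n) sprintf("sim-miR-%03d", seq_len(n))

#' Generate a synthetic microRNA-target database
#'
#' Each microRNA draws a uniform-random target set whose size is uniform in
#' the configured range; target sets may overlap. Deterministic given the
#' seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param seed optional seed override (defaults to \code{cfg$seed}).
#' @return a \code{target_db}.
#' @export
generate_target_db <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  genes <- sim_gene_ids(cfg$n_genes)
  mirnas <- sim_mirna_ids(cfg$n_mirnas)
  sizes <- sample_range(cfg$targets_per_mirna, cfg$n_mirnas)
  conn_m <- rep(mirnas, sizes)
  conn_g <- unlist(lapply(sizes, function(k) sample(genes, k)))
  target_db(conn_m, conn_g)
}

cap_missing <- function(row_na, n) min(row_na, max(0L, n - 4L), floor(0.15 * n))

#' Generate stage-specific expression datasets with a planted signal
#'
#' For each dataset: per-gene baseline means are drawn on a normalized
#' log-intensity-like scale (Normal(8, 2), platform-specific per dataset),
#' sample values add Normal(0, noise_sd) residuals, and recurrent samples
#' receive \code{+target_shift_delta} on every gene targeted by a planted
#' microRNA. Genes are then expanded to 1-k probes with extra probe-level
#' noise, a fraction of probes lose their annotation, and a small fraction
#' of entries go missing (capped so every probe keeps >= 85\% finite
#' values). The ground-truth record (planted microRNAs, delta, seed) is
#' returned alongside; no analysis stage reads it.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param db the \code{target_db} the signal is planted against (normally
#'   from \code{\link{generate_target_db}} with the same config).
#' @return list: \code{datasets} (list of \code{expression_dataset}),
#'   \code{truth} (list: planted, delta, seed).
#' @export
generate_expression_datasets <- function(cfg, db) {
  stopifnot(inherits(cfg, "sim_config"), inherits(db, "target_db"))
  set.seed(cfg$seed + 1L)
  mirnas <- names(db$mirna_index)
  planted <- if (cfg$planted_mirna_count > 0L)
    sort(sample(mirnas, cfg$planted_mirna_count)) else character(0)
  planted_genes <- unique(unlist(db$mirna_index[planted], use.names = FALSE))
  genes <- sim_gene_ids(cfg$n_genes)
  stages <- c(rep("II", cfg$n_datasets_stage2), rep("III", cfg$n_datasets_stage3))
  datasets <- vector("list", length(stages))
  for (d in seq_along(stages)) {
    id <- sprintf("sim_stage%s_d%d", stages[d], sum(stages[seq_len(d)] == stages[d]))
    n1 <- sample_range(cfg$samples_per_group, 1L)
    n0 <- sample_range(cfg$samples_per_group, 1L)
    n <- n1 + n0
    labels <- c(rep(1L, n1), rep(0L, n0))
    samples <- sprintf("%s_s%02d", id, seq_len(n))
    baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 2)
    gmat <- matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                   nrow = cfg$n_genes) + baseline
    if (length(planted_genes) && cfg$target_shift_delta > 0) {
      gi <- match(planted_genes, genes)
      gmat[gi, labels == 1L] <- gmat[gi, labels == 1L] + cfg$target_shift_delta
    }
    k <- sample_range(cfg$probes_per_gene, cfg$n_genes)
    gene_of_probe <- rep(seq_len(cfg$n_genes), k)
    pmat <- gmat[gene_of_probe, , drop = FALSE] +
      matrix(stats::rnorm(length(gene_of_probe) * n, sd = cfg$probe_noise_sd),
             nrow = length(gene_of_probe))
    probe_ids <- sprintf("%s_p%05d", id, seq_along(gene_of_probe))
    rownames(pmat) <- probe_ids
    colnames(pmat) <- samples
    ann <- stats::setNames(genes[gene_of_probe], probe_ids)
    if (cfg$unannotated_rate > 0) {
      drop <- stats::runif(length(ann)) < cfg$unannotated_rate
      ann[drop] <- NA_character_
    }
    if (cfg$missing_rate > 0) {
      for (i in seq_len(nrow(pmat))) {
        nna <- cap_missing(stats::rbinom(1L, n, cfg$missing_rate), n)
        if (nna > 0L) pmat[i, sample.int(n, nna)] <- NA_real_
      }
    }
    datasets[[d]] <- expression_dataset(
      dataset_id = id, values = pmat, probe_gene = ann,
      phenotype = stats::setNames(labels, samples), stage = stages[d])
  }
  list(datasets = datasets,
       truth = list(planted = planted, delta = cfg$target_shift_delta,
                    seed = cfg$seed))
}

#' Generate a synthetic qPCR validation cohort
#'
#' Relative-expression values (log10 scale) are drawn Normal per group and
#' converted back to (ct_mir, ct_ref) pairs through the exact inverse of
#' \code{\link{relative_expression}}, so the round trip reproduces the
#' drawn value to machine precision. Recurrence times are exponential with
#' a group-dependent hazard (the early-recurrence group's hazard is
#' \code{hazard_ratio} times the baseline) and administratively censored at
#' \code{censor_months}. Default group sizes, means and SDs follow the
#' validation cohort this generator emulates (27 non-early vs 41 early
#' patients, marker means 1.57 vs 1.25, common SD 0.5).
#'
#' @param n_early,n_non_early group sizes.
#' @param mean_early,mean_non_early group means of the log10 relative
#'   expression.
#' @param sd common within-group SD.
#' @param hazard_ratio early-vs-non-early hazard ratio (> 0).
#' @param baseline_hazard events per month in the non-early group.
#' @param censor_months administrative censoring time.
#' @param seed integer seed.
#' @return data.frame of class \code{qpcr_cohort} with columns sample_id,
#'   ct_mir, ct_ref, group, age, sex, stage, time_months, event, rel_expr,
#'   plus attribute \code{truth}.
#' @export
generate_qpcr_cohort <- function(n_early = 41L, n_non_early = 27L,
                                 mean_early = 1.25, mean_non_early = 1.57,
                                 sd = 0.5, hazard_ratio = 3,
                                 baseline_hazard = 0.02,
                                 censor_months = 36, seed = 1L) {
  stopifnot(n_early >= 2L, n_non_early >= 2L, sd > 0)
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  set.seed(seed)
  n <- n_early + n_non_early
  group <- c(rep("early", n_early), rep("non_early", n_non_early))
  rel <- c(stats::rnorm(n_early, mean_early, sd),
           stats::rnorm(n_non_early, mean_non_early, sd))
  ct_ref <- stats::rnorm(n, mean = 24, sd = 1)
  ct_mir <- ct_ref - rel / log10(2)   # inverse of relative_expression
  rate <- ifelse(group == "early", hazard_ratio * baseline_hazard,
                 baseline_hazard)
  t_event <- stats::rexp(n, rate = rate)
  event <- as.integer(t_event <= censor_months)
  time_months <- pmin(t_event, censor_months)
  out <- data.frame(sample_id = sprintf("P%03d", seq_len(n)),
                    ct_mir = ct_mir, ct_ref = ct_ref, group = group,
                    age = round(stats::rnorm(n, 66, 13)),
                    sex = sample(c("F", "M"), n, replace = TRUE,
                                 prob = c(0.41, 0.59)),
                    stage = sample(c("I", "II", "III"), n, replace = TRUE,
                                   prob = c(0.15, 0.45, 0.40)),
                    time_months = time_months, event = event,
                    rel_expr = rel, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(mean_early = mean_early,
                             mean_non_early = mean_non_early, sd = sd,
                             hazard_ratio = hazard_ratio, seed = seed)
  class(out) <- c("qpcr_cohort", "data.frame")
  out
}
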