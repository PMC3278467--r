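#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Materializes a full synthetic study: the target database
#' (two-column TSV), one expression TSV + probe-annotation TSV + phenotype
#' TSV per dataset, a \code{ground_truth.json} record (planted microRNAs,
#' delta, seed — written for evaluation only, never read by the analysis),
#' and a ready-to-run \code{config.yaml}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return path to the written \code{config.yaml}, invisibly.
#' @export
simulate_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  db <- generate_target_db(cfg)
  sim <- generate_expression_datasets(cfg, db)
  write_target_db(db, file.path(out_dir, "target_db.tsv"))
  ds_entries <- lapply(sim$datasets, function(ds) {
    id <- ds$dataset_id
    expr_f <- paste0(id, "_expression.tsv")
    ann_f <- paste0(id, "_annotation.tsv")
    ph_f <- paste0(id, "_phenotype.tsv")
    write_matrix_tsv(ds$values, file.path(out_dir, expr_f), id_col = "probe_id")
    ann_all <- stats::setNames(rep(NA_character_, nrow(ds$values)),
                               rownames(ds$values))
    ann_all[names(ds$probe_gene)] <- ds$probe_gene
    utils::write.table(
      data.frame(probe_id = names(ann_all),
                 gene_id = ifelse(is.na(ann_all), "", ann_all)),
      file.path(out_dir, ann_f), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(ds$phenotype),
                 group = unname(ds$phenotype), stage = ds$stage),
      file.path(out_dir, ph_f), sep = "\t", quote = FALSE, row.names = FALSE)
    list(id = id, stage = ds$stage, expression = expr_f,
         annotation = ann_f, phenotype = ph_f)
  })
  jsonlite::write_json(sim$truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- list(seed = cfg$seed, scheme = "linear", beta = 1,
                 n_perm = 1000L, alpha = 0.1, cutoff = 5e-5,
                 target_db = "target_db.tsv", datasets = ds_entries)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE, na = "NA")
  invisible(path)
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$.base <- base
  } else if (is.null(config$.base)) {
    config$.base <- "."
  }
  defaults <- list(seed = 1L, scheme = "linear", beta = 1, n_perm = 1000L,
                   alpha = 0.1, cutoff = 5e-5)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$target_db)) stop("config lacks 'target_db'")
  if (is.null(config$datasets) || !length(config$datasets))
    stop("config lacks 'datasets'")
  config
}

resolve_path <- function(base, p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))

#' Run the full analysis pipeline
#'
#' Executes, in order: probe quality control (IQR filter, probe-to-gene
#' collapse), database restriction to measured genes, per-sample activity
#' scoring, per-dataset permutation association, candidate selection across
#' datasets and stages, and meta-analysis of the cross-stage candidates
#' (all microRNAs when no candidate survives, so the ranking is still
#' reported). Every intermediate table is written to \code{out_dir} along
#' with a machine-readable \code{manifest.json} (config snapshot, input
#' digests, seed, candidate lists, package version). All input files are
#' checked before any computation starts, and rerunning with the same
#' config and seed reproduces the outputs byte for byte.
#'
#' @param config path to a YAML config file or an equivalent list. Keys:
#'   \code{seed}, \code{scheme} (linear/exponential), \code{beta},
#'   \code{n_perm}, \code{alpha}, \code{cutoff}, \code{target_db} and a
#'   \code{datasets} list of \code{id}/\code{stage}/\code{expression}/
#'   \code{annotation}/\code{phenotype} entries (paths relative to the
#'   config file).
#' @param out_dir output directory (created if needed).
#' @param verbose log per-stage counts to stderr.
#' @return the manifest, invisibly (list).
#' @export
run_full_analysis <- function(config, out_dir, verbose = FALSE) {
  config <- read_run_config(config)
  base <- config$.base
  say <- function(...) if (verbose) message(sprintf(...))
  db_path <- resolve_path(base, config$target_db)
  files <- c(db_path, unlist(lapply(config$datasets, function(d)
    resolve_path(base, c(d$expression, d$annotation, d$phenotype)))))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  stages <- vapply(config$datasets, `[[`, "", "stage")
  for (st in unique(stages))
    if (sum(stages == st) < 2L)
      warning("stage ", st, " has a single dataset; meta-analysis over k=1 is degenerate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  db <- read_target_db(db_path, format = "two_column")
  say("target db: %d connections, %d microRNAs, %d genes",
      n_connections(db), length(db$mirna_index), length(db$universe))
  scheme <- weight_scheme(config$scheme, beta = config$beta)

  assoc <- list()
  qc_log <- list()
  for (entry in config$datasets) {
    m <- read_expression_matrix(resolve_path(base, entry$expression))
    ann <- read_probe_annotation(resolve_path(base, entry$annotation))
    ph <- read_phenotype(resolve_path(base, entry$phenotype))
    ds <- expression_dataset(entry$id, m, ann,
                             stats::setNames(ph$group, ph$sample_id),
                             stage = entry$stage)
    filt <- filter_probes_by_iqr(ds)
    gm <- collapse_probes_to_genes(filt)
    dbr <- suppressWarnings(restrict_to_measured(db, rownames(gm$values)))
    say("%s: %d -> %d probes, %d genes, %d microRNAs scored",
        entry$id, nrow(ds$values), nrow(filt$values), nrow(gm$values),
        length(dbr$mirna_index))
    qc_log[[entry$id]] <- list(probes_in = nrow(ds$values),
                               probes_after_iqr = nrow(filt$values),
                               genes = nrow(gm$values),
                               mirnas_scored = length(dbr$mirna_index))
    sc <- score_dataset(gm, dbr, scheme)
    write_activity_scores(sc, file.path(out_dir, paste0("scores_", entry$id, ".tsv")))
    assoc[[entry$id]] <- associate_dataset(sc, n_perm = config$n_perm,
                                           seed = config$seed)
  }
  results <- do.call(rbind, assoc)
  rownames(results) <- NULL
  # a microRNA can lose all measured targets in one dataset; selection and
  # meta-analysis only consider microRNAs scored everywhere
  counts <- table(results$mirna_id)
  complete <- names(counts)[counts == length(config$datasets)]
  if (length(complete) < length(counts))
    say("%d microRNA(s) not scored in every dataset; excluded from selection",
        length(counts) - length(complete))
  results <- results[results$mirna_id %in% complete, , drop = FALSE]
  if (!nrow(results)) stop("no microRNA scored in every dataset")
  utils::write.table(results, file.path(out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cand <- select_candidates(results, alpha = config$alpha)
  say("candidates: %s; cross-stage: %s",
      paste(vapply(names(cand$per_stage), function(s)
        sprintf("stage %s = %d", s, length(cand$per_stage[[s]])), ""),
        collapse = ", "),
      paste(cand$cross_stage, collapse = ", "))
  meta_mirnas <- if (length(cand$cross_stage)) cand$cross_stage else NULL
  meta <- run_meta(results, mirnas = meta_mirnas, cutoff = config$cutoff)
  utils::write.table(meta, file.path(out_dir, "meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_forest_data(meta, results, file.path(out_dir, "forest.tsv"))

  manifest <- list(
    config = config[setdiff(names(config), ".base")],
    inputs = as.list(tools::md5sum(files)),
    seed = config$seed,
    qc = qc_log,
    candidates = cand,
    meta_table = "meta.tsv",
    version = as.character(utils::packageVersion("mirseer")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# per-study and pooled rows for external forest plotting
write_forest_data <- function(meta, results, path) {
  rows <- lapply(meta$mirna_id, function(m) {
    r <- results[results$mirna_id == m, , drop = FALSE]
    mrow <- meta[meta$mirna_id == m, , drop = FALSE]
    rbind(data.frame(mirna_id = m, label = r$dataset_id, effect = r$effect,
                     ci_low = r$effect - 1.96 * r$se,
                     ci_high = r$effect + 1.96 * r$se,
                     stringsAsFactors = FALSE),
          data.frame(mirna_id = m, label = c("pooled_fixed", "pooled_random"),
                     effect = c(mrow$pooled_fixed, mrow$pooled_random),
                     ci_low = c(mrow$ci95_fixed_low, mrow$ci95_random_low),
                     ci_high = c(mrow$ci95_fixed_high, mrow$ci95_random_high),
                     stringsAsFactors = FALSE))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
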