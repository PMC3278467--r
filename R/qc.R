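#' Construct an expression dataset
#'
#' Bundles a normalized probe-by-sample intensity matrix with its probe
#' annotation, the recurrence phenotype and a tumor-stage tag. One object
#' corresponds to one stage-specific dataset: an (accession, stage) pair is
#' treated as an independent unit throughout the analysis.
#'
#' @param dataset_id character scalar.
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param probe_gene named character vector probe_id -> gene_id; probes
#'   absent from it (or mapped to \code{NA}) are treated as unannotated.
#' @param phenotype named integer/numeric vector sample_id -> 0 (no
#'   recurrence) or 1 (recurrence); names must match \code{colnames(values)}
#'   exactly as a set.
#' @param stage \code{"II"} or \code{"III"}.
#' @return an object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(dataset_id, values, probe_gene, phenotype,
                               stage = c("II", "III")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("probe ids (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids (colnames) must be present and unique")
  if (!setequal(colnames(values), names(phenotype)))
    stop("phenotype sample ids do not match the expression columns")
  phenotype <- phenotype[colnames(values)]
  if (!all(phenotype %in% c(0, 1)))
    stop("phenotype must be coded 0 (non-recurrent) / 1 (recurrent)")
  if (min(table(factor(phenotype, levels = c(0, 1)))) < 2L)
    stop("each phenotype group needs at least 2 samples")
  if (any(rowSums(is.finite(values)) == 0L))
    stop("entirely missing probe row(s) present")
  probe_gene <- probe_gene[!is.na(probe_gene)]
  structure(list(dataset_id = dataset_id, values = values,
                 probe_gene = probe_gene, phenotype = phenotype,
                 stage = stage),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s' (stage %s): %d probes x %d samples (%d recurrent / %d non-recurrent)\n",
              x$dataset_id, x$stage, nrow(x$values), ncol(x$values),
              sum(x$phenotype == 1), sum(x$phenotype == 0)))
  invisible(x)
}

probe_iqrs <- function(values) {
  # type-7 (linear interpolation) quartiles, the spreadsheet convention
  apply(values, 1L, function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    q[2L] - q[1L]
  })
}

check_probe_finiteness <- function(values) {
  fin <- rowSums(is.finite(values))
  n <- ncol(values)
  bad <- fin < pmax(4L, ceiling(0.8 * n))
  if (any(bad))
    stop("probe(s) with too few finite values (need >= 4 and >= 80%): ",
         paste(utils::head(rownames(values)[bad], 5L), collapse = ", "))
  invisible(TRUE)
}

#' Filter probes by inter-quartile range
#'
#' Variance screen for uninformative probes: the IQR of every probe across
#' samples is computed once, and probes whose IQR is strictly lower than the
#' median of all probe IQRs are discarded. Probes whose IQR equals the
#' median are retained. Remaining missing entries of retained probes are
#' median-imputed per probe so that downstream ranking sees complete
#' columns.
#'
#' @param ds an \code{expression_dataset} with at least 2 probes, each at
#'   least 80\% finite and with >= 4 finite values.
#' @return the filtered \code{expression_dataset}; the computed IQRs of the
#'   retained probes are attached as attribute \code{"iqr"}.
#' @export
filter_probes_by_iqr <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (nrow(ds$values) < 2L) stop("need at least 2 probes to filter by IQR")
  check_probe_finiteness(ds$values)
  iqr <- probe_iqrs(ds$values)
  keep <- iqr >= stats::median(iqr)
  vals <- ds$values[keep, , drop = FALSE]
  if (anyNA(vals)) {
    vals <- t(apply(vals, 1L, function(v) {
      v[!is.finite(v)] <- stats::median(v, na.rm = TRUE)
      v
    }))
    colnames(vals) <- colnames(ds$values)
  }
  out <- expression_dataset(ds$dataset_id, vals, ds$probe_gene,
                            ds$phenotype, ds$stage)
  attr(out, "iqr") <- iqr[keep]
  attr(out, "n_probes_in") <- length(iqr)
  out
}

#' Collapse probes to one row per gene
#'
#' When a gene is interrogated by several probes, the probe with the
#' largest IQR is retained and the rest removed; probes of equal IQR are
#' broken by keeping the lexicographically smallest probe id. Probes with
#' no gene annotation are dropped and counted.
#'
#' @param ds an \code{expression_dataset}, normally the output of
#'   \code{\link{filter_probes_by_iqr}} (which attaches the IQRs; they are
#'   recomputed here otherwise).
#' @return a \code{gene_matrix}: list with \code{values} (gene x sample
#'   matrix), \code{dataset_id}, \code{phenotype}, \code{stage},
#'   \code{n_unannotated} (probes dropped for lack of annotation).
#' @export
collapse_probes_to_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  probes <- rownames(ds$values)
  gene <- ds$probe_gene[probes]
  annotated <- !is.na(gene)
  if (!any(annotated)) stop("no annotated probe after filtering")
  iqr <- attr(ds, "iqr")
  if (is.null(iqr)) iqr <- probe_iqrs(ds$values)
  idx <- which(annotated)
  # within gene: largest IQR first, ties broken by smallest probe id
  ord <- idx[order(gene[idx], -iqr[idx], probes[idx])]
  pick <- ord[!duplicated(gene[ord])]
  vals <- ds$values[pick, , drop = FALSE]
  rownames(vals) <- unname(gene[pick])
  structure(list(values = vals,
                 dataset_id = ds$dataset_id,
                 phenotype = ds$phenotype,
                 stage = ds$stage,
                 n_unannotated = sum(!annotated)),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("gene_matrix '%s' (stage %s): %d genes x %d samples\n",
              x$dataset_id, x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Run both quality-control steps
#'
#' Convenience wrapper: IQR probe filter followed by probe-to-gene
#' collapse.
#'
#' @inheritParams filter_probes_by_iqr
#' @return a \code{gene_matrix}.
#' @export
run_qc <- function(ds) collapse_probes_to_genes(filter_probes_by_iqr(ds))

#' Read a probe-by-sample expression matrix from TSV
#'
#' Plain layout: first column probe ids, header row of sample ids. The GEO
#' series-matrix layout is also accepted: only the block between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end} is
#' parsed and any surrounding metadata lines are ignored.
#'
#' @param path TSV file path.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  b <- grep("^!series_matrix_table_begin", lines)
  if (length(b)) {
    e <- grep("^!series_matrix_table_end", lines)
    if (!length(e)) stop("series matrix: missing !series_matrix_table_end")
    lines <- lines[(b[1L] + 1L):(e[1L] - 1L)]
  }
  tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"")
  if (ncol(tab) < 2L) stop("expression table needs a probe column and >= 1 sample")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Read a probe-to-gene annotation TSV
#'
#' Two columns with header: \code{probe_id<TAB>gene_id}. Empty gene fields
#' become \code{NA} (unannotated probes).
#'
#' @param path TSV file path.
#' @return named character vector probe_id -> gene_id.
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  g <- as.character(tab[[2L]])
  g[!nzchar(g)] <- NA_character_
  stats::setNames(g, as.character(tab[[1L]]))
}

#' Read a phenotype table
#'
#' TSV with header: \code{sample_id<TAB>group<TAB>stage}, group coded 0
#' (non-recurrent) / 1 (recurrent), stage II or III.
#'
#' @param path TSV file path.
#' @return data.frame with columns sample_id, group, stage.
#' @export
read_phenotype <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("sample_id", "group", "stage")
  if (!all(tab$group %in% c(0L, 1L)))
    stop("phenotype group must be coded 0/1")
  tab
}
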