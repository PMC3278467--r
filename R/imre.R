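#' Rank-weight scheme for activity scoring
#'
#' Genes are ranked within each sample by expression (rank 1 = highest) and
#' each rank is mapped to a weight. The \code{linear} scheme assigns
#' \code{N - r + 1}, so the weight of a gene equals its ascending-expression
#' rank; the \code{exponential} scheme assigns \code{N * exp(-beta * r / N)},
#' concentrating weight on the most highly expressed genes with decay rate
#' \code{beta}.
#'
#' @param kind \code{"linear"} (default) or \code{"exponential"}.
#' @param beta positive decay rate, used only by the exponential scheme.
#' @return an object of class \code{weight_scheme}.
#' @export
weight_scheme <- function(kind = c("linear", "exponential"), beta = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a positive number")
  structure(list(kind = kind, beta = beta), class = "weight_scheme")
}

#' Rank weights for one sample
#'
#' Ranks a sample's gene intensities (rank 1 = highest expression, ties get
#' the average rank) and applies the scheme's weight function. Weights are
#' strictly decreasing in rank, so the result depends on the expression
#' values only through their within-sample ordering: any strictly monotone
#' transform of the input leaves the weights unchanged.
#'
#' @param expr numeric vector of gene intensities for one sample (>= 2
#'   finite values); names are carried through.
#' @param scheme a \code{\link{weight_scheme}}.
#' @return numeric vector of weights, same length and names as \code{expr}.
#' @export
rank_weights <- function(expr, scheme = weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (length(expr) < 2L) stop("need at least 2 genes to rank")
  if (any(!is.finite(expr))) stop("non-finite expression value(s)")
  n <- length(expr)
  r <- rank(-expr, ties.method = "average")
  w <- switch(scheme$kind,
              linear = n - r + 1,
              exponential = n * exp(-scheme$beta * r / n))
  names(w) <- names(expr)
  w
}

#' Activity score of one microRNA in one sample
#'
#' The score is the difference between the mean rank weight of the
#' microRNA's target genes and the mean rank weight of all non-target
#' genes. Under the inverse-correlation assumption (a microRNA represses
#' its direct mRNA targets), a positive score means the targets sit high in
#' the expression ranking, i.e. the microRNA itself is inferred to be
#' down-regulated in that sample.
#'
#' @param weights named numeric vector gene -> weight (from
#'   \code{\link{rank_weights}}).
#' @param targets character vector of target gene ids; must be a non-empty
#'   proper subset of \code{names(weights)}.
#' @return scalar score: mean(weights over targets) - mean(weights over
#'   non-targets).
#' @export
activity_score <- function(weights, targets) {
  if (length(targets) == 0L) stop("empty target set")
  is_t <- names(weights) %in% targets
  nt <- sum(is_t)
  if (nt == 0L) stop("no target gene is present among the weighted genes")
  if (nt == length(weights)) stop("targets cover all genes; non-target set is empty")
  mean(weights[is_t]) - mean(weights[!is_t])
}

#' Score every microRNA in every sample of a dataset
#'
#' Computes rank weights per sample, then the target/non-target mean-weight
#' difference for every microRNA in the database. The database must already
#' be restricted to the measured genes (\code{\link{restrict_to_measured}}).
#'
#' @param gm a \code{gene_matrix} (one row per gene).
#' @param db a \code{target_db} whose universe is a subset of the measured
#'   genes.
#' @param scheme a \code{\link{weight_scheme}}.
#' @return a numeric matrix (microRNA x sample) of class
#'   \code{activity_scores}, with attributes \code{dataset_id},
#'   \code{stage}, \code{phenotype} and \code{scheme}.
#' @export
score_dataset <- function(gm, db, scheme = weight_scheme()) {
  stopifnot(inherits(gm, "gene_matrix"), inherits(db, "target_db"))
  genes <- rownames(gm$values)
  missing <- setdiff(db$universe, genes)
  if (length(missing))
    stop("database not restricted to measured genes; unmeasured targets: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  n_genes <- length(genes)
  weights <- apply(gm$values, 2L, rank_weights, scheme = scheme)
  rownames(weights) <- genes
  mirnas <- names(db$mirna_index)
  # indicator matrix (mirna x gene): score row = t_mean - nt_mean, computed
  # for all microRNAs at once via one matrix product
  ind <- matrix(0, nrow = length(mirnas), ncol = n_genes,
                dimnames = list(mirnas, genes))
  for (m in mirnas) ind[m, db$mirna_index[[m]]] <- 1
  k <- rowSums(ind)
  if (any(k == 0L)) stop("microRNA with no measured target after restriction")
  if (any(k == n_genes)) stop("microRNA targeting every measured gene")
  tsum <- ind %*% weights
  total <- colSums(weights)
  scores <- tsum / k - (matrix(total, nrow = length(mirnas),
                               ncol = ncol(weights), byrow = TRUE) - tsum) /
    (n_genes - k)
  structure(scores,
            dataset_id = gm$dataset_id, stage = gm$stage,
            phenotype = gm$phenotype, scheme = scheme,
            class = c("activity_scores", "matrix", "array"))
}

#' Write an activity-score matrix as TSV
#'
#' The first line is a provenance comment
#' (\code{# dataset=... scheme=... beta=...}); then a header row of sample
#' ids and one row per microRNA.
#'
#' @param scores an \code{activity_scores} matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_activity_scores <- function(scores, path) {
  scheme <- attr(scores, "scheme")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dataset=%s scheme=%s beta=%g",
                     attr(scores, "dataset_id"), scheme$kind, scheme$beta), con)
  writeLines(paste(c("mirna_id", colnames(scores)), collapse = "\t"), con)
  utils::write.table(format(unclass(scores), digits = 15, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  invisible(path)
}
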