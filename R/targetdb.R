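#' Construct a microRNA-target connection database
#'
#' A \code{target_db} is the scoring universe: a set of (microRNA, gene)
#' connection pairs, a per-microRNA index of target genes, and the universe
#' of all genes appearing in any connection. Duplicate pairs are collapsed.
#'
#' @param mirna_id character vector of microRNA identifiers.
#' @param gene_id character vector of gene identifiers, same length.
#' @return An object of class \code{target_db} with components
#'   \code{connections} (data.frame of unique pairs), \code{mirna_index}
#'   (named list mirna -> character vector of targets) and \code{universe}
#'   (sorted character vector of all genes).
#' @export
target_db <- function(mirna_id, gene_id) {
  stopifnot(is.character(mirna_id), is.character(gene_id),
            length(mirna_id) == length(gene_id))
  if (length(mirna_id) == 0L)
    stop("target database is empty: no connections")
  if (any(!nzchar(mirna_id)) || any(!nzchar(gene_id)))
    stop("empty microRNA or gene identifier in connection table")
  keep <- !duplicated(paste(mirna_id, gene_id, sep = "\r"))
  conn <- data.frame(mirna_id = mirna_id[keep], gene_id = gene_id[keep],
                     stringsAsFactors = FALSE)
  conn <- conn[order(conn$mirna_id, conn$gene_id), , drop = FALSE]
  rownames(conn) <- NULL
  idx <- split(conn$gene_id, conn$mirna_id)
  structure(list(connections = conn,
                 mirna_index = idx,
                 universe = sort(unique(conn$gene_id))),
            class = "target_db")
}

#' @export
print.target_db <- function(x, ...) {
  cat(sprintf("target_db: %d connections between %d microRNAs and %d genes\n",
              nrow(x$connections), length(x$mirna_index), length(x$universe)))
  invisible(x)
}

#' Number of connections in a target database
#' @param db a \code{target_db}.
#' @return integer count of unique (microRNA, gene) pairs.
#' @export
n_connections <- function(db) nrow(db$connections)

#' Read a microRNA-target connection table
#'
#' Supports two dialects. \code{two_column}: TSV with header
#' \code{mirna_id<TAB>gene_id}, one connection per line. \code{microcosm_v5}:
#' TSV with named columns and \code{#} comment lines; the microRNA and gene
#' columns are selected by name (defaults \code{SEQ} and \code{EXTERNAL_NAME},
#' the layout of MicroCosm Targets v5 exports).
#'
#' Duplicate pairs are collapsed. An optional alias map translates gene
#' synonyms to canonical symbols before deduplication, since probe
#' annotations from different array platforms do not always use the same
#' symbol as the target database. Identifier matching downstream is exact,
#' case-sensitive string equality.
#'
#' @param path path to the connection table.
#' @param format \code{"two_column"} (default) or \code{"microcosm_v5"}.
#' @param mirna_col,gene_col column names for the microcosm_v5 dialect.
#' @param alias optional alias map: a named character vector
#'   (\code{alias -> canonical}) or a path to a two-column TSV
#'   \code{alias<TAB>canonical} with header.
#' @param species_prefix optional prefix filter on microRNA ids (e.g.
#'   \code{"hsa-"} to keep human microRNAs only); \code{NULL} keeps all.
#' @param verbose print counts after reading.
#' @return a \code{target_db}.
#' @export
read_target_db <- function(path, format = c("two_column", "microcosm_v5"),
                           mirna_col = "SEQ", gene_col = "EXTERNAL_NAME",
                           alias = NULL, species_prefix = NULL,
                           verbose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("target database file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("target database file is empty (no data lines): ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  if (format == "two_column") {
    mi <- 1L; gi <- 2L
    need <- 2L
  } else {
    mi <- match(mirna_col, header)
    gi <- match(gene_col, header)
    if (is.na(mi) || is.na(gi))
      stop("microcosm_v5 header lacks column(s): ",
           paste(c(mirna_col, gene_col)[c(is.na(mi), is.na(gi))], collapse = ", "))
    need <- max(mi, gi)
  }
  nf <- lengths(body)
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, found %d",
                 bad[1L] + 1L, path, need, nf[bad[1L]]))
  mirna <- vapply(body, `[[`, "", mi)
  gene <- vapply(body, `[[`, "", gi)
  if (!is.null(alias)) {
    map <- read_alias_map(alias)
    hit <- gene %in% names(map)
    gene[hit] <- unname(map[gene[hit]])
  }
  if (!is.null(species_prefix)) {
    keep <- startsWith(mirna, species_prefix)
    if (!any(keep)) stop("no microRNA matches species prefix ", species_prefix)
    mirna <- mirna[keep]; gene <- gene[keep]
  }
  db <- target_db(mirna, gene)
  if (verbose)
    message(sprintf("read %d connections: %d microRNAs, %d genes",
                    n_connections(db), length(db$mirna_index),
                    length(db$universe)))
  db
}

read_alias_map <- function(alias) {
  if (is.character(alias) && length(alias) == 1L && file.exists(alias)) {
    tab <- utils::read.delim(alias, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("alias map must have two columns")
    alias <- stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  }
  if (is.null(names(alias)) || any(!nzchar(names(alias))))
    stop("alias map must be a named character vector (alias -> canonical)")
  alias
}

#' Write a target database as a two-column TSV
#'
#' Round-trips losslessly with \code{read_target_db(format = "two_column")}.
#'
#' @param db a \code{target_db}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_target_db <- function(db, path) {
  stopifnot(inherits(db, "target_db"))
  utils::write.table(db$connections, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Restrict a target database to measured genes
#'
#' Scoring operates only on genes present in the expression matrix after
#' quality control, so connections to unmeasured genes are removed.
#' MicroRNAs left with no target are dropped with a warning.
#'
#' @param db a \code{target_db}.
#' @param measured_genes character vector of gene ids present in the data.
#' @return a \code{target_db} whose universe is a subset of
#'   \code{measured_genes}.
#' @export
restrict_to_measured <- function(db, measured_genes) {
  stopifnot(inherits(db, "target_db"))
  if (length(measured_genes) == 0L) stop("measured_genes is empty")
  keep <- db$connections$gene_id %in% measured_genes
  if (!any(keep))
    stop("no database gene overlaps the expression matrix")
  conn <- db$connections[keep, , drop = FALSE]
  dropped <- setdiff(names(db$mirna_index), unique(conn$mirna_id))
  if (length(dropped))
    warning(sprintf("%d microRNA(s) dropped (no measured target): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  target_db(conn$mirna_id, conn$gene_id)
}
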