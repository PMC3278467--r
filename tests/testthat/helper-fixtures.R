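# in-code fixtures shared across test files

# write a two-column connection TSV and return its path
write_conn_tsv <- function(pairs, path = tempfile(fileext = ".tsv")) {
  writeLines(c("mirna_id\tgene_id", vapply(pairs, paste, "", collapse = "\t")),
             path)
  path
}

# tiny expression dataset: rows built to have exact IQRs under type-7
# quartiles (IQR of s * (0,1,2,3) is 1.5 * s)
make_iqr_dataset <- function() {
  base <- c(0, 1, 2, 3)
  vals <- rbind(p1 = base * 0, p2 = base * (2 / 3), p3 = base * (4 / 3),
                p4 = base * 2)  # IQRs 0, 1, 2, 3
  colnames(vals) <- paste0("s", 1:4)
  expression_dataset(
    "fix", vals,
    probe_gene = c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gB"),
    phenotype = c(s1 = 0, s2 = 0, s3 = 1, s4 = 1), stage = "II")
}

# small dataset with k probes per gene and known annotation
make_small_dataset <- function(n_genes = 20, n_samples = 10, seed = 11) {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples, 8, 2), nrow = n_genes,
                 dimnames = list(sprintf("pr%02d", 1:n_genes),
                                 sprintf("s%02d", 1:n_samples)))
  expression_dataset(
    "small", vals,
    probe_gene = setNames(sprintf("g%02d", 1:n_genes), rownames(vals)),
    phenotype = setNames(rep(c(0, 1), each = n_samples / 2), colnames(vals)),
    stage = "II")
}

# brute-force empirical survival function (no censoring): S(t) = P(T > t)
empirical_survival <- function(times, at) {
  vapply(at, function(t) mean(times > t), 0)
}
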