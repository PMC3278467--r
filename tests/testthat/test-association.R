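test_that("effect and SE follow the two-group formulas", {
  es <- effect_and_se(c(3, 5, 1, 1), c(1, 1, 0, 0))
  expect_equal(es$effect, 3.0)
  expect_equal(es$se, 1.0)
  expect_equal(effect_and_se(c(2, 4, 2, 4), c(1, 1, 0, 0))$effect, 0)
  # swapping the label coding negates the effect, SE unchanged
  x <- rnorm(12); l <- rep(c(0, 1), 6)
  a <- effect_and_se(x, l); b <- effect_and_se(x, 1 - l)
  expect_equal(b$effect, -a$effect)
  expect_equal(b$se, a$se)
  expect_error(effect_and_se(c(1, 2, 3), c(1, 0, 0)), "at least 2")
})

test_that("exhaustive permutation p matches hand enumeration", {
  # scores (10, 9, 1, 2), labels (1,1,0,0): |T_obs| = 8; 2 of the C(4,2) = 6
  # assignments reach |T*| >= 8
  p <- permutation_pvalue(c(10, 9, 1, 2), c(1, 1, 0, 0), exhaustive = TRUE)
  expect_equal(p, 2 / 6)
  # all scores equal: every permuted statistic ties T_obs = 0
  expect_equal(permutation_pvalue(rep(1, 6), rep(c(0, 1), 3), exhaustive = TRUE), 1)
  expect_equal(permutation_pvalue(rep(1, 6), rep(c(0, 1), 3), n_perm = 50, seed = 1), 1)
  expect_error(permutation_pvalue(rnorm(22), rep(c(0, 1), 11), exhaustive = TRUE),
               "<= 20")
})

test_that("Monte-Carlo p approaches the exhaustive p and is seed-reproducible", {
  sc <- c(10, 9, 1, 2); lb <- c(1, 1, 0, 0)
  p1 <- permutation_pvalue(sc, lb, n_perm = 1000, seed = 9)
  expect_equal(p1, permutation_pvalue(sc, lb, n_perm = 1000, seed = 9))
  # 99% binomial envelope around the exhaustive value 1/3 (+ smoothing slack)
  expect_lt(abs(p1 - 1 / 3), 2.576 * sqrt((1 / 3) * (2 / 3) / 1000) + 2 / 1001)
  # convergence on a larger instance
  set.seed(4)
  sc2 <- rnorm(12); lb2 <- rep(c(0, 1), each = 6)
  pex <- permutation_pvalue(sc2, lb2, exhaustive = TRUE)
  pmc <- permutation_pvalue(sc2, lb2, n_perm = 20000, seed = 2)
  expect_lt(abs(pmc - pex), 2.576 * sqrt(pex * (1 - pex) / 20000) + 2 / 20001)
})

test_that("permutation p is invariant to location and positive scale", {
  set.seed(8)
  sc <- rnorm(10); lb <- rep(c(0, 1), 5)
  p0 <- permutation_pvalue(sc, lb, n_perm = 500, seed = 3)
  expect_equal(permutation_pvalue(sc + 100, lb, n_perm = 500, seed = 3), p0)
  expect_equal(permutation_pvalue(sc * 7.5, lb, n_perm = 500, seed = 3), p0)
})

test_that("associate_dataset is reproducible and independent of row order", {
  ds <- make_small_dataset(n_genes = 16, n_samples = 12)
  gm <- collapse_probes_to_genes(ds)
  genes <- rownames(gm$values)
  db <- target_db(rep(c("mA", "mB", "mC"), each = 4),
                  c(genes[1:4], genes[5:8], genes[9:12]))
  sc <- score_dataset(gm, db)
  r1 <- associate_dataset(sc, n_perm = 300, seed = 5)
  r2 <- associate_dataset(sc, n_perm = 300, seed = 5)
  expect_identical(r1, r2)
  # reordering microRNA rows must not change any per-microRNA p-value
  sc_rev <- structure(unclass(sc)[rev(rownames(sc)), ],
                      dataset_id = attr(sc, "dataset_id"),
                      stage = attr(sc, "stage"),
                      phenotype = attr(sc, "phenotype"),
                      scheme = attr(sc, "scheme"), class = class(sc))
  r3 <- associate_dataset(sc_rev, n_perm = 300, seed = 5)
  r3 <- r3[match(r1$mirna_id, r3$mirna_id), ]
  expect_equal(r1$p_perm, r3$p_perm)
})

test_that("candidate selection requires the cutoff in every dataset plus sign consistency", {
  row <- function(m, d, st, eff, p)
    data.frame(mirna_id = m, dataset_id = d, stage = st, effect = eff,
               se = 1, p_perm = p, n_rec = 10, n_nonrec = 10, n_perm = 1000)
  res <- rbind(
    # consistent with a selected microRNA: p (0.08, 0.009, 0.02), same sign
    row("miR-29a", "d1", "II", 5, 0.08), row("miR-29a", "d2", "II", 4, 0.009),
    row("miR-29a", "d3", "II", 6, 0.02),
    # one dataset above alpha -> excluded
    row("miR-x", "d1", "II", 5, 0.2), row("miR-x", "d2", "II", 4, 0.01),
    row("miR-x", "d3", "II", 6, 0.01),
    # low p everywhere but inconsistent sign -> excluded
    row("miR-s", "d1", "II", 5, 0.01), row("miR-s", "d2", "II", -4, 0.01),
    row("miR-s", "d3", "II", 6, 0.01),
    # stage III block: miR-29a consistent there too, miR-only2 only in III
    row("miR-29a", "e1", "III", 5, 0.05), row("miR-29a", "e2", "III", 4, 0.04),
    row("miR-x", "e1", "III", 5, 0.5), row("miR-x", "e2", "III", 4, 0.5),
    row("miR-s", "e1", "III", 5, 0.5), row("miR-s", "e2", "III", 4, 0.5),
    row("miR-only2", "d1", "II", 3, 0.01), row("miR-only2", "d2", "II", 3, 0.01),
    row("miR-only2", "d3", "II", 3, 0.01),
    row("miR-only2", "e1", "III", 3, 0.9), row("miR-only2", "e2", "III", 3, 0.9))
  sel <- select_candidates(res, alpha = 0.1)
  expect_setequal(sel$per_stage$II, c("miR-29a", "miR-only2"))
  expect_equal(sel$per_stage$III, "miR-29a")
  expect_equal(sel$cross_stage, "miR-29a")
  # a missing (mirna, dataset) pair is an error naming the gap
  expect_error(select_candidates(res[-1, ]), "miR-29a.*d1")
})

test_that("permutation p-values are calibrated under label-independent scores", {
  set.seed(31)
  n <- 16; lb <- rep(c(0, 1), each = n / 2)
  p <- replicate(250, permutation_pvalue(rnorm(n), lb, n_perm = 150))
  frac <- mean(p <= 0.1)
  # 95% binomial envelope around 0.1 at 250 replicates
  expect_gte(frac, 0.1 - 1.96 * sqrt(0.1 * 0.9 / 250))
  expect_lte(frac, 0.1 + 1.96 * sqrt(0.1 * 0.9 / 250) + 0.01)
})
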