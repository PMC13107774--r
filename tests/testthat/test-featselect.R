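test_that("variance filter keeps columns by population variance", {
  m <- cbind(const = c(1, 1, 1, 1), binary = c(0, 1, 0, 1),
             tiny = c(0, 1e-4, 0, 1e-4))
  expect_equal(variance_filter(m, 1e-5), 2L)   # var 0.25 kept, 2.5e-9 dropped
  set.seed(21)
  r <- matrix(rnorm(200), 10, 20)
  eps <- 0.8
  want <- which(vapply(seq_len(20), function(j) {
    mu <- sum(r[, j]) / 10
    sum((r[, j] - mu)^2) / 10 >= eps
  }, logical(1)))
  expect_equal(variance_filter(r, eps), want)
  expect_error(variance_filter(r[1, , drop = FALSE]), "at least 2")
})

test_that("ANOVA F matches the hand-worked example and the lm oracle", {
  m <- matrix(c(0, 1, 2, 3), 4, 1)
  lab <- c("A", "A", "B", "B")
  expect_equal(anova_f(m, lab), 8)   # MSB = 4, MSW = 0.5

  # equal class means give F = 0
  expect_equal(anova_f(matrix(c(1, 2, 1, 2), 4, 1), lab), 0)

  # MSW = 0 is guarded: perfectly separating feature ranks above all others
  sep <- cbind(c(0, 0, 1, 1), c(0, 1, 2, 3))
  f <- anova_f(sep, lab)
  expect_true(is.finite(f[1]) && f[1] > f[2])

  set.seed(9)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    g <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c("A", "B")
    r <- matrix(rnorm(n * 5), n, 5)
    expect_equal(anova_f(r, g), lm_anova_f(r, g), tolerance = 1e-9)
  }
  expect_error(anova_f(m, rep("A", 4)), "at least 2 classes")
})

test_that("top-K retention caps at K with index tie-breaking", {
  set.seed(2)
  f <- runif(12000)
  expect_length(anova_top_k(f, 10000), 10000)
  expect_equal(anova_top_k(runif(50), 10000), 1:50)   # 'up to' semantics
  # two equal F values at the boundary: the lower index wins
  expect_equal(anova_top_k(c(5, 3, 3, 1), 2), c(1L, 2L))
})

test_that("min-max normalization and fusion behave as specified", {
  nm <- minmax_normalize(c(2, 4, 6))
  expect_equal(nm[1], 0)
  expect_equal(nm[2], 0.5, tolerance = 1e-9)
  expect_equal(nm[3], 1, tolerance = 1e-9)
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))

  expect_equal(fused_score(1, 0, 0, 0), 0.3)
  expect_equal(fused_score(0.4, 0.4, 0.4, 0.4), 0.4)
  expect_equal(fused_score(0, 0, 0, 0), 0)
  expect_error(fused_score(c(1, 2), 1, 1, 1), "mismatched")
  expect_error(fused_score(1, 1, 1, 1, weights = c(1, 1, 1, 1)), "sum to 1")
})

test_that("metric scores are non-negative and track label association", {
  set.seed(14)
  n <- 40
  lab <- rep(c("SubFS", "SFS"), each = n / 2)
  m <- cbind(signal = as.numeric(lab == "SFS"),
             noise = rnorm(n))
  sc <- metric_scores(m, lab, seed = 3)
  expect_true(all(sc$F >= 0 & sc$MI >= 0 & sc$chi2 >= 0 & sc$RF >= 0))
  # a feature identical to the label maximizes every metric
  expect_equal(unname(which.max(sc$MI)), 1L)
  expect_equal(unname(which.max(sc$F)), 1L)
  # label-independent feature has near-zero MI compared with the signal
  expect_lt(sc$MI[2], sc$MI[1] / 2)
  expect_error(metric_scores(m, rep("SFS", n)), "both classes")
})

test_that("stability fusion reduces to a single pass at N=1, fraction=1", {
  set.seed(31)
  n <- 20
  lab <- rep(c("SubFS", "SFS"), each = n / 2)
  m <- matrix(rnorm(n * 8), n, 8)
  m[, 1] <- m[, 1] + 2 * (lab == "SFS")
  cfg <- selection_config(resample_rounds = 1, resample_fraction = 1,
                          keep_fraction = 0.75, rng_seed = 7)
  fus <- stability_fusion(m, lab, cfg)
  sc <- metric_scores(m, lab, cfg, seed = cfg$rng_seed + 100L + 1L)
  manual <- fused_score(minmax_normalize(sc$F), minmax_normalize(sc$MI),
                        minmax_normalize(sc$chi2), minmax_normalize(sc$RF))
  expect_equal(fus$scores$s_bar, manual, tolerance = 1e-12)
  expect_length(fus$retained, 6)   # top 75% of 8
  expect_equal(ncol(fus$fused_rounds), 1)

  # repeated runs with the same seed are bit-identical
  cfg5 <- selection_config(rng_seed = 13)
  f1 <- stability_fusion(m, lab, cfg5)
  f2 <- stability_fusion(m, lab, cfg5)
  expect_identical(f1$scores, f2$scores)
  expect_equal(ncol(f1$fused_rounds), 5)
})

test_that("correlation pruning matches the naive average-linkage oracle", {
  # identical and perfectly anti-correlated columns collapse to one cluster
  x <- rnorm(30)
  m <- cbind(x, x, -x)
  pr <- correlation_prune(m, s_bar = c(0.9, 0.5, 0.2), cut_distance = 0.3)
  expect_equal(length(unique(pr$clusters)), 1)
  expect_equal(pr$representatives, 1L)   # highest fused score wins

  set.seed(77)
  for (i in 1:5) {
    p <- sample(10:30, 1)
    n <- 50
    mm <- matrix(rnorm(n * p), n, p)
    # add a few correlated pairs so clustering is non-trivial
    mm[, 2] <- mm[, 1] + rnorm(n, 0, 0.1)
    mm[, 5] <- -mm[, 4] + rnorm(n, 0, 0.1)
    sb <- runif(p)
    pr <- correlation_prune(mm, sb, cut_distance = 0.3)
    D <- 1 - abs(stats::cor(mm))
    want <- naive_average_linkage(D, 0.3)
    expect_equal(canonical_partition(pr$clusters), canonical_partition(want))
    want_reps <- vapply(split(seq_len(p), want), function(mem) {
      mem[order(-sb[mem], mem)][1]
    }, integer(1))
    expect_equal(pr$representatives, sort(unname(want_reps)))
  }
})

test_that("full selection has monotone stage counts and is reproducible", {
  co <- tiny_cohort()
  tr <- co$kmat$strain_ids
  lab <- co$scores$label[match(tr, co$scores$strain_id)]
  cfg <- selection_config(rng_seed = 19)
  sel <- run_selection(co$kmat, lab, cfg)
  counts <- sel$stage_counts
  expect_true(all(diff(counts) <= 0))
  expect_equal(unname(counts["input"]), 349184)
  expect_true(all(diff(sel$indices) > 0))
  # bit-reproducible under the same seed
  sel2 <- run_selection(co$kmat, lab, cfg)
  expect_identical(sel$indices, sel2$indices)
  expect_identical(sel$scores, sel2$scores)
})

test_that("keep_fraction 1 + zero cut distance keeps one per duplicate group", {
  set.seed(55)
  n <- 20
  lab <- rep(c("SubFS", "SFS"), each = n / 2)
  base <- matrix(rnorm(n * 4), n, 4) + 2 * outer(lab == "SFS", rep(1, 4))
  m <- cbind(base, base[, 2])   # exact duplicate of column 2
  cfg <- selection_config(variance_eps = 0, keep_fraction = 1,
                          cluster_cut_distance = 0, resample_rounds = 1,
                          resample_fraction = 1, rng_seed = 4)
  sel <- run_selection(m, lab, cfg)
  expect_equal(unname(sel$stage_counts["fusion"]), 5)
  # duplicates 2 and 5 merged; everything else kept
  expect_equal(unname(sel$stage_counts["cluster"]), 4)
  expect_false(all(c(2, 5) %in% sel$indices))
  expect_true(any(c(2, 5) %in% sel$indices))
})
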