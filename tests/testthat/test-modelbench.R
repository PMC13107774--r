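test_that("stratified split honors the 60/40 ratio and class balance", {
  ids <- sprintf("s%03d", 1:100)
  lab <- rep(c("SFS", "SubFS"), 50)
  sp <- stratified_split(ids, lab, 0.60, seed = 3)
  expect_length(sp$train, 60)
  expect_length(sp$test, 40)
  tr_lab <- lab[match(sp$train, ids)]
  expect_equal(unname(table(tr_lab)), c(30L, 30L), ignore_attr = TRUE)
  expect_setequal(c(sp$train, sp$test), ids)

  # 67 strains at 34/33: per-class train counts within 1 of global proportion
  ids67 <- sprintf("t%02d", 1:67)
  lab67 <- c(rep("SFS", 34), rep("SubFS", 33))
  sp67 <- stratified_split(ids67, lab67, 0.60, seed = 1)
  expect_length(sp67$train, round(67 * 0.6))
  props <- table(lab67[match(sp67$train, ids67)]) / length(sp67$train)
  expect_true(all(abs(props - table(lab67) / 67) <= 1 / length(sp67$train)))

  expect_error(stratified_split(ids, lab, 1.0, seed = 1), "train_fraction")
  expect_error(stratified_split(c("a", "b", "c"), c("x", "x", "y"), 0.6, 1),
               "at least 2 members")

  sp_a <- stratified_split(ids, lab, 0.6, seed = 9)
  sp_b <- stratified_split(ids, lab, 0.6, seed = 9)
  sp_c <- stratified_split(ids, lab, 0.6, seed = 10)
  expect_identical(sp_a$train, sp_b$train)
  expect_false(identical(sp_a$train, sp_c$train))
})

test_that("AUC equals the normalized pairwise-comparison statistic", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c("SFS", "SFS", "SubFS", "SubFS")),
               1.0)
  expect_equal(auc(rep(0.4, 6), rep(c("SFS", "SubFS"), 3)), 0.5)
  expect_error(auc(1:3, rep("SFS", 3)), "both classes")

  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    lab <- sample(c("SFS", "SubFS"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("SFS", "SubFS")
    s <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
    expect_equal(auc(s, lab), naive_auc(s, lab))
  }
})

test_that("repeated holdout runs every family for every round", {
  set.seed(41)
  n <- 40
  lab <- factor(rep(c("SubFS", "SFS"), each = n / 2),
                levels = c("SubFS", "SFS"))
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + 4 * (lab == "SFS")   # cleanly separable
  rep10 <- suppressWarnings(repeated_holdout(x, lab, rounds = 10, seed = 5))
  expect_equal(dim(rep10$auc_rounds), c(8L, 10L))
  expect_true(all(!is.na(rep10$auc_rounds)))
  expect_true(all(rep10$auc_rounds >= 0 & rep10$auc_rounds <= 1))
  expect_equal(rep10$mean_auc, rowMeans(rep10$auc_rounds))
  expect_equal(max(rep10$mean_auc), 1.0)   # separable data
  expect_equal(rep10$chosen, rep10$ranking[1])
  expect_equal(unname(rep10$mean_auc[rep10$chosen]), max(rep10$mean_auc))
})

test_that("null calibration: permuted labels give near-chance AUC everywhere", {
  set.seed(67)
  n <- 200
  lab <- sample(rep(c("SubFS", "SFS"), each = n / 2))
  x <- matrix(rnorm(n * 10), n, 10)
  repn <- suppressWarnings(repeated_holdout(x, lab, rounds = 10, seed = 8))
  expect_true(all(repn$mean_auc >= 0.35 & repn$mean_auc <= 0.65))
})

test_that("winner refit is evaluated on held-out data without leakage", {
  co <- tiny_cohort()
  cfg <- selection_config(rng_seed = 3)
  res <- suppressWarnings(screen_strains(co$kmat, co$scores, cfg, seed = 5))
  expect_gte(res$report$test_auc, 0.95)   # easy simulated contrast

  # corrupting the held-out rows changes nothing fitted on training data
  km2 <- co$kmat
  test_rows <- match(res$split$test, km2$strain_ids)
  set.seed(99)
  for (r in test_rows) {
    km2$values[r, ] <- sample(km2$values[r, ])
  }
  res2 <- suppressWarnings(screen_strains(km2, co$scores, cfg, seed = 5))
  expect_identical(res$split$train, res2$split$train)
  expect_identical(res$selection$indices, res2$selection$indices)
  expect_identical(res$selection$scores, res2$selection$scores)
  expect_identical(res$report$auc_rounds, res2$report$auc_rounds)
})

test_that("final bundle round-trips and refuses vocabulary mismatches", {
  co <- tiny_cohort()
  bundle <- suppressWarnings(
    fit_final(co$kmat, co$scores, "rf", selection_config(rng_seed = 3),
              seed = 5)
  )
  expect_s3_class(bundle, "model_bundle")
  expect_identical(bundle$config$rng_seed, 3L)

  path <- tempfile(fileext = ".rds")
  write_bundle(bundle, path)
  reloaded <- read_bundle(path)
  probe <- co$fx$fasta[1:2]
  expect_identical(predict(bundle, probe), predict(reloaded, probe))

  broken <- bundle
  broken$vocab_descriptor <- "k=5,6;dim=5120"
  expect_error(predict(broken, probe), "vocabulary descriptor mismatch")

  corrupt <- tempfile(fileext = ".rds")
  saveRDS(list(), corrupt)
  expect_error(read_bundle(corrupt), "not a model bundle")
})
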