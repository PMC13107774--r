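#' Stratified train/test split
#'
#' Splits strain ids into training and test sets at the given fraction
#' (default 60% train / 40% test) with stratified sampling, so per-class
#' training proportions stay within one sample of the global proportion.
#' Per-class training counts are rounded and then adjusted by largest
#' remainder so the total equals round(n * fraction).
#'
#' @param ids Character vector of strain ids.
#' @param labels Class labels aligned with `ids`; every class needs >= 2
#'   members.
#' @param train_fraction Fraction of strains assigned to training
#'   (in (0, 1)).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A `data_split` list with `train`, `test`, `seed`,
#'   `train_fraction`.
#' @export
stratified_split <- function(ids, labels, train_fraction = 0.60, seed = 1L) {
  stopifnot(length(ids) == length(labels))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1): an empty train or test set is ",
         "not a usable split")
  }
  labels <- droplevels(as.factor(labels))
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every class needs at least 2 members; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  n_train <- round(length(ids) * train_fraction)
  raw <- as.numeric(tab) * train_fraction
  base <- floor(raw)
  base <- pmin(pmax(base, 1), as.numeric(tab) - 1)  # keep both sides non-empty
  short <- n_train - sum(base)
  if (short > 0) {
    ord <- order(-(raw - floor(raw)), seq_along(base))
    for (i in ord) {
      if (short == 0) break
      if (base[i] < tab[i] - 1) { base[i] <- base[i] + 1; short <- short - 1 }
    }
  } else if (short < 0) {
    ord <- order(raw - floor(raw), seq_along(base))
    for (i in ord) {
      if (short == 0) break
      if (base[i] > 1) { base[i] <- base[i] - 1; short <- short + 1 }
    }
  }
  set.seed(seed)
  train <- unlist(lapply(seq_along(levels(labels)), function(ci) {
    pool <- ids[labels == levels(labels)[ci]]
    sample(pool, base[ci])
  }), use.names = FALSE)
  structure(
    list(train = sort(train), test = sort(setdiff(ids, train)),
         seed = as.integer(seed), train_fraction = train_fraction),
    class = "data_split"
  )
}

#' @export
print.data_split <- function(x, ...) {
  cat("<data_split> ", length(x$train), " train / ", length(x$test),
      " test (fraction ", x$train_fraction, ", seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties counted one half. Equivalent
#' to the normalized U statistic; all-tied scores give exactly 0.5.
#'
#' @param scores Continuous classifier scores for the positive class.
#' @param labels Class labels; `positive` names the positive level.
#' @param positive Positive class label (default `"SFS"`).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels, positive = "SFS") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated-holdout benchmarking of the classifier registry
#'
#' For each of `rounds` rounds, draws a stratified inner split of the
#' training strains (default 80% inner-train / 20% inner-validation, seeded
#' `seed + round`), fits every classifier family on the inner-training rows
#' and computes the validation AUC from its continuous SFS scores. A family
#' that errors in a round is recorded as missing for that round (with a
#' warning) and excluded from its mean.
#'
#' @param x Numeric design matrix of training strains (standardized selected
#'   features).
#' @param labels Class labels aligned with rows of `x`.
#' @param families Character vector of registry family ids (default: all
#'   eight).
#' @param rounds Number of repeated-holdout rounds (default 10).
#' @param inner_fraction Inner-training fraction per round (default 0.8).
#' @param seed Base seed.
#' @return A `benchmark_report` with the per-round AUC table, per-family
#'   means, the ranking and the chosen family.
#' @export
repeated_holdout <- function(x, labels, families = NULL, rounds = 10L,
                             inner_fraction = 0.8, seed = 1L) {
  stopifnot(rounds >= 1)
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  reg <- classifier_registry(families)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  rownames(x) <- ids
  auc_tab <- matrix(NA_real_, length(reg), rounds,
                    dimnames = list(names(reg), paste0("round", 1:rounds)))
  for (r in seq_len(rounds)) {
    sp <- stratified_split(ids, labels, inner_fraction, seed = seed + r)
    tr <- match(sp$train, ids); va <- match(sp$test, ids)
    for (fam in names(reg)) {
      res <- tryCatch({
        model <- reg[[fam]]$fit(x[tr, , drop = FALSE], labels[tr],
                                seed = seed + 7000L + r)
        s <- reg[[fam]]$score(model, x[va, , drop = FALSE])
        auc(s, labels[va])
      }, error = function(e) {
        warning("family '", fam, "' failed in round ", r, ": ",
                conditionMessage(e))
        NA_real_
      })
      auc_tab[fam, r] <- res
    }
  }
  mean_auc <- rowMeans(auc_tab, na.rm = TRUE)
  # ties broken by registry order
  ranking <- names(reg)[order(-mean_auc, seq_along(mean_auc))]
  structure(
    list(auc_rounds = auc_tab, mean_auc = mean_auc, ranking = ranking,
         chosen = ranking[1], rounds = rounds,
         inner_fraction = inner_fraction, seed = as.integer(seed),
         test_auc = NA_real_),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", nrow(x$auc_rounds), " families x ", x$rounds,
      " rounds; chosen: ", x$chosen, " (mean AUC ",
      sprintf("%.3f", x$mean_auc[x$chosen]), ")", sep = "")
  if (!is.na(x$test_auc)) cat("; test AUC ", sprintf("%.3f", x$test_auc),
                              sep = "")
  cat("\n")
  invisible(x)
}

#' Refit the winning family and evaluate it on the held-out test set
#'
#' The family with the highest mean repeated-holdout AUC is refit on the
#' full training design and scored on the test design. Both designs must
#' have been produced with feature selection and standardization fitted on
#' the training strains only, so no test information leaks into the model.
#'
#' @param report A `benchmark_report` from [repeated_holdout()].
#' @param x_train,labels_train Training design matrix and labels.
#' @param x_test,labels_test Held-out test design matrix and labels.
#' @param seed Seed for the refit.
#' @return The completed `benchmark_report` with `test_auc` and the fitted
#'   `final_model`.
#' @export
select_and_evaluate <- function(report, x_train, labels_train,
                                x_test, labels_test, seed = 1L) {
  stopifnot(inherits(report, "benchmark_report"))
  labels_train <- droplevels(as.factor(labels_train))
  spec <- classifier_registry(report$chosen)[[1]]
  model <- spec$fit(as.matrix(x_train), labels_train, seed = seed)
  s <- spec$score(model, as.matrix(x_test))
  report$test_auc <- auc(s, labels_test)
  report$final_model <- model
  report
}
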