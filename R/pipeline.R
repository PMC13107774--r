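#' Subset a k-mer matrix by strain
#'
#' @param kmat A `kmer_matrix`.
#' @param ids Strain ids or row indices to keep.
#' @return A `kmer_matrix` with the selected rows.
#' @export
subset_strains <- function(kmat, ids) {
  stopifnot(inherits(kmat, "kmer_matrix"))
  idx <- resolve_rows(kmat$values, ids)
  kmat$values <- kmat$values[idx, , drop = FALSE]
  kmat$strain_ids <- kmat$strain_ids[idx]
  kmat$window_totals <- kmat$window_totals[idx, , drop = FALSE]
  kmat
}

#' Train-and-benchmark screening pipeline
#'
#' The full internal-evaluation workflow on a labelled cohort: stratified
#' 60/40 train/test split; three-stage feature selection and z-score
#' standardization fitted on the training strains only; repeated-holdout
#' benchmarking of the eight classifier families on the training strains;
#' refit of the winning family on all training strains and evaluation on
#' the held-out test strains. No test-strain information reaches feature
#' selection, standardization or model fitting.
#'
#' @param kmat `kmer_matrix` of the labelled cohort.
#' @param labels Class labels (`SFS`/`SubFS`) aligned with
#'   `kmat$strain_ids`, or a labelled score tibble from
#'   [score_phenotypes()].
#' @param config A [selection_config()]; its `rng_seed` drives the
#'   selection stages.
#' @param train_fraction Outer training fraction (default 0.60).
#' @param rounds Repeated-holdout rounds (default 10).
#' @param inner_fraction Inner-training fraction per round (default 0.8).
#' @param seed Seed for the outer split, the holdout rounds and refits.
#' @return A `screen_result`: `split`, `selection`, `report` (completed
#'   benchmark with test AUC), plus the label vector used.
#' @export
screen_strains <- function(kmat, labels, config = selection_config(),
                           train_fraction = 0.60, rounds = 10L,
                           inner_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(kmat, "kmer_matrix"))
  if (is.data.frame(labels)) {
    labels <- labels$label[match(kmat$strain_ids, labels$strain_id)]
  }
  labels <- droplevels(as.factor(labels))
  stopifnot(length(labels) == length(kmat$strain_ids), !anyNA(labels))
  names(labels) <- kmat$strain_ids

  split <- stratified_split(kmat$strain_ids, labels, train_fraction, seed)
  ktrain <- subset_strains(kmat, split$train)
  sel <- run_selection(ktrain, labels[split$train], config)

  z_train <- design_matrix(ktrain, sel)
  z_test <- design_matrix(subset_strains(kmat, split$test), sel)

  report <- repeated_holdout(z_train, labels[split$train], rounds = rounds,
                             inner_fraction = inner_fraction, seed = seed)
  report <- select_and_evaluate(report, z_train, labels[split$train],
                                z_test, labels[split$test], seed = seed)
  structure(
    list(split = split, selection = sel, report = report, labels = labels,
         seed = as.integer(seed)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n  ")
  print(x$split)
  cat("  ")
  print(x$selection)
  cat("  ")
  print(x$report)
  invisible(x)
}

#' Export a selection report as JSON
#'
#' Writes per-stage survivor counts and the selected-feature table (k-mer,
#' vocabulary index, averaged fused score, cluster) to a JSON file.
#'
#' @param sel A `selected_features` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  stopifnot(inherits(sel, "selected_features"))
  selected <- sel$scores[sel$scores$selected, , drop = FALSE]
  jsonlite::write_json(
    list(stage_counts = as.list(sel$stage_counts),
         selected = selected,
         config = unclass(sel$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Export a benchmark report as JSON
#'
#' @param report A `benchmark_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  jsonlite::write_json(
    list(auc_rounds = as.data.frame(report$auc_rounds),
         mean_auc = as.list(report$mean_auc),
         ranking = report$ranking, chosen = report$chosen,
         test_auc = report$test_auc, rounds = report$rounds,
         inner_fraction = report$inner_fraction, seed = report$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
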