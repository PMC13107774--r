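#' Configuration for the three-stage feature-selection pipeline
#'
#' Defaults follow the pipeline's published operating point: variance
#' threshold 1e-5; ANOVA retains up to 10,000 top-F features; fusion weights
#' 0.3 (F), 0.3 (mutual information), 0.2 (chi-squared), 0.2 (random-forest
#' importance); 5 resampling rounds each drawing a stratified 80% subsample;
#' top 80% of features kept by averaged fused score; average-linkage
#' correlation clustering cut at distance 0.3 (i.e. features with average
#' absolute correlation >= 0.7 merge).
#'
#' @param variance_eps Minimum population variance for a column to survive
#'   the low-variance filter.
#' @param anova_top_k Maximum number of features retained by F-value.
#' @param fusion_weights Numeric length-4 vector (F, MI, chi2, RF) summing
#'   to 1.
#' @param resample_rounds Number of stability resampling rounds N.
#' @param resample_fraction Fraction of training strains drawn per round.
#' @param with_replacement Draw resamples with replacement instead of the
#'   default stratified subsampling without replacement.
#' @param keep_fraction Fraction R of features kept after score averaging.
#' @param cluster_cut_distance Height at which the average-linkage dendrogram
#'   over 1 - |Pearson rho| is cut.
#' @param minmax_eps Small positive guard added to the min-max denominator.
#' @param mi_bins Number of quantile bins for the mutual-information
#'   estimator.
#' @param rf_trees Trees in the random forest used for importance scoring.
#' @param rng_seed Base seed; round r uses `rng_seed + r`.
#' @return A `selection_config` object.
#' @export
selection_config <- function(variance_eps = 1e-5,
                             anova_top_k = 10000L,
                             fusion_weights = c(F = 0.3, MI = 0.3,
                                                chi2 = 0.2, RF = 0.2),
                             resample_rounds = 5L,
                             resample_fraction = 0.8,
                             with_replacement = FALSE,
                             keep_fraction = 0.80,
                             cluster_cut_distance = 0.3,
                             minmax_eps = 1e-12,
                             mi_bins = 10L,
                             rf_trees = 200L,
                             rng_seed = 1L) {
  stopifnot(length(fusion_weights) == 4, variance_eps >= 0,
            anova_top_k >= 1, resample_rounds >= 1,
            resample_fraction > 0, resample_fraction <= 1,
            keep_fraction > 0, keep_fraction <= 1,
            cluster_cut_distance >= 0, minmax_eps > 0, mi_bins >= 2,
            rf_trees >= 1)
  if (abs(sum(fusion_weights) - 1) > 1e-9) {
    stop("fusion weights must sum to 1")
  }
  structure(
    list(variance_eps = variance_eps, anova_top_k = as.integer(anova_top_k),
         fusion_weights = fusion_weights,
         resample_rounds = as.integer(resample_rounds),
         resample_fraction = resample_fraction,
         with_replacement = with_replacement,
         keep_fraction = keep_fraction,
         cluster_cut_distance = cluster_cut_distance,
         minmax_eps = minmax_eps, mi_bins = as.integer(mi_bins),
         rf_trees = as.integer(rf_trees), rng_seed = as.integer(rng_seed)),
    class = "selection_config"
  )
}

#' Low-variance filter
#'
#' Keeps column j iff its population variance (divide by n) over the
#' training rows is at least `eps`. Applied to the raw frequency matrix,
#' before z-scoring: a variance filter on standardized columns is vacuous
#' since every non-constant column then has variance 1.
#'
#' @param m Numeric or sparse matrix, rows = training strains.
#' @param eps Variance threshold.
#' @return Integer vector of surviving column indices (ascending).
#' @export
variance_filter <- function(m, eps = 1e-5) {
  m <- as_values(m)
  if (nrow(m) < 2) stop("need at least 2 rows")
  mu <- Matrix::colMeans(m)
  v <- Matrix::colMeans(m^2) - mu^2
  which(as.numeric(v) >= eps)
}

#' Per-column one-way ANOVA F statistics
#'
#' F_j = MSB_j / MSW_j with the between-class mean square
#' MSB = sum_c n_c (xbar_jc - xbar_j)^2 / (C - 1) and the within-class mean
#' square MSW = sum_c sum_i (x_ij - xbar_jc)^2 / (n - C). A zero MSW is
#' guarded by adding 1e-12 to the denominator, so perfectly separating
#' features get a finite, maximal-rank F rather than infinity.
#'
#' @param m Numeric matrix, rows = samples.
#' @param labels Class labels (>= 2 classes, n > C).
#' @return Numeric vector of F values, one per column.
#' @export
anova_f <- function(m, labels) {
  m <- as.matrix(as_values(m))
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  C <- length(classes)
  n <- nrow(m)
  if (C < 2) stop("need at least 2 classes")
  if (n <= C) stop("need more samples than classes")
  grand <- colMeans(m)
  msb <- numeric(ncol(m))
  msw <- numeric(ncol(m))
  for (cl in classes) {
    rows <- labels == cl
    nc <- sum(rows)
    cm <- colMeans(m[rows, , drop = FALSE])
    msb <- msb + nc * (cm - grand)^2
    msw <- msw + colSums(sweep(m[rows, , drop = FALSE], 2, cm)^2)
  }
  (msb / (C - 1)) / (msw / (n - C) + 1e-12)
}

#' Retain the top-K columns by F value
#'
#' Keeps min(K, available) columns with the largest F; ties at the cutoff
#' are broken by ascending column index for reproducibility.
#'
#' @param f Numeric vector of F values indexed by column.
#' @param k Maximum number of columns to retain.
#' @return Integer vector of retained column indices, ascending.
#' @export
anova_top_k <- function(f, k = 10000L) {
  stopifnot(k >= 1)
  keep <- min(as.integer(k), length(f))
  ord <- order(f, seq_along(f), decreasing = c(TRUE, FALSE), method = "radix")
  sort(ord[seq_len(keep)])
}

#' Min-max normalize a score vector to \[0, 1\]
#'
#' s' = (s - min) / (max - min + eps). A constant vector maps to
#' (approximately) all zeros via the eps guard.
#'
#' @param s Numeric scores.
#' @param eps Small positive denominator guard.
#' @return Normalized scores.
#' @export
minmax_normalize <- function(s, eps = 1e-12) {
  stopifnot(length(s) >= 1)
  (s - min(s)) / (max(s) - min(s) + eps)
}

#' Fuse four normalized importance scores
#'
#' S_fused = alpha F' + beta MI' + gamma chi2' + delta RF', with weights
#' summing to 1 so the fused score stays in \[0, 1\].
#'
#' @param f_n,mi_n,chi2_n,rf_n Normalized score vectors of equal length.
#' @param weights Length-4 weight vector (F, MI, chi2, RF).
#' @return Fused score vector.
#' @export
fused_score <- function(f_n, mi_n, chi2_n, rf_n,
                        weights = c(0.3, 0.3, 0.2, 0.2)) {
  lens <- c(length(f_n), length(mi_n), length(chi2_n), length(rf_n))
  if (length(unique(lens)) != 1) stop("score vectors have mismatched lengths")
  if (abs(sum(weights) - 1) > 1e-9) stop("fusion weights must sum to 1")
  weights[1] * f_n + weights[2] * mi_n + weights[3] * chi2_n + weights[4] * rf_n
}

# mutual information between a continuous feature and the class label via a
# deterministic quantile-binned plug-in estimator (natural log)
#' @noRd
mi_binned <- function(x, labels, bins = 10L) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7)
  brk <- unique(c(-Inf, qs[-1]))   # open lowest bin keeps discrete values apart
  if (length(brk) < 3 && length(unique(x)) < 2) return(0)
  b <- cut(x, breaks = brk, include.lowest = TRUE)
  tab <- table(b, labels)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
}

# chi-squared relevance statistic for non-negative features vs class label:
# observed per-class feature mass against class-prior expectation
#' @noRd
chi2_scores <- function(m, labels) {
  labels <- droplevels(as.factor(labels))
  onehot <- stats::model.matrix(~ labels - 1)
  observed <- t(onehot) %*% m                      # C x p
  priors <- colSums(onehot) / nrow(m)
  expected <- priors %o% colSums(m)                # C x p
  contrib <- (observed - expected)^2 / expected
  contrib[expected == 0] <- 0
  as.numeric(colSums(contrib))
}

#' Raw importance metrics on one resample
#'
#' Computes the four per-column relevance scores used by the fusion stage:
#' ANOVA F; mutual information from a deterministic 10-bin quantile plug-in
#' estimator; a chi-squared statistic computed on features min-max shifted
#' to \[0, 1\] within the resample (the statistic requires non-negative
#' input); and impurity (Gini) importance from a seeded random forest.
#'
#' @param m Numeric matrix of the resampled rows (standardized features).
#' @param labels Class labels for those rows (both classes present).
#' @param config A [selection_config()].
#' @param seed Seed for the random forest.
#' @return Tibble with columns `column`, `F`, `MI`, `chi2`, `RF`.
#' @export
metric_scores <- function(m, labels, config = selection_config(), seed = 1L) {
  m <- as.matrix(as_values(m))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("resample must contain both classes")
  f <- anova_f(m, labels)
  mi <- apply(m, 2, mi_binned, labels = labels, bins = config$mi_bins)
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  m01 <- sweep(m, 2, rng[1, ], "-")
  m01 <- sweep(m01, 2, ifelse(span > 0, span, 1), "/")
  chi2 <- chi2_scores(m01, labels)
  set.seed(seed)
  rf <- randomForest::randomForest(x = m, y = labels,
                                   ntree = config$rf_trees)
  rfimp <- as.numeric(rf$importance[, "MeanDecreaseGini"])
  tibble::tibble(column = seq_len(ncol(m)), F = f, MI = mi, chi2 = chi2,
                 RF = rfimp)
}

#' @noRd
stratified_rows <- function(labels, fraction, replace, seed) {
  set.seed(seed)
  sort(unlist(lapply(levels(labels), function(cl) {
    rows <- which(labels == cl)
    n_take <- max(1L, round(length(rows) * fraction))
    sample(rows, n_take, replace = replace)
  }), use.names = FALSE))
}

#' Stability-enhanced fusion scoring
#'
#' Runs N rounds of stratified resampling (default: 80% subsample without
#' replacement, seeded `rng_seed + round`); in each round computes the four
#' importance metrics, min-max normalizes each, and fuses them with the
#' configured weights; the final score of a feature is the mean fused score
#' across rounds. Features are then ranked and the top `keep_fraction` are
#' retained (ties broken by ascending column index).
#'
#' @param m Standardized numeric matrix (training rows only).
#' @param labels Class labels for the rows.
#' @param config A [selection_config()].
#' @return A list with `scores` (tibble: per-feature per-metric means, the
#'   averaged fused score `s_bar`, rank) and `retained` (ascending column
#'   indices of the kept features).
#' @export
stability_fusion <- function(m, labels, config = selection_config()) {
  m <- as.matrix(as_values(m))
  labels <- droplevels(as.factor(labels))
  if (nrow(m) < 5) stop("need at least 5 training rows")
  if (nlevels(labels) < 2) stop("need both classes")
  w <- config$fusion_weights
  fused_rounds <- matrix(NA_real_, ncol(m), config$resample_rounds)
  for (r in seq_len(config$resample_rounds)) {
    rows <- NULL
    for (attempt in 1:10) {
      cand <- stratified_rows(labels, config$resample_fraction,
                              config$with_replacement,
                              seed = config$rng_seed + r + (attempt - 1) * 1000L)
      if (nlevels(droplevels(labels[cand])) == 2) { rows <- cand; break }
      message("single-class resample in round ", r, "; redrawing")
    }
    if (is.null(rows)) stop("could not draw a two-class resample in round ", r)
    sc <- metric_scores(m[rows, , drop = FALSE], labels[rows], config,
                        seed = config$rng_seed + 100L + r)
    fused_rounds[, r] <- fused_score(
      minmax_normalize(sc$F, config$minmax_eps),
      minmax_normalize(sc$MI, config$minmax_eps),
      minmax_normalize(sc$chi2, config$minmax_eps),
      minmax_normalize(sc$RF, config$minmax_eps),
      weights = w
    )
  }
  s_bar <- rowMeans(fused_rounds)
  ord <- order(s_bar, seq_along(s_bar), decreasing = c(TRUE, FALSE),
               method = "radix")
  n_keep <- max(1L, round(config$keep_fraction * ncol(m)))
  retained <- sort(ord[seq_len(min(n_keep, ncol(m)))])
  scores <- tibble::tibble(
    column = seq_len(ncol(m)),
    s_bar = s_bar,
    rank = match(seq_along(s_bar), ord),
    retained = seq_len(ncol(m)) %in% retained
  )
  list(scores = scores, retained = retained, fused_rounds = fused_rounds)
}

#' Correlation-clustering redundancy pruning
#'
#' Builds the absolute Pearson correlation matrix over training rows
#' (constant-column pairs are defined to have rho = 0), converts it to the
#' distance D = 1 - |rho|, clusters features by average-linkage agglomeration
#' cut at `cut_distance`, and keeps the feature with the highest averaged
#' fused score in each cluster (ties broken by ascending column index).
#'
#' @param m Numeric matrix restricted to the retained columns.
#' @param s_bar Averaged fused score per retained column.
#' @param cut_distance Dendrogram cut height.
#' @return List with `clusters` (integer assignment per column),
#'   `representatives` (ascending indices into the columns of `m`), and the
#'   distance matrix `D`.
#' @export
correlation_prune <- function(m, s_bar, cut_distance = 0.3) {
  m <- as.matrix(as_values(m))
  p <- ncol(m)
  stopifnot(length(s_bar) == p, p >= 1)
  if (p == 1) {
    return(list(clusters = 1L, representatives = 1L,
                D = matrix(0, 1, 1)))
  }
  rho <- suppressWarnings(abs(stats::cor(m)))
  rho[is.na(rho)] <- 0          # constant columns: correlation defined as 0
  diag(rho) <- 1
  D <- 1 - rho
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  clusters <- stats::cutree(hc, h = cut_distance)
  reps <- vapply(split(seq_len(p), clusters), function(members) {
    best <- members[order(-s_bar[members], members)][1]
    as.integer(best)
  }, integer(1))
  list(clusters = as.integer(clusters),
       representatives = sort(unname(reps)), D = D)
}

#' Run the full three-stage feature selection
#'
#' Stage order: low-variance filter on raw frequencies -> z-score
#' standardization of the survivors -> ANOVA top-K -> stability-enhanced
#' fusion scoring with top-R retention -> correlation-clustering pruning.
#' All ties break by ascending vocabulary index and every stochastic step is
#' seeded from `config$rng_seed`, so the result is reproducible bit for bit.
#'
#' @param x A `kmer_matrix` or raw numeric matrix of training strains.
#' @param labels Class labels aligned with the rows.
#' @param config A [selection_config()].
#' @return A `selected_features` object: `indices` (ascending vocabulary
#'   column indices), `stage_counts`, per-feature `scores`,
#'   standardization parameters for the selected columns, cluster
#'   provenance and the config used.
#' @export
run_selection <- function(x, labels, config = selection_config()) {
  m_raw <- as_values(x)
  vocab <- if (inherits(x, "kmer_matrix")) x$vocabulary else NULL
  labels <- droplevels(as.factor(labels))
  p0 <- ncol(m_raw)

  idx1 <- variance_filter(m_raw, config$variance_eps)
  if (length(idx1) == 0) {
    stop("no features survive the low-variance filter (eps = ",
         config$variance_eps, ")")
  }
  m1 <- m_raw[, idx1, drop = FALSE]
  std <- fit_standardization(m1)
  z1 <- apply_standardization(m1, std)

  f <- anova_f(z1, labels)
  keep2 <- anova_top_k(f, config$anova_top_k)
  idx2 <- idx1[keep2]
  z2 <- z1[, keep2, drop = FALSE]

  fus <- stability_fusion(z2, labels, config)
  idx3 <- idx2[fus$retained]
  z3 <- z2[, fus$retained, drop = FALSE]
  s_bar3 <- fus$scores$s_bar[fus$retained]

  pr <- correlation_prune(z3, s_bar3, config$cluster_cut_distance)
  idx4 <- idx3[pr$representatives]

  scores <- tibble::tibble(
    index = idx3,
    s_bar = s_bar3,
    cluster = pr$clusters,
    selected = idx3 %in% idx4
  )
  if (!is.null(vocab)) scores$kmer <- kmer_at(vocab, scores$index)

  sel_std <- list(
    mu = std$mu[match(idx4, idx1)],
    sigma = std$sigma[match(idx4, idx1)]
  )
  structure(
    list(indices = idx4,
         stage_counts = c(input = p0, variance = length(idx1),
                          anova = length(idx2), fusion = length(idx3),
                          cluster = length(idx4)),
         scores = scores,
         std_mu = sel_std$mu, std_sigma = sel_std$sigma,
         config = config),
    class = "selected_features"
  )
}

#' @export
print.selected_features <- function(x, ...) {
  cat("<selected_features> stages: ",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Extract the standardized selected-feature design matrix
#'
#' Restricts a raw-frequency matrix to the selected columns and applies the
#' z-score parameters recorded during selection (fitted on the selection's
#' training strains, never on new rows).
#'
#' @param x A `kmer_matrix` or raw matrix with the full vocabulary columns.
#' @param sel A `selected_features` object.
#' @return Dense numeric matrix, rows as in `x`, one column per selected
#'   feature.
#' @export
design_matrix <- function(x, sel) {
  stopifnot(inherits(sel, "selected_features"))
  m <- as.matrix(as_values(x)[, sel$indices, drop = FALSE])
  denom <- ifelse(sel$std_sigma > 0, sel$std_sigma, 1)
  z <- sweep(sweep(m, 2, sel$std_mu, "-"), 2, denom, "/")
  z[, sel$std_sigma == 0] <- 0
  z
}
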