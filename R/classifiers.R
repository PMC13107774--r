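# Classifier registry: eight families benchmarked by repeated-holdout AUC.
# Each entry is fit(x, y, seed) -> model and score(model, x) -> continuous
# class-1 (SFS) score. Features arrive already z-scored, so every fitter
# runs with its own internal scaling disabled. The registry order is also
# the deterministic tie-break order for model ranking.

pos_class <- "SFS"

# glmnet requires >= 2 columns; pad one-column designs with a zero dummy
#' @noRd
pad2 <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.dummy` = 0)
}

#' @noRd
fit_lr <- function(x, y, seed) {
  glmnet::glmnet(pad2(x), y, family = "binomial", alpha = 0,
                 lambda = 1e-2, standardize = FALSE)
}
#' @noRd
score_lr <- function(model, x) {
  as.numeric(stats::predict(model, newx = pad2(x), type = "response"))
}

#' @noRd
fit_svm <- function(x, y, seed) {
  e1071::svm(x, y, kernel = "radial", scale = FALSE)
}
#' @noRd
score_svm <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # the decision value is oriented toward the class named first in the
  # "A/B" column label; flip when that class is not SFS
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first == pos_class) s else -s
}

#' @noRd
fit_rf <- function(x, y, seed) {
  set.seed(seed)
  randomForest::randomForest(x, y, ntree = 200)
}
#' @noRd
score_rf <- function(model, x) {
  stats::predict(model, x, type = "prob")[, pos_class]
}

#' @noRd
fit_nb <- function(x, y, seed) {
  e1071::naiveBayes(x, y)
}
#' @noRd
score_nb <- function(model, x) {
  p <- stats::predict(model, as.data.frame(x), type = "raw")[, pos_class]
  if (any(!is.finite(p))) stop("naive Bayes produced non-finite scores")
  p
}

# k-NN is instance-based: "fit" stores the training data; score is the
# fraction of the k nearest neighbours in the SFS class
#' @noRd
fit_knn <- function(x, y, seed) {
  list(x = x, y = y, k = min(5L, nrow(x)))
}
#' @noRd
score_knn <- function(model, x) {
  pr <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
  frac <- attr(pr, "prob")
  ifelse(pr == pos_class, frac, 1 - frac)
}

#' @noRd
fit_dt <- function(x, y, seed) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- y
  rpart::rpart(.y ~ ., data = df, method = "class",
               control = rpart::rpart.control(minsplit = 5, cp = 0.01))
}
#' @noRd
score_dt <- function(model, x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  stats::predict(model, df, type = "prob")[, pos_class]
}

#' @noRd
fit_xgb <- function(x, y, params, nrounds, seed) {
  set.seed(seed)
  d <- xgboost::xgb.DMatrix(x, label = as.numeric(y == pos_class))
  xgboost::xgb.train(params = c(params, list(objective = "binary:logistic",
                                             nthread = 1)),
                     data = d, nrounds = nrounds, verbose = 0)
}
#' @noRd
score_xgb <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x))
}

#' The eight-family classifier registry
#'
#' Families, in fixed registry (and ranking tie-break) order: ridge logistic
#' regression (`lr`), RBF-kernel support vector machine (`svm`), random
#' forest (`rf`), Gaussian naive Bayes (`nb`), k-nearest neighbours (`knn`,
#' k = 5), a single decision tree (`dt`), depth-wise gradient-boosted trees
#' (`gbtA`: max_depth 6, eta 0.3, 50 rounds) and leaf-wise histogram
#' gradient-boosted trees (`gbtB`: lossguide growth, 31 leaves, eta 0.1,
#' 100 rounds). Hyperparameters are ecosystem defaults, frozen here and
#' recorded in the model bundle. Every family exposes a continuous SFS
#' score (probability or decision value) for AUC computation.
#'
#' @param families Optional character vector to subset the registry.
#' @return Named list of classifier specs (`fit`, `score`, `label`).
#' @export
classifier_registry <- function(families = NULL) {
  reg <- list(
    lr = list(label = "logistic regression (ridge)",
              fit = fit_lr, score = score_lr),
    svm = list(label = "support vector machine (RBF)",
               fit = fit_svm, score = score_svm),
    rf = list(label = "random forest", fit = fit_rf, score = score_rf),
    nb = list(label = "naive Bayes", fit = fit_nb, score = score_nb),
    knn = list(label = "k-nearest neighbours", fit = fit_knn,
               score = score_knn),
    dt = list(label = "decision tree", fit = fit_dt, score = score_dt),
    gbtA = list(label = "gradient-boosted trees (depth-wise)",
                fit = function(x, y, seed) {
                  fit_xgb(x, y, list(max_depth = 6, eta = 0.3), 50L, seed)
                },
                score = score_xgb),
    gbtB = list(label = "gradient-boosted trees (leaf-wise)",
                fit = function(x, y, seed) {
                  fit_xgb(x, y, list(tree_method = "hist",
                                     grow_policy = "lossguide",
                                     max_leaves = 31, max_depth = 0,
                                     eta = 0.1), 100L, seed)
                },
                score = score_xgb)
  )
  if (!is.null(families)) {
    unknown <- setdiff(families, names(reg))
    if (length(unknown) > 0) stop("unknown families: ",
                                  paste(unknown, collapse = ", "))
    reg <- reg[families]
  }
  reg
}
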