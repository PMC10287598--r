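#' Patient-wise cross-validated gradient-boosting classification
#'
#' Folds are partitioned patient-wise (all ROIs of a patient share a fold).
#' Within each fold, imputation means and standardization parameters are fit
#' on the training rows only and applied to both sides; a gradient tree
#' boosting classifier (depth 3, 200 trees, learning rate 0.1 — explicit,
#' reproducible defaults) is fit and scored on the held-out fold.
#'
#' @param features Numeric matrix or data frame of feature columns (may
#'   contain `NA` for empty segmentations).
#' @param labels Binary vector (0 = benign, 1 = malignant; factors and
#'   logicals are coerced).
#' @param patient_ids Vector of patient identifiers, one per row.
#' @param folds Number of folds, default 5.
#' @param seed RNG seed for the patient shuffle and the booster.
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @return Object of class `mc_crossval`: per-fold list of `scores`,
#'   `labels`, `fold` assignment per row.
#' @export
crossval_classify <- function(features, labels, patient_ids, folds = 5L,
                              seed = 1L, nrounds = 200L, max_depth = 3L,
                              eta = 0.1) {
  X <- as.matrix(as.data.frame(features))
  y <- as.integer(as.logical(as.numeric(labels)))
  if (length(unique(y)) < 2) stop("need both classes present")
  stopifnot(nrow(X) == length(y), length(patient_ids) == length(y))
  pats <- unique(patient_ids)
  if (length(pats) < folds)
    stop("fewer patients than folds; patient-wise partition impossible")
  set.seed(seed)
  fold_of_pat <- sample(rep(seq_len(folds), length.out = length(pats)))
  names(fold_of_pat) <- as.character(pats)
  fold <- fold_of_pat[as.character(patient_ids)]
  fold_results <- lapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
      stop("fold ", f, " contains a single class; re-seed or merge folds")
    pp <- fit_preprocess(X[tr, , drop = FALSE])
    Xtr <- apply_preprocess(X[tr, , drop = FALSE], pp)
    Xte <- apply_preprocess(X[te, , drop = FALSE], pp)
    dtrain <- xgboost::xgb.DMatrix(Xtr, label = y[tr], nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed),
      data = dtrain, nrounds = nrounds, verbose = 0)
    scores <- predict(booster, xgboost::xgb.DMatrix(Xte, nthread = 1))
    list(scores = as.numeric(scores), labels = y[te])
  })
  structure(list(folds = fold_results, fold = unname(fold)),
            class = "mc_crossval")
}

# Imputation means + standardization parameters from training rows only.
fit_preprocess <- function(X) {
  mu_imp <- colMeans(X, na.rm = TRUE)
  mu_imp[is.nan(mu_imp)] <- 0
  Xi <- X
  for (j in seq_len(ncol(Xi))) Xi[is.na(Xi[, j]), j] <- mu_imp[j]
  mu <- colMeans(Xi)
  sd <- apply(Xi, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(impute = mu_imp, center = mu, scale = sd)
}

apply_preprocess <- function(X, pp) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- pp$impute[j]
  scale(X, center = pp$center, scale = pp$scale)[, , drop = FALSE]
}

# Trapezoidal rank-based ROC AUC; tied scores contribute 1/2 (constant
# scores give exactly 0.5).
roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validation ROC report at a high-sensitivity operating point
#'
#' Per fold: ROC AUC (rank-based, ties counted half) and, at the score
#' threshold whose sensitivity is closest to `sensitivity_target`
#' (ties resolve to the higher threshold), accuracy, sensitivity,
#' specificity, and positive predictive value. Reported as mean and
#' standard deviation across folds.
#'
#' @param cv An `mc_crossval` from [crossval_classify()].
#' @param sensitivity_target Target sensitivity, default 0.9.
#' @return Data frame with rows auc, accuracy, sensitivity, specificity,
#'   ppv and columns `mean`, `sd`.
#' @export
roc_report <- function(cv, sensitivity_target = 0.9) {
  stopifnot(inherits(cv, "mc_crossval"))
  per <- vapply(cv$folds, function(f) {
    sc <- f$scores; y <- f$labels
    auc <- roc_auc(sc, y)
    thr_cand <- sort(unique(sc), decreasing = TRUE)
    sens <- vapply(thr_cand, function(t) mean(sc[y == 1] >= t), numeric(1))
    best <- which(abs(sens - sensitivity_target) ==
                    min(abs(sens - sensitivity_target)))[1]
    t <- thr_cand[best]
    pred <- as.integer(sc >= t)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
    c(auc = auc,
      accuracy = (tp + tn) / length(y),
      sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
      ppv = if (tp + fp) tp / (tp + fp) else NA_real_)
  }, numeric(5))
  data.frame(metric = rownames(per), mean = rowMeans(per),
             sd = apply(per, 1, stats::sd), row.names = NULL)
}

#' @export
print.mc_crossval <- function(x, ...) {
  cat(sprintf("mc_crossval: %d fold(s), %d sample(s)\n",
              length(x$folds), length(x$fold)))
  print(roc_report(x))
  invisible(x)
}
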