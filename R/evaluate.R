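#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney U) formulation with ties counted 0.5:
#' identical to trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric prediction scores (higher = more likely sensitive).
#' @param labels 0/1 response of the same length, both classes present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# internal: stratified train/test index split; returns list(train, test) of
# patient positions, each part keeping both classes
stratified_split <- function(y, train_fraction) {
  idx_pos <- which(y == 1)
  idx_neg <- which(y == 0)
  n_tr_pos <- round(train_fraction * length(idx_pos))
  n_tr_neg <- round(train_fraction * length(idx_neg))
  if (n_tr_pos < 1 || n_tr_neg < 1 ||
      n_tr_pos >= length(idx_pos) || n_tr_neg >= length(idx_neg))
    stop("cohort too small for a stratified ", train_fraction, " split")
  tr <- c(sample(idx_pos, n_tr_pos), sample(idx_neg, n_tr_neg))
  list(train = sort(tr), test = sort(setdiff(seq_along(y), tr)))
}

#' Repeated stratified split evaluation
#'
#' Trains on a stratified `train_fraction` of the labeled cohort and computes
#' the AUROC of the final scores on the held-out patients, repeated
#' `repeats` times with fresh splits; reports mean and standard deviation.
#'
#' @param fm labeled feature matrix.
#' @param labels named 0/1 response.
#' @param reference unlabeled reference feature matrix.
#' @param train_fraction fraction of each class used for training.
#' @param repeats number of random splits.
#' @param seed integer seed driving all splits.
#' @param config [igensig_config()].
#' @return list: `auroc_mean`, `auroc_sd` (NA when `repeats == 1`),
#'   `per_repeat` data.frame, `train_fraction`, `repeats`, `seed`.
#' @export
split_experiment <- function(fm, labels, reference, train_fraction = 0.9,
                             repeats = 10, seed = 1,
                             config = igensig_config()) {
  fm <- as_feature_matrix(fm)
  labels <- align_labels(fm, labels)
  y <- as.numeric(labels)
  aucs <- numeric(repeats)
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max, repeats)
  for (r in seq_len(repeats)) {
    set.seed(split_seeds[r])
    sp <- stratified_split(y, train_fraction)
    tr_lab <- labels[sp$train]
    model <- igensig_train(fm[names(tr_lab), , drop = FALSE], tr_lab,
                           reference, config)
    te_lab <- labels[sp$test]
    sc <- score_cohort(model, fm[names(te_lab), , drop = FALSE], loo = FALSE)
    aucs[r] <- auroc(sc$final_score, te_lab[sc$patient_id])
  }
  list(auroc_mean = mean(aucs),
       auroc_sd = if (repeats > 1) stats::sd(aucs) else NA_real_,
       per_repeat = data.frame(repeat_id = seq_len(repeats), auroc = aucs),
       train_fraction = train_fraction, repeats = repeats, seed = seed)
}

#' L1-regularized logistic baseline
#'
#' Lasso-penalized logistic regression on the raw binary features, with the
#' penalty chosen by internal cross-validation; the conventional
#' high-dimensional baseline the integral-signature model is compared
#' against.
#'
#' @param fm training feature matrix.
#' @param labels training 0/1 response (both classes).
#' @param test_fm feature matrix to score (same feature universe; missing
#'   features are treated as absent).
#' @param seed seed for the cross-validation folds.
#' @param nfolds folds for `glmnet::cv.glmnet`.
#' @return named numeric vector of test decision scores (linear predictor).
#' @export
l1_baseline <- function(fm, labels, test_fm, seed = 1, nfolds = 5) {
  fm <- as_feature_matrix(fm)
  labels <- align_labels(fm, labels)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  x <- fm[names(labels), , drop = FALSE]
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             foldid = foldid)
  test_fm <- as_feature_matrix(test_fm)
  xt <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(nrow(test_fm), ncol(x)),
                             dimnames = list(rownames(test_fm), colnames(x)))
  common <- intersect(colnames(test_fm), colnames(x))
  xt[, common] <- test_fm[, common, drop = FALSE]
  drop(stats::predict(cvfit, newx = xt, s = "lambda.min", type = "link"))
}

#' Feature-error robustness experiment
#'
#' Quantifies degradation of held-out AUROC under simulated feature errors
#' (random false-positive/false-negative bits, see [inject_errors()])
#' injected into either the training or the validation matrix, across a grid
#' of error rates, with several error seeds per rate. Optionally runs the
#' L1-logistic baseline on identical data for contrast: the redundancy
#' penalty design predicts the integral-signature model degrades less.
#'
#' @param fm labeled feature matrix.
#' @param labels named 0/1 response.
#' @param reference unlabeled reference feature matrix.
#' @param rates error-rate grid.
#' @param target `"train"` or `"validation"`: which matrix is corrupted.
#' @param baseline run the L1-logistic baseline too.
#' @param n_error_seeds error replicates per rate.
#' @param mode error mode, see [inject_errors()].
#' @param train_fraction stratified training fraction.
#' @param seed master seed.
#' @param config [igensig_config()].
#' @return list with `summary` (data.frame rate, method, auroc_mean,
#'   auroc_sd) and `runs` (one row per replicate).
#' @export
robustness_experiment <- function(fm, labels, reference,
                                  rates = c(0, 0.05, 0.10, 0.15, 0.20, 0.25),
                                  target = c("validation", "train"),
                                  baseline = TRUE, n_error_seeds = 5,
                                  mode = "both", train_fraction = 0.9,
                                  seed = 1, config = igensig_config()) {
  target <- match.arg(target)
  fm <- as_feature_matrix(fm)
  labels <- align_labels(fm, labels)
  y <- as.numeric(labels)
  set.seed(seed)
  split_seeds <- sample.int(.Machine$integer.max, n_error_seeds)
  error_seeds <- sample.int(.Machine$integer.max, n_error_seeds * length(rates))
  runs <- list()
  row <- 0
  for (s in seq_len(n_error_seeds)) {
    set.seed(split_seeds[s])
    sp <- stratified_split(y, train_fraction)
    tr_lab <- labels[sp$train]
    te_lab <- labels[sp$test]
    tr_fm0 <- fm[names(tr_lab), , drop = FALSE]
    te_fm0 <- fm[names(te_lab), , drop = FALSE]
    for (ri in seq_along(rates)) {
      rate <- rates[ri]
      es <- error_seeds[(s - 1) * length(rates) + ri]
      tr_fm <- if (target == "train" && rate > 0)
        inject_errors(tr_fm0, rate, mode, seed = es) else tr_fm0
      te_fm <- if (target == "validation" && rate > 0)
        inject_errors(te_fm0, rate, mode, seed = es) else te_fm0
      model <- igensig_train(tr_fm, tr_lab, reference, config)
      sc <- score_cohort(model, te_fm, loo = FALSE)
      row <- row + 1
      runs[[row]] <- data.frame(rate = rate, method = "igensig",
                                error_seed = s,
                                auroc = auroc(sc$final_score,
                                              te_lab[sc$patient_id]))
      if (baseline) {
        bl <- l1_baseline(tr_fm, tr_lab, te_fm, seed = es)
        row <- row + 1
        runs[[row]] <- data.frame(rate = rate, method = "lasso",
                                  error_seed = s,
                                  auroc = auroc(bl[names(te_lab)], te_lab))
      }
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(runs, runs[c("rate", "method")]),
                                   function(d) data.frame(
                                     rate = d$rate[1], method = d$method[1],
                                     auroc_mean = mean(d$auroc),
                                     auroc_sd = stats::sd(d$auroc))))
  rownames(summary) <- NULL
  list(summary = summary[order(summary$method, summary$rate), ], runs = runs)
}
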