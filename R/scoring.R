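#' Model configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults:
#' the weight retention cutoff (0.13), the expression level scheme, the
#' dynamic-cut clustering parameters, and the D-line angle grid step.
#'
#' @param cutoff retention threshold on |omega|.
#' @param scheme expression [level_scheme()].
#' @param deep_split,min_cluster_size,cut_height_frac see
#'   [cluster_patient_features()].
#' @param angle_grid_deg D-line search grid step, degrees.
#' @param seed integer seed recorded with the model.
#' @return list of class `igensig_config`.
#' @export
igensig_config <- function(cutoff = 0.13, scheme = level_scheme(),
                           deep_split = 2, min_cluster_size = 2,
                           cut_height_frac = 0.99, angle_grid_deg = 0.5,
                           seed = 1L) {
  structure(list(cutoff = cutoff, scheme = scheme, deep_split = deep_split,
                 min_cluster_size = min_cluster_size,
                 cut_height_frac = cut_height_frac,
                 angle_grid_deg = angle_grid_deg, seed = as.integer(seed)),
            class = "igensig_config")
}

# internal: both class scores for one patient. The penalty clustering, n and
# epsilon-bar are patient-level quantities over ALL of the patient's retained
# features; the effective-weight sums are then split by class and share the
# effective feature number EFN = n / epsilon_bar.
score_pair_impl <- function(patient_features, weights, sim, config) {
  keep <- weights$retained & weights$feature_id %in% patient_features
  feats <- weights$feature_id[keep]
  if (length(feats) == 0)
    return(c(sensitive = 0, resistant = 0))
  pen <- epsilon_vector(feats, sim,
                        deep_split = config$deep_split,
                        min_cluster_size = config$min_cluster_size,
                        cut_height_frac = config$cut_height_frac)
  ew <- abs(weights$omega[keep]) / pen$epsilon
  efn <- pen$n / pen$epsilon_bar
  is_sens <- weights$class[keep] == "sensitive"
  c(sensitive = sum(ew[is_sens]) / efn,
    resistant = sum(ew[!is_sens]) / efn)
}

#' Penalized class score of a patient
#'
#' Computes the redundancy penalties epsilon_i (see [epsilon_vector()]) over
#' the patient's retained features and returns, for the requested class,
#' sum over that class of |omega_i| / epsilon_i, divided by the effective
#' feature number EFN = n / mean(epsilon). n, the clustering and
#' mean(epsilon) are patient-level quantities over all of the patient's
#' retained features, shared by the two class scores: the class scores are
#' per-effective-feature accumulations of sensitive versus resistant
#' evidence on a common scale. With no redundancy (all epsilon = 1) and a
#' patient carrying features of a single class, the score reduces to the
#' mean |omega| of those features; k-fold duplicated features collapse to
#' the weight of a single copy. A patient with no retained features of the
#' class scores 0.
#'
#' @param patient_features feature ids carried by the patient.
#' @param weights weight table ([compute_weights()]).
#' @param sim similarity matrix covering the retained features.
#' @param class `"sensitive"` or `"resistant"`.
#' @param config [igensig_config()].
#' @return non-negative class score.
#' @export
class_score <- function(patient_features, weights, sim,
                        class = c("sensitive", "resistant"),
                        config = igensig_config()) {
  class <- match.arg(class)
  unname(score_pair_impl(as.character(patient_features), weights, sim,
                         config)[class])
}

#' Fit the dividing line (D-line) by Youden index
#'
#' Patients live in the (resistant score R, sensitive score S) plane; the
#' D-line S = m R through the origin separates predicted sensitive (above)
#' from predicted resistant (below). The slope is chosen over an angle grid
#' theta in \{step, 2 step, ..., 90 - step\} degrees to maximize the training
#' Youden index J = TPR - FPR of the rule S > tan(theta) R; ties break to the
#' smallest angle.
#'
#' @param R,S numeric vectors of resistant / sensitive scores.
#' @param labels 0/1 response (1 = sensitive), both classes present.
#' @param angle_grid_deg grid step in degrees.
#' @return list of class `dline`: `slope`, `theta_deg`, `youden_J`,
#'   `angle_grid_deg`.
#' @export
fit_dline <- function(R, S, labels, angle_grid_deg = 0.5) {
  y <- as.numeric(labels)
  stopifnot(length(R) == length(S), length(S) == length(y))
  if (!all(is.finite(R)) || !all(is.finite(S))) stop("scores must be finite")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (length(unique(paste(R, S))) == 1) {
    warning("all (R, S) score pairs identical; D-line slope defaults to 1")
    pred <- S > R
    J <- mean(pred[y == 1]) - mean(pred[y == 0])
    return(structure(list(slope = 1, theta_deg = 45, youden_J = J,
                          angle_grid_deg = angle_grid_deg), class = "dline"))
  }
  thetas <- seq(angle_grid_deg, 90 - angle_grid_deg, by = angle_grid_deg)
  J <- vapply(thetas, function(th) {
    pred <- S > tan(th * pi / 180) * R
    mean(pred[y == 1]) - mean(pred[y == 0])
  }, numeric(1))
  best <- which.max(J)  # first maximum = smallest angle
  structure(list(slope = tan(thetas[best] * pi / 180),
                 theta_deg = thetas[best], youden_J = J[best],
                 angle_grid_deg = angle_grid_deg), class = "dline")
}

#' Signed distance to the D-line (final score)
#'
#' Perpendicular distance of (R, S) to the line S = m R, signed positive
#' above the line: (S - m R) / sqrt(1 + m^2). Sensitive patients fall above
#' the D-line and get positive final scores.
#'
#' @param R,S resistant / sensitive scores (vectorized).
#' @param dline fitted [fit_dline()] object.
#' @return signed distances.
#' @export
final_score <- function(R, S, dline) {
  (S - dline$slope * R) / sqrt(1 + dline$slope^2)
}

#' Train an integral genomic signature response model
#'
#' Pipeline: prune level-1 expression features; compute phi weights against
#' the response; prune genes with same-trend up/down features; build the
#' Otsuka-Ochiai similarity matrix of the retained features from the
#' unlabeled reference cohort; compute leave-one-out class scores for every
#' training patient; fit the D-line on those scores. The returned artifact is
#' self-contained: scoring a new cohort needs only the artifact and that
#' cohort's feature matrix.
#'
#' @param fm training feature matrix (patients x features).
#' @param labels named 0/1 response vector (1 = pCR/sensitive).
#' @param reference unlabeled reference feature matrix over the same feature
#'   universe (used only for co-occurrence, never labels).
#' @param config [igensig_config()].
#' @return object of class `igensig_model`: `weights`, `sim`, `dline`,
#'   `config`, `train_labels`, `train_scores`.
#' @export
igensig_train <- function(fm, labels, reference, config = igensig_config()) {
  fm <- as_feature_matrix(fm)
  labels <- align_labels(fm, labels)
  fm1 <- prune_level1(fm)
  wt <- compute_weights(fm1, labels, config$cutoff)
  fm2 <- prune_same_trend(fm1, wt)
  wt <- wt[wt$feature_id %in% colnames(fm2), , drop = FALSE]
  retained <- wt$feature_id[wt$retained]
  if (length(retained) == 0)
    stop("no features retained after pruning at cutoff ", config$cutoff)
  sim <- ochiai_matrix(reference, retained)
  model <- structure(list(weights = wt, sim = sim, dline = NULL,
                          config = config, train_labels = labels),
                     class = "igensig_model")
  train_scores <- score_cohort(model, fm2, loo = TRUE, .fit = TRUE)
  model$dline <- fit_dline(train_scores$resistant_score,
                           train_scores$sensitive_score,
                           labels[train_scores$patient_id],
                           config$angle_grid_deg)
  train_scores$final_score <- final_score(train_scores$resistant_score,
                                          train_scores$sensitive_score,
                                          model$dline)
  train_scores$predicted <- as.integer(train_scores$final_score > 0)
  model$train_scores <- train_scores
  model
}

#' Score a cohort with a trained model
#'
#' Computes per patient the sensitive and resistant class scores, the signed
#' distance to the D-line (final score), and the predicted label
#' (1 iff final score > 0). With `loo = TRUE` (training patients only, `fm`
#' must be the training matrix) the weights are recomputed with the patient
#' held out, so a training patient's own label never informs its score; the
#' retained universe stays restricted to the model's similarity matrix.
#' Patients carrying no retained features score (0, 0, 0).
#'
#' @param model `igensig_model` from [igensig_train()].
#' @param fm feature matrix of the cohort to score; features are intersected
#'   with the model's universe.
#' @param loo logical; leave-one-out reweighting for training patients.
#' @param .fit internal: skip D-line projection (used while fitting).
#' @return data.frame: `patient_id`, `sensitive_score`, `resistant_score`,
#'   `final_score`, `predicted`.
#' @export
score_cohort <- function(model, fm, loo = FALSE, .fit = FALSE) {
  stopifnot(inherits(model, "igensig_model"))
  fm <- as_feature_matrix(fm)
  universe <- rownames(model$sim)
  config <- model$config
  patients <- rownames(fm)
  if (loo) {
    not_train <- setdiff(patients, names(model$train_labels))
    if (length(not_train))
      stop("loo scoring requested for non-training patients: ",
           paste(utils::head(not_train, 5), collapse = ", "))
  }
  S <- numeric(length(patients))
  R <- numeric(length(patients))
  tfm <- methods::as(fm, "TsparseMatrix")
  feat_by_patient <- split(colnames(fm)[tfm@j + 1L], factor(rownames(fm)[tfm@i + 1L], levels = patients))
  for (k in seq_along(patients)) {
    p <- patients[k]
    feats <- feat_by_patient[[p]]
    wt <- if (loo) {
      w <- loo_adjusted_weights(fm, model$train_labels, p, config$cutoff)
      w[w$feature_id %in% universe, , drop = FALSE]
    } else {
      model$weights
    }
    pair <- score_pair_impl(feats, wt, model$sim, config)
    S[k] <- pair[["sensitive"]]
    R[k] <- pair[["resistant"]]
  }
  out <- data.frame(patient_id = patients, sensitive_score = S,
                    resistant_score = R, stringsAsFactors = FALSE)
  if (!.fit) {
    out$final_score <- final_score(R, S, model$dline)
    out$predicted <- as.integer(out$final_score > 0)
  }
  out
}

#' Write a per-patient score table
#'
#' TSV: `patient_id`, `sensitive_score`, `resistant_score`, `final_score`,
#' `predicted`.
#'
#' @param scores data.frame from [score_cohort()].
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("patient_id\tsensitive_score\tresistant_score\tfinal_score\tpredicted",
               sprintf("%s\t%.10g\t%.10g\t%.10g\t%d", scores$patient_id,
                       scores$sensitive_score, scores$resistant_score,
                       scores$final_score, scores$predicted)),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Save / load a trained model artifact
#'
#' The artifact directory is self-contained plain text: `weights.tsv`,
#' `similarity.tsv` (upper-triangle triplets of nonzero coefficients),
#' `dline.json`, `config.yaml`, `train_labels.tsv`.
#'
#' @param model `igensig_model`.
#' @param dir directory to create/overwrite.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "igensig_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_weight_table(model$weights, file.path(dir, "weights.tsv"))
  K <- as.matrix(model$sim)
  ut <- which(upper.tri(K, diag = FALSE) & K != 0, arr.ind = TRUE)
  con <- file(file.path(dir, "similarity.tsv"), open = "wb")
  writeLines(c(paste0("# features\t", paste(rownames(K), collapse = "\t")),
               "feature_i\tfeature_j\tK",
               sprintf("%s\t%s\t%.10g", rownames(K)[ut[, 1]],
                       colnames(K)[ut[, 2]], K[ut])),
             con, sep = "\n", useBytes = TRUE)
  close(con)
  jsonlite::write_json(model$dline[c("slope", "theta_deg", "youden_J",
                                     "angle_grid_deg")],
                       file.path(dir, "dline.json"), auto_unbox = TRUE,
                       digits = NA)
  cfg <- model$config
  yaml::write_yaml(list(cutoff = cfg$cutoff, up_levels = cfg$scheme$up,
                        down_levels = cfg$scheme$down,
                        deep_split = cfg$deep_split,
                        min_cluster_size = cfg$min_cluster_size,
                        cut_height_frac = cfg$cut_height_frac,
                        angle_grid_deg = cfg$angle_grid_deg, seed = cfg$seed),
                   file.path(dir, "config.yaml"))
  write_labels(model$train_labels, file.path(dir, "train_labels.tsv"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  wt <- read_weight_table(file.path(dir, "weights.tsv"))
  lines <- readLines(file.path(dir, "similarity.tsv"))
  feats <- strsplit(sub("^# features\t", "", lines[1]), "\t", fixed = TRUE)[[1]]
  K <- diag(1, length(feats))
  dimnames(K) <- list(feats, feats)
  if (length(lines) > 2) {
    trip <- utils::read.delim(text = lines[-1],
                              colClasses = c("character", "character", "numeric"))
    i <- match(trip$feature_i, feats)
    j <- match(trip$feature_j, feats)
    K[cbind(i, j)] <- trip$K
    K[cbind(j, i)] <- trip$K
  }
  dj <- jsonlite::read_json(file.path(dir, "dline.json"), simplifyVector = TRUE)
  cfgy <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- igensig_config(cutoff = cfgy$cutoff,
                        scheme = level_scheme(cfgy$up_levels, cfgy$down_levels),
                        deep_split = cfgy$deep_split,
                        min_cluster_size = cfgy$min_cluster_size,
                        cut_height_frac = cfgy$cut_height_frac,
                        angle_grid_deg = cfgy$angle_grid_deg,
                        seed = cfgy$seed)
  structure(list(weights = wt, sim = K,
                 dline = structure(as.list(dj), class = "dline"),
                 config = cfg,
                 train_labels = read_labels(file.path(dir, "train_labels.tsv"))),
            class = "igensig_model")
}

#' @export
print.igensig_model <- function(x, ...) {
  cat("Integral genomic signature response model\n")
  cat(sprintf("  retained features : %d (%d sensitive, %d resistant)\n",
              sum(x$weights$retained),
              sum(x$weights$retained & x$weights$class == "sensitive"),
              sum(x$weights$retained & x$weights$class == "resistant")))
  cat(sprintf("  weight cutoff     : %.3f\n", x$config$cutoff))
  if (!is.null(x$dline))
    cat(sprintf("  D-line slope      : %.4f (theta = %.1f deg, training J = %.3f)\n",
                x$dline$slope, x$dline$theta_deg, x$dline$youden_J))
  invisible(x)
}
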