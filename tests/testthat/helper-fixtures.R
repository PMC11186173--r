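# shared fixture builders and independent oracles (kept deliberately naive:
# they exist to cross-check the vectorized implementation, not to be fast)

# random binary feature matrix with no empty patients
random_fm <- function(n_patients, n_features, density = 0.2, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_patients * n_features, 1, density), n_patients,
                dimnames = list(sprintf("P%03d", seq_len(n_patients)),
                                sprintf("F%03d", seq_len(n_features))))
    if (all(rowSums(m) > 0)) return(as_feature_matrix(m))
  }
}

# brute-force Otsuka-Ochiai from explicit carrier sets
ochiai_bruteforce <- function(reference, features) {
  carriers <- lapply(features, function(f) {
    if (f %in% colnames(reference)) rownames(reference)[reference[, f] == 1]
    else character(0)
  })
  p <- length(features)
  K <- matrix(0, p, p, dimnames = list(features, features))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    a <- carriers[[i]]; b <- carriers[[j]]
    K[i, j] <- if (i == j) 1
    else if (length(a) == 0 || length(b) == 0) 0
    else length(intersect(a, b)) / sqrt(length(a) * length(b))
  }
  K
}

# trapezoidal ROC integration oracle
auroc_trapezoid <- function(scores, labels) {
  y <- as.numeric(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y == 1] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y == 0] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# similarity matrix for exact {0,1} block structure: features in the same
# block get K = 1, different blocks K = 0
block_sim <- function(block_of) {
  ids <- names(block_of)
  K <- outer(block_of, block_of, function(a, b) as.numeric(a == b))
  dimnames(K) <- list(ids, ids)
  K
}

# a tiny trained model fixture on synthetic data (shared across tests)
small_sim <- function(seed = 7) {
  simulate_cohorts(sim_config(n_patients = 60, n_reference = 150,
                              n_blocks = 8, block_size = 6,
                              n_predictive_blocks = 4, seed = seed))
}
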