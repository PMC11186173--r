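#' Synthetic cohort generator configuration
#'
#' The generator emulates the two data structures the method exploits:
#' blocks of redundant binary features (within-block co-occurrence) and a
#' large unlabeled reference cohort sharing that co-occurrence structure.
#' Each block has a latent Bernoulli driver per patient; every feature in the
#' block copies the driver with independent flip noise. In predictive blocks
#' the driver probability depends on the response label through the `effect`
#' pair; predictive blocks alternate direction (odd blocks sensitive, even
#' blocks resistant, i.e. the effect pair swapped) so that both response
#' classes have planted signal. The reference cohort is drawn label-free from
#' the label-marginalized block model.
#'
#' @param n_patients labeled cohort size.
#' @param n_reference unlabeled reference cohort size.
#' @param n_blocks number of feature blocks.
#' @param block_size features per block.
#' @param n_predictive_blocks leading blocks carrying label signal.
#' @param effect carriage probability pair `(p_given_pCR, p_given_nonpCR)`
#'   for the driver of a sensitive-direction predictive block.
#' @param background driver carriage probability of non-predictive blocks.
#' @param flip_noise per-feature probability of flipping the driver state.
#' @param label_balance fraction of pCR (sensitive) patients.
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200, n_reference = 1000, n_blocks = 40,
                       block_size = 25, n_predictive_blocks = 8,
                       effect = c(0.7, 0.2), background = 0.15,
                       flip_noise = 0.02, label_balance = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_patients >= 1, n_reference >= 1, n_blocks >= 1, block_size >= 1,
            n_predictive_blocks >= 0, n_predictive_blocks <= n_blocks,
            all(effect >= 0 & effect <= 1), background >= 0, background <= 1,
            flip_noise >= 0, flip_noise <= 1,
            label_balance > 0, label_balance < 1)
  structure(list(n_patients = n_patients, n_reference = n_reference,
                 n_blocks = n_blocks, block_size = block_size,
                 n_predictive_blocks = n_predictive_blocks, effect = effect,
                 background = background, flip_noise = flip_noise,
                 label_balance = label_balance, seed = as.integer(seed)),
            class = "sim_config")
}

# internal: block-model matrix given per-patient driver probabilities
# (patients x blocks) -> binary patients x (blocks*block_size) matrix
block_model_draw <- function(driver_prob, block_size, flip_noise, patient_ids,
                             feature_ids) {
  n <- nrow(driver_prob)
  drivers <- matrix(stats::rbinom(length(driver_prob), 1, driver_prob), n)
  feats <- drivers[, rep(seq_len(ncol(drivers)), each = block_size),
                   drop = FALSE]
  flips <- matrix(stats::rbinom(length(feats), 1, flip_noise), n)
  feats <- abs(feats - flips)   # XOR with flip noise
  dimnames(feats) <- list(patient_ids, feature_ids)
  as_feature_matrix(feats)
}

#' Generate matched labeled and reference cohorts
#'
#' See [sim_config()] for the generative model. Reproducible bit-exactly
#' under a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `fm` (labeled feature matrix), `labels` (named 0/1,
#'   exactly `round(label_balance * n_patients)` sensitive), `reference`
#'   (unlabeled feature matrix), and `truth` (data.frame of feature_id,
#'   block, predictive flag, direction; plus attribute `null_model` when the
#'   effect pair carries no signal).
#' @export
simulate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  B <- cfg$n_blocks
  feature_ids <- sprintf("SIM:B%02d|F%03d",
                         rep(seq_len(B), each = cfg$block_size),
                         rep(seq_len(cfg$block_size), times = B))
  patient_ids <- sprintf("P%04d", seq_len(n))
  ref_ids <- sprintf("R%04d", seq_len(cfg$n_reference))

  n_pos <- round(cfg$label_balance * n)
  labels <- stats::setNames(sample(c(rep(1L, n_pos), rep(0L, n - n_pos))),
                            patient_ids)

  # per-block driver probabilities; predictive blocks alternate direction
  direction <- rep(NA_character_, B)
  if (cfg$n_predictive_blocks > 0)
    direction[seq_len(cfg$n_predictive_blocks)] <-
      rep(c("sensitive", "resistant"),
          length.out = cfg$n_predictive_blocks)
  p_pcr <- ifelse(is.na(direction), cfg$background,
                  ifelse(direction == "sensitive", cfg$effect[1], cfg$effect[2]))
  p_non <- ifelse(is.na(direction), cfg$background,
                  ifelse(direction == "sensitive", cfg$effect[2], cfg$effect[1]))
  driver_prob <- matrix(ifelse(rep(labels, B) == 1, rep(p_pcr, each = n),
                               rep(p_non, each = n)), n, B)
  fm <- block_model_draw(driver_prob, cfg$block_size, cfg$flip_noise,
                         patient_ids, feature_ids)

  # reference: label-free marginal of the same block model
  p_ref <- cfg$label_balance * p_pcr + (1 - cfg$label_balance) * p_non
  ref_prob <- matrix(rep(p_ref, each = cfg$n_reference), cfg$n_reference, B)
  reference <- block_model_draw(ref_prob, cfg$block_size, cfg$flip_noise,
                                ref_ids, feature_ids)

  truth <- data.frame(
    feature_id = feature_ids,
    block = rep(seq_len(B), each = cfg$block_size),
    predictive = rep(!is.na(direction), each = cfg$block_size),
    direction = rep(direction, each = cfg$block_size),
    stringsAsFactors = FALSE
  )
  if (cfg$effect[1] == cfg$effect[2])
    attr(truth, "null_model") <- TRUE
  list(fm = fm, labels = labels, reference = reference, truth = truth,
       config = cfg)
}

#' Inject simulated feature errors
#'
#' Emulates genotyping/expression-call errors. `false_negative` clears each
#' set bit independently with probability `rate`. `false_positive` sets clear
#' bits with a per-zero probability normalized so that the expected number of
#' added bits equals `rate` times the current set-bit count (binary genomic
#' matrices are sparse; un-normalized per-zero flipping would not resemble
#' sequencing error). `both` applies each mechanism at `rate / 2`.
#' Deterministic under `seed`.
#'
#' @param fm feature matrix.
#' @param rate error rate in \[0, 0.25\]; a higher rate warns.
#' @param mode `"false_positive"`, `"false_negative"`, or `"both"`.
#' @param seed integer seed.
#' @return corrupted feature matrix with the same dimensions and dimnames.
#' @export
inject_errors <- function(fm, rate, mode = c("both", "false_positive",
                                             "false_negative"), seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(rate >= 0)
  if (rate > 0.25) warning("error rate above 0.25 exceeds the intended range")
  fm <- as_feature_matrix(fm)
  if (rate == 0) return(fm)
  set.seed(seed)
  m <- as.matrix(fm)
  ones <- which(m == 1)
  zeros <- which(m == 0)
  fn_rate <- switch(mode, false_negative = rate, both = rate / 2, 0)
  fp_mult <- switch(mode, false_positive = rate, both = rate / 2, 0)
  if (fn_rate > 0 && length(ones))
    m[ones[stats::runif(length(ones)) < fn_rate]] <- 0
  if (fp_mult > 0 && length(zeros)) {
    per_zero <- min(1, fp_mult * length(ones) / length(zeros))
    m[zeros[stats::runif(length(zeros)) < per_zero]] <- 1
  }
  as_feature_matrix(m)
}
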