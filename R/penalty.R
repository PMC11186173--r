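# Redundancy penalty: per-patient clustering of the patient's retained
# features on the reference co-occurrence similarity, and the epsilon
# penalization factors (sum of within-cluster similarity coefficients).

# Hybrid dynamic tree cut on an hclust tree.
#
# Reimplementation of the hybrid dynamic branch-cutting idea for dendrograms:
# a static cut at `cut_height_frac` of the tree height defines the coarse
# branches; each branch is then recursively split at its top merge when both
# sub-branches look like genuine clusters — internally tight (normalized core
# scatter <= max_core_scatter) and well separated from the merge (normalized
# gap >= min_gap). deep_split in 0..4 controls how aggressively branches are
# split via the standard mapping max_core_scatter = (0.64, 0.73, 0.82, 0.91,
# 0.95)[deep_split + 1], min_gap = (1 - max_core_scatter) * 3/4. Leaves not
# assigned to any cluster of size >= min_cluster_size get label 0.
#
# Returns an integer label per leaf, in leaf order; 0 = unassigned.
dynamic_hybrid_cut <- function(hc, deep_split = 2, min_cluster_size = 2,
                               cut_height_frac = 0.99) {
  stopifnot(deep_split %in% 0:4)
  h <- hc$height
  m <- length(h)
  n <- m + 1L
  if (m == 0L) return(1L)
  cut_h <- cut_height_frac * max(h)
  ref_h <- unname(stats::quantile(h, 0.05, names = FALSE))
  denom <- max(cut_h - ref_h, .Machine$double.eps)
  max_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  min_gap <- (1 - max_scatter) * 3 / 4

  # per merge node: member leaves, count and sum of internal merge heights
  members <- vector("list", m)
  sum_h <- numeric(m)
  cnt_h <- integer(m)
  for (k in seq_len(m)) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    mem_a <- if (a < 0) -a else members[[a]]
    mem_b <- if (b < 0) -b else members[[b]]
    members[[k]] <- c(mem_a, mem_b)
    sum_h[k] <- h[k] + (if (a > 0) sum_h[a] else 0) + (if (b > 0) sum_h[b] else 0)
    cnt_h[k] <- 1L + (if (a > 0) cnt_h[a] else 0L) + (if (b > 0) cnt_h[b] else 0L)
  }

  node_size <- function(x) if (x < 0) 1L else length(members[[x]])
  node_members <- function(x) if (x < 0) -x else members[[x]]
  node_scatter <- function(x) {
    if (x < 0 || cnt_h[x] == 0L) return(0)
    (sum_h[x] / cnt_h[x] - ref_h) / denom
  }
  node_hmax <- function(x) if (x < 0) ref_h else h[x]

  labels <- integer(n)
  next_lab <- 0L

  assign_all <- function(x) {
    next_lab <<- next_lab + 1L
    labels[node_members(x)] <<- next_lab
  }

  qualifies <- function(x, h_top) {
    gap <- (h_top - node_hmax(x)) / denom
    node_size(x) >= min_cluster_size &&
      node_scatter(x) <= max_scatter &&
      gap >= min_gap
  }

  process <- function(x) {
    a <- hc$merge[x, 1]; b <- hc$merge[x, 2]
    h_top <- h[x]
    ok_a <- qualifies(a, h_top)
    ok_b <- qualifies(b, h_top)
    if (ok_a && ok_b) {
      process_cluster(a)
      process_cluster(b)
    } else if (ok_a && node_size(b) < min_cluster_size) {
      labels[node_members(b)] <<- 0L
      process_cluster(a)
    } else if (ok_b && node_size(a) < min_cluster_size) {
      labels[node_members(a)] <<- 0L
      process_cluster(b)
    } else {
      assign_all(x)
    }
  }

  # a candidate cluster: a single leaf stays unassigned (-> singleton later);
  # an internal node is either split further or assigned as one cluster
  process_cluster <- function(x) {
    if (x < 0) { labels[-x] <<- 0L; return(invisible()) }
    process(x)
  }

  # static stage: branches below the cut height
  static <- stats::cutree(hc, h = cut_h)
  for (cl in unique(static)) {
    leaves <- which(static == cl)
    if (length(leaves) < min_cluster_size) {
      labels[leaves] <- 0L
      next
    }
    # root of this static branch: the merge node holding exactly these leaves
    root <- which(vapply(seq_len(m), function(k) {
      length(members[[k]]) == length(leaves) && all(members[[k]] %in% leaves)
    }, logical(1)))[1]
    process_cluster(root)
  }
  labels
}

#' Cluster one patient's retained features on reference similarity
#'
#' Ward-variant (ward.D2) agglomerative clustering on the distance
#' d_ij = 1 - K_ij, cut with a hybrid dynamic tree cut (deepSplit depth 2,
#' minimum cluster size 2). Features the cut leaves unassigned become
#' singleton clusters, so every feature gets a label.
#'
#' @param sim_sub principal similarity submatrix for the patient's retained
#'   features (at least one feature).
#' @param deep_split dynamic-cut depth, 0 (conservative) to 4 (aggressive).
#' @param min_cluster_size smallest cluster the cut may emit.
#' @param cut_height_frac static cut as a fraction of tree height.
#' @return named integer vector: feature id -> cluster label (1..k).
#' @export
cluster_patient_features <- function(sim_sub, deep_split = 2,
                                     min_cluster_size = 2,
                                     cut_height_frac = 0.99) {
  sim_sub <- as.matrix(sim_sub)
  p <- nrow(sim_sub)
  if (p == 0) stop("no features to cluster")
  ids <- rownames(sim_sub)
  if (p == 1) return(stats::setNames(1L, ids))
  d <- stats::as.dist(1 - sim_sub)
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- dynamic_hybrid_cut(hc, deep_split, min_cluster_size,
                               cut_height_frac)
  # unassigned features become singletons
  un <- which(labels == 0L)
  if (length(un))
    labels[un] <- max(labels) + seq_along(un)
  # relabel to consecutive 1..k in order of first appearance
  stats::setNames(as.integer(factor(labels, levels = unique(labels))), ids)
}

#' Per-patient redundancy penalization factors
#'
#' For each of a patient's retained features i, epsilon_i is the sum of
#' Otsuka-Ochiai coefficients K_ij over the patient's features j sharing i's
#' cluster (including K_ii = 1, so epsilon_i >= 1). Coefficients to features
#' outside i's cluster are excluded: non-significant overlaps between
#' unrelated features must not accumulate into the penalty.
#'
#' @param patient_features non-empty character vector of the patient's
#'   retained feature ids.
#' @param sim similarity matrix covering those features.
#' @param ... passed to [cluster_patient_features()].
#' @return list with `feature_id`, `epsilon` (named numeric), `n` (feature
#'   count) and `epsilon_bar` (mean epsilon).
#' @export
epsilon_vector <- function(patient_features, sim, ...) {
  patient_features <- as.character(patient_features)
  if (length(patient_features) == 0)
    stop("patient carries no retained features: unscorable")
  sub <- similarity_submatrix(sim, patient_features)
  cl <- cluster_patient_features(sub, ...)
  eps <- numeric(length(patient_features))
  for (lab in unique(cl)) {
    idx <- which(cl == lab)
    eps[idx] <- rowSums(sub[idx, idx, drop = FALSE])
  }
  names(eps) <- patient_features
  list(feature_id = patient_features, epsilon = eps,
       n = length(patient_features), epsilon_bar = mean(eps),
       clusters = cl)
}
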