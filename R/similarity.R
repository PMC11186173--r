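#' Otsuka-Ochiai co-occurrence similarity between genomic features
#'
#' For features i and j with reference carrier sets A_i and A_j,
#' K_ij = |A_i ∩ A_j| / sqrt(|A_i| |A_j|) — the cosine similarity of the two
#' carrier sets, estimated from a large unlabeled reference cohort. Features
#' carried by no reference patient get K_ij = 0 (j != i) and K_ii = 1, so the
#' downstream penalty degrades gracefully to 1 (non-redundant).
#'
#' @param reference binary feature matrix of the unlabeled reference cohort
#'   (patients x features). Must have at least one patient.
#' @param features character vector of feature ids to compute the matrix for;
#'   ids absent from the reference are treated as zero-carrier features.
#' @param sparse_above integer; above this many features the matrix is stored
#'   sparse, with coefficients below `sparse_tol` dropped.
#' @param sparse_tol similarity threshold used only for sparse storage.
#' @return symmetric similarity matrix with `features` as dimnames; dense
#'   `matrix` up to `sparse_above` features, `dgCMatrix` beyond.
#' @export
ochiai_matrix <- function(reference, features, sparse_above = 5000,
                          sparse_tol = 0.01) {
  if (nrow(reference) == 0) stop("reference cohort is empty")
  reference <- as_feature_matrix(reference)
  features <- as.character(features)
  if (anyDuplicated(features)) stop("duplicate feature ids requested")
  p <- length(features)
  idx <- match(features, colnames(reference))
  # columns for features absent from the reference stay all-zero
  X <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nrow(reference), p),
                            dimnames = list(rownames(reference), features))
  present <- which(!is.na(idx))
  if (length(present))
    X[, present] <- reference[, idx[present], drop = FALSE]
  counts <- Matrix::colSums(X)
  co <- as.matrix(Matrix::crossprod(X))
  denom <- sqrt(outer(counts, counts))
  K <- ifelse(denom > 0, co / denom, 0)
  diag(K) <- 1
  dimnames(K) <- list(features, features)
  if (p > sparse_above) {
    K[K < sparse_tol] <- 0
    K <- methods::as(K, "CsparseMatrix")
  }
  K
}

#' Principal submatrix of a similarity matrix
#'
#' @param sim similarity matrix from [ochiai_matrix()].
#' @param features feature ids to keep, in the requested order; all must be
#'   present in `sim`.
#' @return principal submatrix in the requested order (dense matrix).
#' @export
similarity_submatrix <- function(sim, features) {
  features <- as.character(features)
  miss <- setdiff(features, rownames(sim))
  if (length(miss))
    stop("features absent from similarity matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  as.matrix(sim[features, features, drop = FALSE])
}
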