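#' Phi coefficient of a binary feature against the response
#'
#' The phi (mean square contingency) coefficient is the Pearson
#' product-moment correlation of two 0/1 vectors, computable from the 2x2
#' contingency table: (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0). A constant
#' feature column returns 0 (no association).
#'
#' @param feature_column 0/1 vector.
#' @param labels 0/1 response vector of the same length, both classes present.
#' @return phi in \[-1, 1\].
#' @export
phi_coefficient <- function(feature_column, labels) {
  f <- as.numeric(feature_column)
  y <- as.numeric(labels)
  if (length(f) != length(y) || length(f) < 2)
    stop("feature and labels must have equal length >= 2")
  if (all(y == y[1])) stop("labels contain a single class")
  n <- length(f)
  n11 <- sum(f * y)
  nf <- sum(f)
  ny <- sum(y)
  if (nf == 0 || nf == n) return(0)
  num <- n11 * (n - nf - ny + n11) - (nf - n11) * (ny - n11)
  num / sqrt(nf * (n - nf) * ny * (n - ny))
}

#' Compute per-feature weights and the retained feature set
#'
#' Each feature's weight omega is its phi coefficient with the sensitive
#' (pCR = 1) label. Features with |omega| below the significance cutoff are
#' dropped from the signature; retained features with omega > 0 form the
#' sensitive class, omega < 0 the resistant class.
#'
#' @param fm binary feature matrix containing all labeled patients.
#' @param labels named 0/1 response vector (a subset of `fm`'s patients).
#' @param cutoff retention threshold on |omega|; 0.13 by default.
#' @return data.frame (the weight table): `feature_id`, `omega`, `class`
#'   (`"sensitive"`/`"resistant"`), `retained`.
#' @export
compute_weights <- function(fm, labels, cutoff = 0.13) {
  fm <- as_feature_matrix(fm)
  labels <- align_labels(fm, labels)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (ncol(fm) == 0) {
    warning("empty feature set: empty weight table")
    return(data.frame(feature_id = character(0), omega = numeric(0),
                      class = character(0), retained = logical(0)))
  }
  X <- fm[names(labels), , drop = FALSE]
  n <- length(y)
  ny <- sum(y)
  n11 <- as.numeric(Matrix::crossprod(X, y))
  nf <- Matrix::colSums(X)
  num <- n11 * (n - nf - ny + n11) - (nf - n11) * (ny - n11)
  den <- sqrt(nf * (n - nf) * ny * (n - ny))
  omega <- ifelse(nf == 0 | nf == n, 0, num / den)
  data.frame(
    feature_id = colnames(fm),
    omega = omega,
    class = ifelse(omega > 0, "sensitive", "resistant"),
    retained = abs(omega) >= cutoff,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Leave-one-out adjusted weights for a training patient
#'
#' When scoring a patient that was part of the training cohort, its own label
#' must not inform the feature weights; the weight table is recomputed on the
#' cohort with that patient held out. External (test) patients are scored
#' with the full-cohort weights.
#'
#' @param fm training feature matrix.
#' @param labels training labels.
#' @param held_out patient id to remove (must be labeled).
#' @param cutoff retention threshold on |omega|.
#' @return weight table as in [compute_weights()].
#' @export
loo_adjusted_weights <- function(fm, labels, held_out, cutoff = 0.13) {
  if (!held_out %in% names(labels)) stop("held_out is not a labeled patient")
  rest <- labels[setdiff(names(labels), held_out)]
  if (length(unique(as.numeric(rest))) < 2)
    stop("removing ", held_out, " leaves a single response class")
  compute_weights(fm, rest, cutoff)
}

#' Write / read a weight table
#'
#' TSV with columns `feature_id`, `omega` (6 decimals), `class`, `retained`.
#'
#' @param weights weight table.
#' @param path file path.
#' @export
write_weight_table <- function(weights, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("feature_id\tomega\tclass\tretained",
               sprintf("%s\t%.6f\t%s\t%s", weights$feature_id, weights$omega,
                       weights$class, ifelse(weights$retained, "TRUE", "FALSE"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "numeric",
                                                "character", "logical"),
                           check.names = FALSE)
  if (!identical(names(tab), c("feature_id", "omega", "class", "retained")))
    stop("malformed weight table: ", path)
  tab
}
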