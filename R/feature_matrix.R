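#' Construct a binary feature matrix
#'
#' The central container of the package: a sparse binary incidence matrix of
#' patients (rows) by genomic features (columns). A set bit means the patient
#' carries the feature (a mutation, a rearrangement, or membership in an
#' expression level). Absence of a bit means 0; there are no missing values.
#'
#' @param patient_ids character vector of unique patient identifiers.
#' @param feature_ids character vector of unique, namespaced feature
#'   identifiers (e.g. `"EXPR:ERBB2|Up_L3"`, `"MUT:TP53"`, `"AGR:A-B"`).
#' @param pairs two-column data.frame (`patient_id`, `feature_id`) listing the
#'   set bits; every id must be declared. Duplicate pairs are an error.
#' @return a `dgCMatrix` with dimnames `list(patient_ids, feature_ids)` and
#'   all stored values equal to 1.
#' @export
feature_matrix <- function(patient_ids, feature_ids, pairs) {
  patient_ids <- as.character(patient_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(patient_ids)) stop("duplicate patient_ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature_ids")
  if (nrow(pairs) > 0) {
    i <- match(as.character(pairs[[1]]), patient_ids)
    j <- match(as.character(pairs[[2]]), feature_ids)
    if (anyNA(i)) stop("pairs reference undeclared patient_id")
    if (anyNA(j)) stop("pairs reference undeclared feature_id")
    if (anyDuplicated(cbind(i, j))) stop("duplicate (patient, feature) pair")
  } else {
    i <- integer(0); j <- integer(0)
  }
  Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(patient_ids), length(feature_ids)),
    dimnames = list(patient_ids, feature_ids)
  )
}

#' Validate and coerce a feature matrix
#'
#' Accepts any matrix-like object with 0/1 entries and dimnames and returns
#' the canonical sparse representation used internally.
#'
#' @param x matrix or sparse Matrix with row (patient) and column (feature)
#'   dimnames and values in \{0, 1\}.
#' @return a binary `dgCMatrix`.
#' @export
as_feature_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("feature matrix needs patient rownames and feature colnames")
  m <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (length(m@x) && !all(m@x %in% c(0, 1)))
    stop("feature matrix values must be 0 or 1")
  m <- Matrix::drop0(m)
  if (anyDuplicated(rownames(m))) stop("duplicate patient_ids")
  if (anyDuplicated(colnames(m))) stop("duplicate feature_ids")
  m
}

#' Read a binary feature matrix
#'
#' Two plain-text dialects are supported. `long-tsv` is a two-column TSV with
#' header `patient_id<TAB>feature_id` and one row per set bit. `mtx-triplet`
#' is a MatrixMarket coordinate file `<path>` with sidecar label files
#' `<path>.rows.txt` (patients) and `<path>.cols.txt` (features).
#'
#' @param path file path.
#' @param format `"long-tsv"` (default) or `"mtx-triplet"`.
#' @return a binary feature matrix (see [feature_matrix()]).
#' @export
read_feature_matrix <- function(path, format = c("long-tsv", "mtx-triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("feature file not found: ", path)
  if (format == "long-tsv") {
    tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
    if (!identical(names(tab), c("patient_id", "feature_id")))
      stop("long-tsv header must be 'patient_id<TAB>feature_id': ", path)
    if (anyDuplicated(tab)) stop("duplicate (patient, feature) pair in ", path)
    patients <- unique(tab$patient_id)
    features <- unique(tab$feature_id)
    feature_matrix(patients, features, tab)
  } else {
    rows_path <- paste0(path, ".rows.txt")
    cols_path <- paste0(path, ".cols.txt")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stop("mtx-triplet sidecar label files missing for ", path)
    m <- Matrix::readMM(path)
    patients <- readLines(rows_path)
    features <- readLines(cols_path)
    if (nrow(m) != length(patients) || ncol(m) != length(features))
      stop("mtx dimensions disagree with sidecar label files for ", path)
    dimnames(m) <- list(patients, features)
    as_feature_matrix(m)
  }
}

#' Write a binary feature matrix
#'
#' Inverse of [read_feature_matrix()]. The `long-tsv` writer emits set bits in
#' matrix order (by patient row, then feature column), UTF-8 with LF line
#' endings, so write/read/write round-trips are byte-identical.
#'
#' @param fm feature matrix.
#' @param path output path.
#' @param format `"long-tsv"` or `"mtx-triplet"`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, format = c("long-tsv", "mtx-triplet")) {
  format <- match.arg(format)
  fm <- as_feature_matrix(fm)
  if (format == "long-tsv") {
    tm <- methods::as(fm, "TsparseMatrix")
    # order by patient row then feature name, so that a write/read/write
    # cycle is byte-stable regardless of column order
    ord <- order(tm@i, colnames(fm)[tm@j + 1L])
    lines <- c("patient_id\tfeature_id",
               paste(rownames(fm)[tm@i[ord] + 1L],
                     colnames(fm)[tm@j[ord] + 1L], sep = "\t"))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    Matrix::writeMM(methods::as(fm, "nsparseMatrix"), path)
    writeLines(rownames(fm), paste0(path, ".rows.txt"))
    writeLines(colnames(fm), paste0(path, ".cols.txt"))
  }
  invisible(path)
}

#' Read / write response labels
#'
#' Labels are a named 0/1 vector: 1 = pathological complete response
#' (sensitive), 0 = non-pCR (resistant). On disk: TSV with header
#' `patient_id<TAB>response`.
#'
#' @param path file path.
#' @return named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  tab <- utils::read.delim(path, colClasses = c("character", "integer"),
                           check.names = FALSE)
  if (!identical(names(tab), c("patient_id", "response")))
    stop("labels header must be 'patient_id<TAB>response': ", path)
  if (!all(tab$response %in% c(0L, 1L))) stop("responses must be 0 or 1")
  if (anyDuplicated(tab$patient_id)) stop("duplicate patient_id in labels")
  stats::setNames(tab$response, tab$patient_id)
}

#' @rdname read_labels
#' @param labels named 0/1 vector.
#' @export
write_labels <- function(labels, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("patient_id\tresponse",
               paste(names(labels), as.integer(labels), sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a continuous expression matrix
#'
#' TSV of genes (rows) by patients (columns); first column `gene_id`. Values
#' are library-normalized expression on any consistent scale — only
#' within-gene ranks are used downstream.
#'
#' @param path file path.
#' @return numeric matrix, genes x patients.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("expression matrix first column must be gene_id: ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("expression values must be finite")
  m
}

# internal: add all-zero rows for patients absent from a feature matrix
# (the long-tsv dialect cannot represent patients carrying no features)
pad_patients <- function(fm, patient_ids) {
  fm <- as_feature_matrix(fm)
  extra <- setdiff(patient_ids, rownames(fm))
  if (length(extra) == 0) return(fm)
  pad <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(extra), ncol(fm)),
                              dimnames = list(extra, colnames(fm)))
  rbind(fm, pad)
}

# internal: align a label vector to a feature matrix, keeping label order
align_labels <- function(fm, labels) {
  miss <- setdiff(names(labels), rownames(fm))
  if (length(miss))
    stop("labeled patients absent from feature matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  labels
}
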