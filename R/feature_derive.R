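#' Twelve-level expression feature scheme
#'
#' Differential-expression features are defined at twelve nested stringency
#' levels per direction. A patient's within-cohort percentile rank of a gene
#' (average-rank convention, scale (0, 100]) is compared to the level cutoffs:
#' `Up_Lk` is set iff percentile >= `up[k]`, `Down_Lk` iff percentile <=
#' `down[k]`. Membership is cumulative: a patient in `Up_L5` is also in
#' `Up_L1..L4`. Level 1 is the weakest (and is pruned before modeling, see
#' [prune_level1()]); level 12 the most extreme.
#'
#' @param up increasing percentile cutoffs in (50, 100), length 12.
#' @param down decreasing percentile cutoffs in (0, 50), length 12; defaults
#'   mirror `up`.
#' @return object of class `level_scheme`.
#' @export
level_scheme <- function(up = seq(52, 96, by = 4), down = 100 - up) {
  if (length(up) != 12 || length(down) != 12)
    stop("level scheme needs exactly 12 cutoffs per direction")
  if (any(diff(up) <= 0) || any(up <= 50) || any(up >= 100))
    stop("Up cutoffs must be strictly increasing within (50, 100)")
  if (any(diff(down) >= 0) || any(down >= 50) || any(down <= 0))
    stop("Down cutoffs must be strictly decreasing within (0, 50)")
  structure(list(up = up, down = down), class = "level_scheme")
}

#' Derive nested expression-level features
#'
#' For each gene, patients are ranked across the cohort (average ranks, ties
#' share rank) and the rank is scaled to a percentile in (0, 100]. Binary
#' features `EXPR:<gene>|Up_Lk` / `EXPR:<gene>|Down_Lk` record membership in
#' each nested level of the scheme. Genes constant across patients are
#' uninformative and emit no features.
#'
#' @param expr numeric matrix, genes x patients (>= 2 patients).
#' @param scheme a [level_scheme()].
#' @return binary feature matrix, patients x features. Features carried by no
#'   patient are dropped.
#' @export
derive_expression_features <- function(expr, scheme = level_scheme()) {
  stopifnot(inherits(scheme, "level_scheme"))
  if (ncol(expr) < 2) stop("need >= 2 patients to rank expression")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and patient colnames")
  n <- ncol(expr)
  pairs <- vector("list", nrow(expr))
  for (g in seq_len(nrow(expr))) {
    v <- expr[g, ]
    if (max(v) == min(v)) next   # constant gene: no information
    pct <- 100 * rank(v, ties.method = "average") / n
    gene <- rownames(expr)[g]
    up_hits <- which(outer(pct, scheme$up, ">="), arr.ind = TRUE)
    dn_hits <- which(outer(pct, scheme$down, "<="), arr.ind = TRUE)
    pairs[[g]] <- data.frame(
      patient_id = colnames(expr)[c(up_hits[, 1], dn_hits[, 1])],
      feature_id = c(
        sprintf("EXPR:%s|Up_L%d", gene, up_hits[, 2]),
        sprintf("EXPR:%s|Down_L%d", gene, dn_hits[, 2])
      ),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0)
    return(feature_matrix(colnames(expr), character(0),
                          data.frame(patient_id = character(0),
                                     feature_id = character(0))))
  feature_matrix(colnames(expr), unique(pairs$feature_id), pairs)
}

#' Derive binary variant features
#'
#' One feature per (class, gene-or-pair): `MUT:<gene>` for somatic
#' nonsynonymous mutations, `AGR:<geneA>-<geneB>` for adjacent gene
#' rearrangements. A patient is set iff it has at least one qualifying record
#' (repeated records are idempotent).
#'
#' @param variants data.frame with columns `patient_id`, `gene_or_pair`,
#'   `class` (values `MUT` or `AGR`).
#' @return binary feature matrix over the patients present in `variants`.
#' @export
derive_variant_features <- function(variants) {
  req <- c("patient_id", "gene_or_pair", "class")
  if (!all(req %in% names(variants)))
    stop("variant table needs columns: ", paste(req, collapse = ", "))
  if (nrow(variants) == 0)
    return(feature_matrix(character(0), character(0),
                          data.frame(patient_id = character(0),
                                     feature_id = character(0))))
  bad <- which(!variants$class %in% c("MUT", "AGR") |
                 is.na(variants$patient_id) | variants$patient_id == "" |
                 is.na(variants$gene_or_pair) | variants$gene_or_pair == "")
  if (length(bad))
    stop("malformed variant row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  pairs <- unique(data.frame(
    patient_id = as.character(variants$patient_id),
    feature_id = paste0(variants$class, ":", variants$gene_or_pair),
    stringsAsFactors = FALSE
  ))
  feature_matrix(unique(pairs$patient_id), unique(pairs$feature_id), pairs)
}

# internal: parse expression feature ids -> data.frame(gene, direction, level);
# NA rows for non-expression features
parse_expr_features <- function(feature_ids) {
  m <- regmatches(feature_ids,
                  regexec("^EXPR:(.+)\\|(Up|Down)_L([0-9]+)$", feature_ids))
  gene <- vapply(m, function(x) if (length(x)) x[2] else NA_character_, "")
  dir <- vapply(m, function(x) if (length(x)) x[3] else NA_character_, "")
  lev <- vapply(m, function(x) if (length(x)) as.integer(x[4]) else NA_integer_, 1L)
  data.frame(feature_id = feature_ids, gene = gene, direction = dir,
             level = lev, stringsAsFactors = FALSE)
}

#' Prune level-1 expression features
#'
#' Removes every `Up_L1` / `Down_L1` expression feature: the weakest level of
#' differential expression carries too feeble an effect and would bias the
#' integral signature. Idempotent.
#'
#' @param fm feature matrix.
#' @return feature matrix without level-1 expression features.
#' @export
prune_level1 <- function(fm) {
  fm <- as_feature_matrix(fm)
  info <- parse_expr_features(colnames(fm))
  drop <- !is.na(info$level) & info$level == 1L
  fm[, !drop, drop = FALSE]
}

#' Prune genes with same-trend up/down expression features
#'
#' A gene whose up-regulation and down-regulation features both predict the
#' same response direction is internally inconsistent; all expression features
#' of such genes are removed. The check uses the retained features' weight
#' signs: if any retained Up feature and any retained Down feature of the same
#' gene share a sign, the gene's expression features go. Idempotent.
#'
#' @param fm feature matrix.
#' @param weights weight table from [compute_weights()] covering `fm`'s
#'   features.
#' @return pruned feature matrix.
#' @export
prune_same_trend <- function(fm, weights) {
  fm <- as_feature_matrix(fm)
  info <- parse_expr_features(colnames(fm))
  w <- weights[match(colnames(fm), weights$feature_id), ]
  expr <- !is.na(info$gene) & !is.na(w$omega) & w$retained
  bad_genes <- character(0)
  for (gene in unique(info$gene[expr])) {
    rows <- expr & info$gene == gene
    up_signs <- sign(w$omega[rows & info$direction == "Up"])
    dn_signs <- sign(w$omega[rows & info$direction == "Down"])
    if (length(intersect(up_signs, dn_signs)) > 0)
      bad_genes <- c(bad_genes, gene)
  }
  drop <- !is.na(info$gene) & info$gene %in% bad_genes
  fm[, !drop, drop = FALSE]
}
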