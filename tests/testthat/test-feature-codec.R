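test_that("long-tsv read/write round-trips bit-identically", {
  fm <- random_fm(50, 200, density = 0.15, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f1)
  back <- read_feature_matrix(f1)
  expect_identical(as.matrix(back), as.matrix(fm)[rownames(back), colnames(back)])
  expect_setequal(rownames(back), rownames(fm))
  expect_setequal(colnames(back), colnames(fm))
  write_feature_matrix(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("long-tsv parsing handles small, empty and malformed inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tfeature_id", "P1\tF1", "P1\tF2", "P2\tF2"), path)
  fm <- read_feature_matrix(path)
  expect_equal(dim(fm), c(2, 2))
  expect_equal(sum(fm), 3)
  expect_equal(as.numeric(fm["P2", c("F1", "F2")]), c(0, 1))

  writeLines("patient_id\tfeature_id", path)
  empty <- read_feature_matrix(path)
  expect_equal(nrow(empty), 0)

  writeLines(c("patient_id\tfeature_id", "P1\tF1", "P1\tF1"), path)
  expect_error(read_feature_matrix(path), "duplicate")
  expect_error(read_feature_matrix(path, format = "nope"))
})

test_that("mtx-triplet dialect round-trips the incidence", {
  fm <- random_fm(20, 30, seed = 3)
  path <- withr::local_tempfile(fileext = ".mtx")
  write_feature_matrix(fm, path, format = "mtx-triplet")
  back <- read_feature_matrix(path, format = "mtx-triplet")
  expect_identical(dimnames(back), dimnames(fm))
  expect_equal(as.matrix(back), as.matrix(fm))
})

test_that("labels read/write round-trip and validate", {
  labs <- setNames(c(1L, 0L, 1L), c("P1", "P2", "P3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(labs, path)
  expect_identical(read_labels(path), labs)
  writeLines(c("patient_id\tresponse", "P1\t2"), path)
  expect_error(read_labels(path), "0 or 1")
})

test_that("expression level features follow the average-rank percentile", {
  # 1 gene, 4 patients, values 1..4 -> percentiles 25, 50, 75, 100
  expr <- matrix(1:4, 1, dimnames = list("G1", paste0("P", 1:4)))
  fm <- derive_expression_features(expr, level_scheme())
  # P4 at percentile 100 carries all 12 Up levels, no Down
  p4 <- colnames(fm)[fm["P4", ] == 1]
  expect_setequal(p4, sprintf("EXPR:G1|Up_L%d", 1:12))
  # P1 at percentile 25 carries Down levels with cutoff >= 25: 48..28 = L1..L6
  p1 <- colnames(fm)[fm["P1", ] == 1]
  expect_setequal(p1, sprintf("EXPR:G1|Down_L%d", 1:6))
  # P2 at percentile 50 carries nothing (50 < 52 and 50 > 48)
  expect_equal(sum(fm["P2", ]), 0)
})

test_that("a custom scheme with Up_L12 at 99 excludes all but the maximum", {
  expr <- matrix(1:4, 1, dimnames = list("G1", paste0("P", 1:4)))
  sch <- level_scheme(up = c(52, 56, 60, 64, 68, 72, 76, 80, 84, 88, 92, 99))
  fm <- derive_expression_features(expr, sch)
  l12 <- "EXPR:G1|Up_L12"
  expect_true(l12 %in% colnames(fm))
  expect_equal(which(fm[, l12] == 1), c(P4 = 4L))
})

test_that("level membership is nested and never bidirectional; constant genes vanish", {
  set.seed(5)
  expr <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(paste0("G", 1:5), sprintf("P%02d", 1:30)))
  expr[3, ] <- 7  # constant gene
  fm <- as.matrix(derive_expression_features(expr))
  info <- igensigrx:::parse_expr_features(colnames(fm))
  expect_false(any(info$gene == "G3"))
  for (g in unique(info$gene)) for (dir in c("Up", "Down")) {
    cols <- which(info$gene == g & info$direction == dir)
    levs <- info$level[cols]
    for (p in rownames(fm)) {
      carried <- levs[fm[p, cols] == 1]
      if (length(carried))  # nested: carrying level k implies all below
        expect_setequal(carried, seq_len(max(carried)))
    }
  }
  for (g in unique(info$gene)) for (p in rownames(fm)) {
    up <- any(fm[p, info$gene == g & info$direction == "Up"] == 1)
    dn <- any(fm[p, info$gene == g & info$direction == "Down"] == 1)
    expect_false(up && dn)
  }
})

test_that("variant features are idempotent per (class, gene)", {
  vt <- data.frame(patient_id = c("P1", "P1", "P2", "P1"),
                   gene_or_pair = c("TP53", "TP53", "TP53", "A-B"),
                   class = c("MUT", "MUT", "MUT", "AGR"))
  fm <- derive_variant_features(vt)
  expect_setequal(colnames(fm), c("MUT:TP53", "AGR:A-B"))
  expect_equal(as.numeric(fm["P1", c("MUT:TP53", "AGR:A-B")]), c(1, 1))
  expect_equal(as.numeric(fm["P2", c("MUT:TP53", "AGR:A-B")]), c(1, 0))
  expect_equal(ncol(derive_variant_features(vt[0, ])), 0)
  bad <- data.frame(patient_id = "P1", gene_or_pair = "X", class = "SNV")
  expect_error(derive_variant_features(bad), "row")
})

test_that("level-1 pruning removes exactly the weakest level and is idempotent", {
  m <- matrix(1, 2, 4, dimnames = list(
    c("P1", "P2"),
    c("EXPR:G1|Up_L1", "EXPR:G1|Up_L2", "EXPR:G2|Down_L1", "MUT:TP53")))
  out <- prune_level1(m)
  expect_setequal(colnames(out), c("EXPR:G1|Up_L2", "MUT:TP53"))
  expect_identical(colnames(prune_level1(out)), colnames(out))
})

test_that("same-trend genes lose all their expression features", {
  feats <- c("EXPR:G1|Up_L3", "EXPR:G1|Down_L2", "EXPR:G2|Up_L3",
             "EXPR:G2|Down_L2", "EXPR:G3|Up_L2", "MUT:TP53")
  m <- matrix(1, 2, length(feats), dimnames = list(c("P1", "P2"), feats))
  wt <- data.frame(feature_id = feats,
                   omega = c(0.2, 0.15, 0.2, -0.2, 0.2, 0.4),
                   class = "sensitive", retained = TRUE)
  out <- prune_same_trend(m, wt)
  # G1 up/down share a sign -> dropped; G2 opposite trend and G3 unpaired kept
  expect_setequal(colnames(out), c("EXPR:G2|Up_L3", "EXPR:G2|Down_L2",
                                   "EXPR:G3|Up_L2", "MUT:TP53"))
  wt2 <- wt[wt$feature_id %in% colnames(out), ]
  expect_identical(colnames(prune_same_trend(out, wt2)), colnames(out))
})
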