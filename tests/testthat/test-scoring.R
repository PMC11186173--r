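wt_of <- function(ids, omega, class = NULL, retained = TRUE) {
  data.frame(feature_id = ids, omega = omega,
             class = if (is.null(class)) ifelse(omega > 0, "sensitive", "resistant") else class,
             retained = retained, stringsAsFactors = FALSE)
}

test_that("orthogonal reference reduces a class score to the mean |omega|", {
  ids <- c("a", "b")
  K <- diag(2); dimnames(K) <- list(ids, ids)
  wt <- wt_of(ids, c(0.3, 0.4))
  expect_equal(class_score(ids, wt, K, "sensitive"), 0.35, tolerance = 1e-12)
  expect_equal(class_score(ids, wt, K, "resistant"), 0)
  # resistant side: same closed form on the magnitudes
  wtr <- wt_of(ids, c(-0.3, -0.4))
  expect_equal(class_score(ids, wtr, K, "resistant"), 0.35, tolerance = 1e-12)
  # larger orthogonal case
  set.seed(8)
  ids2 <- paste0("f", 1:9)
  K2 <- diag(9); dimnames(K2) <- list(ids2, ids2)
  w <- runif(9, 0.14, 0.6)
  expect_equal(class_score(ids2, wt_of(ids2, w), K2, "sensitive"), mean(w),
               tolerance = 1e-12)
})

test_that("hand-worked redundant trio reproduces the effective-weight formula", {
  ids <- c("f1", "f2", "f3")
  K <- diag(3); K[1, 2] <- K[2, 1] <- 1
  dimnames(K) <- list(ids, ids)
  wt <- wt_of(ids, c(0.3, 0.3, 0.4))
  # independent hand evaluation: eps = (2, 2, 1), eps_bar = 5/3,
  # sum EW = 0.3/2 + 0.3/2 + 0.4/1 = 0.70, EFN = 3/(5/3) = 1.8
  eps <- c(2, 2, 1)
  hand <- sum(c(0.3, 0.3, 0.4) / eps) / (3 / mean(eps))
  expect_equal(hand, 0.7 / 1.8)
  expect_equal(class_score(ids, wt, K, "sensitive"), hand, tolerance = 1e-12)
})

test_that("class scores ignore features the patient lacks and unretained features", {
  ids <- c("a", "b", "c")
  K <- diag(3); dimnames(K) <- list(ids, ids)
  wt <- wt_of(ids, c(0.5, 0.3, 0.2), retained = c(TRUE, TRUE, FALSE))
  expect_equal(class_score(c("a", "c"), wt, K, "sensitive"), 0.5)
  expect_equal(class_score(character(0), wt, K, "sensitive"), 0)
})

test_that("mixed-class patients share one effective feature number", {
  ids <- c("s1", "s2", "r1", "r2")
  K <- diag(4); dimnames(K) <- list(ids, ids)
  wt <- wt_of(ids, c(0.4, 0.2, -0.3, -0.1))
  # patient-level n = 4, eps all 1: S = (0.4 + 0.2)/4, R = (0.3 + 0.1)/4
  expect_equal(class_score(ids, wt, K, "sensitive"), 0.15, tolerance = 1e-12)
  expect_equal(class_score(ids, wt, K, "resistant"), 0.10, tolerance = 1e-12)
})

test_that("uniform k-fold feature duplication leaves class scores unchanged", {
  set.seed(14)
  base_ids <- paste0("g", 1:6)
  w <- c(0.45, 0.3, 0.2, -0.35, -0.25, -0.15)
  # orthogonal base features; duplication makes K = 1 within copy groups
  for (k in c(2, 3, 5)) {
    dup_ids <- paste0(rep(base_ids, each = k), "_copy", rep(seq_len(k), 6))
    K_base <- diag(6); dimnames(K_base) <- list(base_ids, base_ids)
    K_dup <- block_sim(setNames(rep(1:6, each = k), dup_ids))
    wt_base <- wt_of(base_ids, w)
    wt_dup <- wt_of(dup_ids, rep(w, each = k))
    for (carried in list(base_ids, base_ids[c(1, 4)], base_ids[1:3])) {
      carried_dup <- paste0(rep(carried, each = k), "_copy", rep(seq_len(k), length(carried)))
      for (cls in c("sensitive", "resistant")) {
        expect_equal(class_score(carried_dup, wt_dup, K_dup, cls),
                     class_score(carried, wt_base, K_base, cls),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("D-line slope maximizes Youden J with smallest-angle tie-break", {
  # separable: sensitives above the diagonal, resistants below
  R <- c(0.1, 0.2, 0.9, 0.8)
  S <- c(0.9, 0.8, 0.1, 0.2)
  y <- c(1, 1, 0, 0)
  dl <- fit_dline(R, S, y)
  expect_equal(dl$youden_J, 1)
  # grid oracle: smallest separating grid angle
  thetas <- seq(0.5, 89.5, by = 0.5)
  J <- vapply(thetas, function(th) {
    pred <- S > tan(th * pi / 180) * R
    mean(pred[y == 1]) - mean(pred[y == 0])
  }, numeric(1))
  expect_equal(dl$theta_deg, thetas[which.max(J)])
  expect_equal(dl$slope, tan(dl$theta_deg * pi / 180))
  # flipped labels: no angle does better than J = 0
  dl_flip <- fit_dline(R, S, 1 - y)
  expect_lte(dl_flip$youden_J, 0)
  # single sensitive above, single resistant below
  expect_equal(fit_dline(c(0, 1), c(1, 0), c(1, 0))$youden_J, 1)
  expect_error(fit_dline(c(0, 1), c(1, 0), c(1, 1)), "single class")
  expect_warning(dl_deg <- fit_dline(c(1, 1), c(1, 1), c(1, 0)), "identical")
  expect_equal(dl_deg$slope, 1)
})

test_that("final score is the signed perpendicular distance to the D-line", {
  dl <- structure(list(slope = 1), class = "dline")
  d <- 0.37
  expect_equal(final_score(0, d * sqrt(2), dl), d, tolerance = 1e-12)
  expect_equal(final_score(d * sqrt(2), 0, dl), -d, tolerance = 1e-12)
  expect_equal(final_score(0.4, 0.4, dl), 0)
  dl2 <- structure(list(slope = 2.5), class = "dline")
  expect_equal(final_score(1, 2.5, dl2), 0)
})

test_that("training runs end-to-end and LOO scoring reproduces the fit", {
  sim <- small_sim(seed = 7)
  model <- igensig_train(sim$fm, sim$labels, sim$reference,
                         igensig_config(seed = 7))
  wt <- model$weights
  expect_gt(sum(wt$retained & wt$class == "sensitive"), 0)
  expect_gt(sum(wt$retained & wt$class == "resistant"), 0)
  resc <- score_cohort(model, sim$fm, loo = TRUE)
  expect_equal(resc$sensitive_score, model$train_scores$sensitive_score)
  expect_equal(resc$final_score, model$train_scores$final_score)
  expect_identical(resc$predicted, as.integer(resc$final_score > 0))
  expect_error(score_cohort(model, sim$reference, loo = TRUE), "non-training")
})

test_that("tiny four-patient cohort trains end-to-end", {
  m <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1,
                1, 0, 1, 0), 4, 3,
              dimnames = list(paste0("P", 1:4), paste0("F", 1:3)))
  y <- setNames(c(1, 1, 0, 0), paste0("P", 1:4))
  ref <- random_fm(20, 3, density = 0.4, seed = 1)
  colnames(ref) <- paste0("F", 1:3)
  model <- igensig_train(m, y, ref, igensig_config(seed = 1))
  sc <- score_cohort(model, m)
  expect_equal(nrow(sc), 4)
  expect_true(all(is.finite(sc$final_score)))
})

test_that("scores are invariant to patient and feature order; empty patients score zero", {
  sim <- small_sim(seed = 9)
  model <- igensig_train(sim$fm, sim$labels, sim$reference,
                         igensig_config(seed = 9))
  sc <- score_cohort(model, sim$fm)
  set.seed(1)
  fm_perm <- sim$fm[sample(nrow(sim$fm)), sample(ncol(sim$fm))]
  sc_perm <- score_cohort(model, fm_perm)
  m <- merge(sc, sc_perm, by = "patient_id")
  expect_equal(m$final_score.x, m$final_score.y, tolerance = 1e-12)
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(1, 2),
                                dimnames = list("PX", colnames(sim$fm)[1:2]))
  sc0 <- score_cohort(model, empty)
  expect_equal(unlist(sc0[1, c("sensitive_score", "resistant_score", "final_score")]),
               c(sensitive_score = 0, resistant_score = 0, final_score = 0))
})

test_that("model artifacts save and load losslessly enough to re-score", {
  sim <- small_sim(seed = 5)
  model <- igensig_train(sim$fm, sim$labels, sim$reference,
                         igensig_config(seed = 5))
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_equal(back$dline$slope, model$dline$slope)
  expect_equal(back$train_labels, model$train_labels)
  sc1 <- score_cohort(model, sim$fm)
  sc2 <- score_cohort(back, sim$fm)
  # weights are serialized at 6 decimals; scores agree to that precision
  expect_equal(sc2$final_score, sc1$final_score, tolerance = 1e-4)
})
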