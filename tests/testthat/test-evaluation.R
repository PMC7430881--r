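# Folding, ROC sweep, cross-validation, network extraction, ranking.

test_that("fold assignment is balanced and reproducible", {
  m <- matrix(0, 10, 10, dimnames = list(paste0("u", 1:10), paste0("d", 1:10)))
  f <- make_folds(m, seed = 42)
  expect_equal(unname(table(f$fold)), rep(20L, 5), ignore_attr = TRUE)
  expect_identical(f$fold, make_folds(m, seed = 42)$fold)
  expect_false(identical(f$fold, make_folds(m, seed = 43)$fold))

  m7 <- matrix(0, 7, 1, dimnames = list(paste0("u", 1:7), "d"))
  sizes <- sort(unname(table(factor(make_folds(m7, 1)$fold, levels = 0:4))))
  expect_equal(as.integer(sizes), c(1L, 1L, 1L, 2L, 2L))
})

test_that("masking zeroes exactly the fold's positives and is restorable", {
  set.seed(NULL)
  Y <- matrix(1, 4, 5, dimnames = list(paste0("u", 1:4), paste0("d", 1:5)))
  f <- make_folds(Y, 7)
  masked <- mask_fold(Y, f, 2)
  expect_equal(sum(Y) - sum(masked), sum(f$fold == 2))
  restored <- masked
  restored[f$fold == 2] <- Y[f$fold == 2]
  expect_identical(restored, Y)

  Y0 <- Y * 0
  expect_identical(mask_fold(Y0, f, 0), Y0)   # nothing to mask
  expect_error(mask_fold(Y, f, 9), "0..4")
})

test_that("the ROC sweep agrees with exhaustive enumeration", {
  Y <- matrix(c(1, 0, 0, 1, 0, 1), 2, 3,
              dimnames = list(c("u1", "u2"), c("d1", "d2", "d3")))
  f <- make_folds(Y, 5)
  pred <- idssim:::with_seed(9, matrix(runif(6), 2, 3,
                                       dimnames = dimnames(Y)))
  for (fold in 0:4) {
    cells <- f$fold == fold
    if (sum(Y[cells] == 1) == 0 || sum(Y[cells] == 0) == 0) next
    roc <- fold_roc(pred, Y, f, fold)
    orc <- oracle_roc(pred[cells], Y[cells])
    expect_equal(roc$tpr, orc$tpr)
    expect_equal(roc$fpr, orc$fpr)
  }
})

test_that("perfect ranking and constant scores give the expected curves", {
  Y <- matrix(c(rep(1, 4), rep(0, 6)), 2, 5,
              dimnames = list(c("u1", "u2"), paste0("d", 1:5)))
  f <- structure(list(seed = 0, fold = matrix(0L, 2, 5,
                                              dimnames = dimnames(Y))),
                 class = "fold_assignment")   # everything in fold 0
  perfect <- Y * 0.9 + 0.05
  roc <- fold_roc(perfect, Y, f, 0)
  expect_equal(idssim:::trapezoid(roc$fpr, roc$tpr), 1)

  flat <- Y * 0 + 0.5
  roc2 <- fold_roc(flat, Y, f, 0)
  # a single effective threshold: the curve is the two endpoints
  expect_equal(idssim:::trapezoid(roc2$fpr, roc2$tpr), 0.5)

  allpos <- Y * 0 + 1
  expect_warning(r3 <- fold_roc(perfect, allpos, f, 0), "degenerate")
  expect_true(r3$degenerate)
})

test_that("cross-validation reaches the sanity ceiling with an oracle predictor", {
  fx <- planted_fixture(seed = 21)
  vocab <- fx$vocab
  assoc <- synth_assoc(vocab, n_lncrnas = 12, n_diseases = 10, n_blocks = 2,
                       seed = 21)
  # oracle: the original (unmasked) labels plus tiny noise on the zeros
  oracle_pred <- function(masked, fsm, dssm, k = 5, eta = 0.9) {
    noise <- idssim:::with_seed(1, matrix(runif(length(assoc), 0, 1e-3),
                                          nrow(assoc), ncol(assoc),
                                          dimnames = dimnames(assoc)))
    pmax(assoc, noise)
  }
  cv <- cross_validate(assoc, vocab, repeats = 2, base_seed = 5,
                       predictor = oracle_pred, fs_from_masked = FALSE)
  expect_gt(cv$auc, 0.99)
  expect_equal(range(cv$mean_fpr), c(0, 1))
  expect_equal(cv$mean_tpr[1], 0)
  expect_equal(cv$mean_tpr[length(cv$mean_tpr)], 1)
  expect_true(all(diff(cv$mean_tpr) >= -1e-12))
})

test_that("one repeat equals one averaged pass over the five folds", {
  v <- synth_vocab(n_terms = 30, seed = 8)
  assoc <- synth_assoc(v, n_lncrnas = 10, n_diseases = 8, n_blocks = 2,
                       seed = 8)
  cv1 <- cross_validate(assoc, v, repeats = 1, base_seed = 3)
  expect_lte(cv1$n_curves, 5L)
  expect_gte(cv1$n_curves, 1L)
  # determinism: identical call, identical curve
  cv2 <- cross_validate(assoc, v, repeats = 1, base_seed = 3)
  expect_identical(cv1$mean_tpr, cv2$mean_tpr)
  expect_identical(cv1$auc, cv2$auc)
})

test_that("the significant network equals a brute-force filter", {
  for (seed in 1:10) {
    Y <- idssim:::with_seed(seed, matrix(rbinom(48, 1, 0.25), 6, 8))
    dimnames(Y) <- list(sprintf("u%d", 1:6), sprintf("d%d", 1:8))
    pred <- idssim:::with_seed(seed + 50,
                               matrix(runif(48), 6, 8,
                                      dimnames = dimnames(Y)))
    pred <- pmax(pred, Y)
    net <- significant_network(pred, Y)
    orc <- oracle_network(pred, Y)
    expect_equal(net$threshold, orc$threshold)
    got <- net$edges[order(net$edges$lncrna, net$edges$disease), ]
    want <- if (is.null(orc$edges)) got[0, ] else
      orc$edges[order(orc$edges$lncrna, orc$edges$disease), ]
    expect_equal(got$score, want$score)
    expect_identical(got$lncrna, want$lncrna)
    # every reported edge is a previously unknown association
    if (nrow(got)) expect_true(all(Y[cbind(got$lncrna, got$disease)] == 0))
  }
})

test_that("tied potential scores give an empty network", {
  Y <- matrix(0, 2, 4, dimnames = list(c("u1", "u2"), paste0("d", 1:4)))
  Y["u1", "d1"] <- 1
  pred <- matrix(0.3, 2, 4, dimnames = dimnames(Y))
  pred["u1", "d1"] <- 1
  net <- significant_network(pred, Y)   # all 7 potentials tied: sd = 0
  expect_identical(nrow(net$edges), 0L)

  pred2 <- pred
  pred2["u2", "d4"] <- 0.95    # a clear outlier above the tight cluster
  net2 <- significant_network(pred2, Y)
  expect_identical(nrow(net2$edges), 1L)
  expect_identical(net2$edges$lncrna, "u2")
  expect_identical(net2$edges$disease, "d4")

  ones <- matrix(1, 2, 4, dimnames = dimnames(Y))
  expect_warning(net3 <- significant_network(pred, ones), "no potential")
  expect_identical(nrow(net3$edges), 0L)
})

test_that("per-disease ranking is deterministic and bounded", {
  Y <- matrix(0, 4, 1, dimnames = list(c("b", "a", "d", "c"), "dz"))
  pred <- matrix(c(0.5, 0.9, 0.1, 0.5), 4, 1, dimnames = dimnames(Y))
  tk <- top_k(pred, Y, "dz", k = 3)
  expect_identical(tk$lncrna, c("a", "b", "c"))   # tie 0.5 broken by name
  expect_identical(tk$rank, 1:3)

  all4 <- top_k(pred, Y, "dz", k = 99)
  expect_identical(nrow(all4), 4L)

  tied <- pred * 0 + 0.2
  expect_identical(top_k(tied, Y, "dz", k = 4)$lncrna, c("a", "b", "c", "d"))
  expect_error(top_k(pred, Y, "nope"), "unknown disease")
})
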