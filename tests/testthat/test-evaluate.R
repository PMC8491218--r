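test_that("a separable model reproduces its own training labels", {
  fix <- planted_classification_fixture(n = 40, n_inform = 2, delta = 6,
                                        seed = 1)
  m <- forward_select(rownames(fix$x), fix$x, fix$y, C = 100, sigma = 10,
                      seed = 1)
  pr <- predict(m, fix$x)
  expect_equal(as.character(pr$label), as.character(fix$y[pr$sample]))
  # duplicated sample column -> identical predictions
  x2 <- cbind(fix$x, DUP = fix$x[, 1])
  pr2 <- predict(m, x2)
  expect_equal(pr2$decision[pr2$sample == "DUP"],
               pr2$decision[pr2$sample == colnames(fix$x)[1]])
})

test_that("prediction fails loudly on missing features or NA expression", {
  fix <- planted_classification_fixture(n = 20, n_inform = 2, seed = 2)
  m <- forward_select(c("INF01", "INF02"), fix$x, fix$y, C = 10, sigma = 1,
                      seed = 2)
  expect_error(predict(m, fix$x[setdiff(rownames(fix$x), m$features[1]), ]),
               "missing signature feature")
  xna <- fix$x
  xna[m$features[1], 3] <- NA
  expect_error(predict(m, xna), "NA")
})

test_that("confusion arithmetic reproduces the published PE rows", {
  # gefitinib: 10 sensitive at 100%, 2 resistant at 50%
  cm <- reconstruct_confusion(10, 2, 100, 50)
  expect_equal(round(mcc(cm$tp, cm$fn, cm$tn, cm$fp), 2), 0.67)
  # sunitinib: 6 sensitive at 67%, 12 resistant at 92%
  cm <- reconstruct_confusion(6, 12, 67, 92)
  expect_equal(round(mcc(cm$tp, cm$fn, cm$tn, cm$fp), 2), 0.61)
  expect_equal(round(100 * (cm$tp + cm$tn) / 18), 83)
  # lapatinib: 8 sensitive at 63%, 23 resistant at 74%
  cm <- reconstruct_confusion(8, 23, 63, 74)
  expect_equal(round(mcc(cm$tp, cm$fn, cm$tn, cm$fp), 2), 0.33)
  expect_equal(round(100 * (cm$tp + cm$tn) / 31), 71)
})

test_that("MCC conventions: perfection, degeneracy, symmetry", {
  expect_equal(mcc(10, 0, 10, 0), 1)
  expect_equal(mcc(0, 10, 0, 10), -1)
  expect_equal(mcc(12, 0, 0, 8), 0)  # all predicted resistant
  set.seed(5)
  for (i in 1:50) {
    cm <- sample(0:20, 4, replace = TRUE)
    expect_equal(abs(mcc(cm[1], cm[2], cm[3], cm[4])),
                 abs(mcc(cm[3], cm[4], cm[1], cm[2])), tolerance = 1e-12)
  }
})

test_that("score matches a brute-force per-sample tally on random matrices", {
  set.seed(6)
  for (i in 1:1000) {
    cm <- sample(0:15, 4, replace = TRUE)  # tp, fn, tn, fp
    if (cm[1] + cm[2] == 0 || cm[3] + cm[4] == 0) next
    truth <- c(rep("resistant", cm[1] + cm[2]),
               rep("sensitive", cm[3] + cm[4]))
    pred <- c(rep("resistant", cm[1]), rep("sensitive", cm[2]),
              rep("sensitive", cm[3]), rep("resistant", cm[4]))
    ids <- sprintf("s%02d", seq_along(truth))
    rep <- score_predictions(setNames(pred, ids), setNames(truth, ids))
    expect_identical(c(rep$tp, rep$fn, rep$tn, rep$fp), as.integer(cm))
    # brute-force MCC from the tally
    den <- (cm[1] + cm[4]) * (cm[1] + cm[2]) * (cm[3] + cm[4]) *
      (cm[3] + cm[2])
    want <- if (den == 0) 0 else
      (cm[1] * cm[3] - cm[4] * cm[2]) / sqrt(den)
    expect_equal(rep$mcc, want, tolerance = 1e-12)
    expect_equal(rep$overall_acc, (cm[1] + cm[3]) / sum(cm),
                 tolerance = 1e-12)
  }
})

test_that("AUC is 1 for perfect, 0 for inverted, ~0.5 for random ranking", {
  truth <- factor(rep(c("sensitive", "resistant"), each = 100),
                  levels = c("sensitive", "resistant"))
  d <- c(seq_len(100), 100 + seq_len(100))
  expect_equal(rank_auc(d, truth), 1)
  expect_equal(rank_auc(-d, truth), 0)
  set.seed(7)
  expect_equal(rank_auc(rnorm(200), truth), 0.5, tolerance = 0.1)
  expect_true(is.na(rank_auc(1:5, factor(rep("resistant", 5),
                                         c("sensitive", "resistant")))))
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  truth <- factor(sample(c("sensitive", "resistant"), 60, replace = TRUE),
                  levels = c("sensitive", "resistant"))
  d <- rnorm(60) + (truth == "resistant")
  want <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = d, levels = c("sensitive", "resistant"),
    direction = "<", quiet = TRUE)))
  expect_equal(rank_auc(d, truth), want, tolerance = 1e-12)
})

test_that("model selection maximizes MCC with documented tie-breaks", {
  mk <- function(mcc, oa) structure(list(mcc = mcc, overall_acc = oa),
                                    class = "validation_report")
  expect_equal(select_best(list(mk(0.2, 0.9), mk(0.7, 0.5),
                                mk(0.5, 0.9))), 2L)
  expect_equal(select_best(list(mk(0.5, 0.6), mk(0.5, 0.8))), 2L)
  expect_equal(select_best(list(mk(0.4, 0.7))), 1L)
  mods <- list(structure(list(features = c("A", "B", "C")),
                         class = "signature_model"),
               structure(list(features = "A"), class = "signature_model"))
  expect_equal(select_best(list(mk(0.5, 0.7), mk(0.5, 0.7)), mods), 2L)
})

test_that("group-stratified reports partition the cohort", {
  ids <- sprintf("s%02d", 1:20)
  truth <- setNames(rep(c("sensitive", "resistant"), 10), ids)
  pred <- truth; pred[1:4] <- rev(pred[1:4])
  groups <- setNames(rep(c("M", "F"), each = 10), ids)
  rep <- score_predictions(setNames(pred, ids), truth, groups = groups)
  expect_named(rep$group_reports, c("F", "M"))
  expect_equal(rep$group_reports$F$n + rep$group_reports$M$n, 20)
  expect_equal(rep$group_reports$M$overall_acc, 6 / 10)
  expect_equal(rep$group_reports$F$overall_acc, 1)
})

test_that("leave-one-gene-out importance flags what matters", {
  set.seed(10)
  agree_noise <- replicate(20, {
    s <- sample.int(1e6, 1)
    fix <- planted_classification_fixture(n = 48, n_inform = 1, n_noise = 1,
                                          delta = 5, seed = s)
    test <- planted_classification_fixture(n = 30, n_inform = 1, n_noise = 1,
                                           delta = 5, seed = s + 1)
    xy <- list(x = fix$x, y = fix$y)
    m <- forward_select(c("INF01", "NSE01"), fix$x, fix$y, C = 100,
                        sigma = 10, seed = s)
    if (length(m$features) < 2)
      m <- structure(modifyList(m, list(features = c("INF01", "NSE01"))),
                     class = "signature_model")
    # refit with both features so removal is defined for each
    m$decision_params <- pesig:::fit_gaussian_svm(
      t(fix$x[m$features, ]), fix$y, m$C, m$sigma)
    imp <- loo_gene_importance(m, fix$x, fix$y, test$x, test$y, seed = s)
    c(noise = abs(imp$delta_mcc[imp$gene == "NSE01"]),
      inform_oa = imp$delta_overall_acc[imp$gene == "INF01"])
  })
  # removing the noise gene barely moves MCC on average
  expect_lt(mean(agree_noise["noise", ]), 0.1)
  # removing the informative gene collapses accuracy towards chance
  expect_lt(mean(agree_noise["inform_oa", ]), -0.3)
})

test_that("single-feature models refuse leave-one-out analysis", {
  fix <- planted_classification_fixture(n = 20, seed = 11)
  m <- forward_select("INF01", fix$x, fix$y, C = 10, sigma = 1, seed = 11)
  expect_error(loo_gene_importance(m, fix$x, fix$y, fix$x, fix$y),
               ">= 2 features")
})
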