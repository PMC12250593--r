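random_confusion <- function(seed) {
  set.seed(seed)
  matrix(rpois(16, sample(3:40, 1)), 4, 4,
         dimnames = list(truth = ecg_classes, prediction = ecg_classes))
}

test_that("the confusion matrix tallies true/predicted pairs exactly", {
  y <- c("SB", "AFIB", "SB", "SR", "GSVT")
  cm <- ecg_confusion(y, y)
  expect_equal(diag(cm), c(SB = 2L, AFIB = 1L, GSVT = 1L, SR = 1L))
  expect_equal(sum(cm), 5)

  set.seed(3)
  yt <- sample(ecg_classes, 200, replace = TRUE)
  yp <- sample(ecg_classes, 200, replace = TRUE)
  cm2 <- ecg_confusion(yt, yp)
  expect_equal(sum(cm2), 200)
  # brute-force tally oracle
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(cm2[i, j],
                   sum(yt == ecg_classes[i] & yp == ecg_classes[j]))
    }
  }
  expect_error(ecg_confusion(c("SB", "XX"), c("SB", "SB")), "class set")
})

test_that("per-class metrics match the one-vs-rest oracle", {
  perfect <- diag(c(10L, 20L, 30L, 40L))
  dimnames(perfect) <- list(ecg_classes, ecg_classes)
  pc <- per_class_metrics(perfect)
  expect_true(all(as.matrix(pc[, -1]) == 1))
  expect_equal(attr(pc, "accuracy"), 1)

  for (s in 1:100) {
    cm <- random_confusion(s)
    pc <- suppressWarnings(per_class_metrics(cm))
    or <- oracle_per_class(cm)
    expect_equal(as.matrix(pc[, -1]), or, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(attr(pc, "accuracy"), sum(diag(cm)) / sum(cm),
                 tolerance = 1e-12)
  }
})

test_that("degenerate confusion matrices use the documented conventions", {
  # class never predicted: precision 0 with a warning, no error
  cm <- matrix(0L, 4, 4, dimnames = list(ecg_classes, ecg_classes))
  cm[1, 1] <- 10L
  cm[2, 1] <- 5L
  warns <- testthat::capture_warnings(pc <- per_class_metrics(cm))
  expect_gt(length(warns), 0)
  expect_match(warns[1], "undefined")
  expect_equal(pc$precision[2], 0)

  # constant predictor: kappa 0 (observed equals expected agreement)
  const <- matrix(0L, 4, 4, dimnames = list(ecg_classes, ecg_classes))
  const[, 1] <- c(10L, 10L, 10L, 10L)
  expect_equal(cohen_kappa(const), 0)
  expect_equal(mcc_multiclass(const), 0)
  expect_error(per_class_metrics(matrix(0, 4, 4)), "empty")
})

test_that("kappa and MCC match textbook oracles and their bounds", {
  perfect <- diag(c(5L, 5L, 5L, 5L))
  expect_equal(cohen_kappa(perfect), 1)
  expect_equal(mcc_multiclass(perfect), 1)
  for (s in 101:200) {
    cm <- random_confusion(s)
    expect_equal(cohen_kappa(cm), oracle_kappa(cm), tolerance = 1e-12)
    expect_equal(mcc_multiclass(cm), oracle_mcc(cm), tolerance = 1e-12)
    expect_gte(cohen_kappa(cm), -1)
    expect_lte(cohen_kappa(cm), 1)
    expect_gte(mcc_multiclass(cm), -1)
    expect_lte(mcc_multiclass(cm), 1)
  }
})

test_that("relabeling classes permutes rows but fixes the aggregates", {
  cm <- random_confusion(7)
  perm <- c(2, 4, 1, 3)
  cmp <- cm[perm, perm]
  expect_equal(cohen_kappa(cmp), cohen_kappa(cm), tolerance = 1e-12)
  expect_equal(mcc_multiclass(cmp), mcc_multiclass(cm), tolerance = 1e-12)
  pc <- suppressWarnings(per_class_metrics(cm))
  pcp <- suppressWarnings(per_class_metrics(cmp))
  expect_equal(as.matrix(pcp[, -1]), as.matrix(pc[perm, -1]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("evaluate_model scores forward functions and fits consistently", {
  ds <- tiny_dataset(n = 20, seed = 13)
  onehot_truth <- function(records) {
    y <- match(as.character(records$label), ecg_classes)
    m <- matrix(0, nrow(records), 4)
    m[cbind(seq_len(nrow(records)), y)] <- 1
    m
  }
  rep1 <- evaluate_model(onehot_truth, ds)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$kappa, 1)

  const_model <- function(records) {
    matrix(rep(c(1, 0, 0, 0), each = nrow(records)), nrow(records), 4)
  }
  rep2 <- suppressWarnings(evaluate_model(const_model, ds))
  expect_equal(rep2$accuracy, mean(ds$label == "SB"))

  # internal consistency: F1 recomputable from its own P and S
  pc <- suppressWarnings(tidy(rep2))
  ok <- pc$precision + pc$sensitivity > 0
  expect_equal(pc$f1[ok],
               2 * pc$precision[ok] * pc$sensitivity[ok] /
                 (pc$precision[ok] + pc$sensitivity[ok]),
               tolerance = 1e-12)
  g <- glance(rep2)
  expect_equal(g$n, 20)
})
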