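test_that("logistic fit separates a separable toy set", {
  x <- matrix(rep(c(0, 1), each = 5), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(0L, 1L), each = 5)
  fit <- fit_lr(x, y)
  pr <- predict(fit, x)
  expect_equal(pr$call, y)
  expect_equal(confusion_metrics(y, pr$call)$accuracy, 100)
  # deterministic: no random initialisation
  expect_identical(coef(fit), coef(fit_lr(x, y)))
})

test_that("a constant feature reduces to the intercept-only model", {
  x <- matrix(1, nrow = 20, ncol = 1, dimnames = list(NULL, "const"))
  y <- c(rep(1L, 15), rep(0L, 5))
  fit <- fit_lr(x, y)
  pr <- predict(fit, x)
  expect_equal(pr$probability, rep(0.75, 20), tolerance = 0.02)
})

test_that("prediction is the sigmoid of the affine score", {
  zero <- structure(list(coefficients = c(f = 0), intercept = 0,
                         descriptor_names = "f", threshold = 0.5),
                    class = "psgkm_lr")
  x <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "f"))
  pr <- predict(zero, x)
  expect_equal(pr$probability, rep(0.5, 10))
  expect_equal(pr$call, rep(1L, 10))  # 0.5 >= threshold

  # monotonicity in a positive-coefficient feature
  up <- structure(list(coefficients = c(f = 2), intercept = -1,
                       descriptor_names = "f", threshold = 0.5),
                  class = "psgkm_lr")
  xs <- matrix(seq(-3, 3, length.out = 50), ncol = 1,
               dimnames = list(NULL, "f"))
  p <- predict(up, xs)$probability
  expect_true(all(diff(p) > 0))

  # column mismatch names the offender
  bad <- xs; colnames(bad) <- "g"
  expect_error(predict(up, bad), "descriptor mismatch.*'g'")
})

test_that("confusion metrics follow the stated formulas", {
  # TP=3, FP=1, FN=2, TN=4
  labels <- c(rep(1, 5), rep(0, 5))
  calls <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- confusion_metrics(labels, calls)
  expect_equal(m$TP, 3); expect_equal(m$FP, 1)
  expect_equal(m$FN, 2); expect_equal(m$TN, 4)
  expect_equal(m$accuracy, 70)
  expect_equal(m$precision, 75)
  expect_equal(m$sensitivity, 60)
  expect_equal(m$specificity, 80)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_equal(round(m$f1, 3), 0.667)
  expect_equal(m$mcc, (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6), tolerance = 1e-12)
  expect_equal(round(m$mcc, 3), 0.408)

  perfect <- confusion_metrics(rep(c(1, 0), 5), rep(c(1, 0), 5))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)

  # all-positive truth, all-positive calls: specificity undefined -> 0 + flag
  conv <- confusion_metrics(rep(1, 5), rep(1, 5))
  expect_equal(conv$specificity, 0)
  expect_true("specificity" %in% conv$undefined)
  expect_error(confusion_metrics(1, c(1, 0)), "equal length")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(12)
  for (i in 1:20) {
    labels <- rbinom(40, 1, 0.5)
    calls <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    m <- confusion_metrics(labels, calls)
    P <- sum(labels == 1); N <- sum(labels == 0)
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N),
                 tolerance = 1e-9)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_equal(m$TP + m$TN + m$FP + m$FN, 40)
  }
})

test_that("curve areas behave at the limits and match the rank oracle", {
  labels <- rep(c(1, 0), each = 10)
  perfect <- curves_and_areas(labels, as.numeric(labels))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$aupr, 1)

  flat <- curves_and_areas(labels, rep(0.4, 20))
  expect_equal(flat$auroc, 0.5)

  set.seed(33)
  for (i in 1:10) {
    lab <- rbinom(80, 1, 0.5)
    if (length(unique(lab)) < 2) next
    score <- round(runif(80), 2)  # ties on purpose
    cur <- curves_and_areas(lab, score)
    expect_equal(cur$auroc, mw_auc(lab, score), tolerance = 1e-9)
    expect_true(cur$aupr >= 0 && cur$aupr <= 1)
  }

  big <- curves_and_areas(rep(c(1, 0), 5000), runif(10000))
  expect_equal(big$auroc, 0.5, tolerance = 0.02)
  expect_error(curves_and_areas(rep(1, 5), runif(5)), "both classes")
})

test_that("model JSON persistence round-trips probabilities exactly", {
  ds <- toy_dataset(15, seed = 61,
                    plant = list(template = "GG-U", start = 5,
                                 p_pos = 0.9, p_neg = 0.1))
  fit <- psgkm(ds, k = 3, seed = 2, num_trees = 50)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(predict(back, ds)$probability, predict(fit, ds)$probability)
  expect_identical(back$model$descriptor_names, fit$model$descriptor_names)
})

test_that("leave-one-out on a separable toy scores 100 percent", {
  ds <- toy_dataset(5, L = 9, seed = 71,
                    plant = list(template = "AGU", start = 1,
                                 p_pos = 1, p_neg = 0))
  cv <- cross_validate(ds, folds = 10, repeats = 1, k = 2, seed = 3,
                       num_trees = 50)
  expect_equal(cv$per_repeat$accuracy, 100)
})

test_that("cross-validation is reproducible and stratified", {
  ds <- toy_dataset(30, L = 21, seed = 81,
                    plant = list(template = "A-CG", start = 3,
                                 p_pos = 0.9, p_neg = 0.1))
  cv1 <- cross_validate(ds, folds = 3, repeats = 2, k = 5, seed = 17,
                        num_trees = 50)
  cv2 <- cross_validate(ds, folds = 3, repeats = 2, k = 5, seed = 17,
                        num_trees = 50)
  expect_identical(cv1$summary, cv2$summary)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_equal(nrow(cv1$per_fold), 6L)
  expect_equal(length(cv1$selections), 6L)
  # every fold's test share of positives within one sample of balance
  expect_true(all(abs(cv1$per_fold$n_test - 20) <= 1))
  # report serialization
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv1, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$folds, 3)
  expect_equal(obj$summary$metric,
               c("accuracy", "precision", "sensitivity", "specificity",
                 "f1", "mcc", "auroc", "aupr"))
  expect_error(cross_validate(ds, folds = 1), "folds")
})
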