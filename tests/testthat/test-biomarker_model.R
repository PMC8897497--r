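test_that("percentile capping normalises into [0, 1]", {
  withr::with_seed(91, {
    x <- matrix(rlnorm(200 * 3, log(100), 1), ncol = 3,
                dimnames = list(NULL, c("A", "B", "C")))
    f <- cap_normalize_features(x)
    expect_true(all(f >= 0 & f <= 1))
    q <- quantile(x[, 1], 0.975, type = 7, names = FALSE)
    i <- which.min(abs(x[, 1] - q))
    expect_equal(unname(f[i, 1]), min(x[i, 1] / q, 1))
    # half the percentile maps to 0.5
    y <- matrix(c(q / 2, x[-1, 1]), ncol = 1, dimnames = list(NULL, "A"))
    qy <- quantile(y[, 1], 0.975, type = 7, names = FALSE)
    expect_equal(unname(cap_normalize_features(y)[1, 1]), min(q / 2 / qy, 1))
  })
  expect_error(cap_normalize_features(matrix(0, 5, 1,
                                             dimnames = list(NULL, "A"))),
               "all-zero")
})

test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c("P", "P", "H", "H"), c("P", "P", "H", "H")), 1)
  # sens 0.8, spec 0.9 -> 0.85
  labels <- c(rep("P", 10), rep("H", 10))
  preds <- c(rep("P", 8), rep("H", 2), rep("H", 9), "P")
  expect_equal(balanced_accuracy(preds, labels), 0.85)
  expect_error(balanced_accuracy(c("P", "P"), c("P", "P")), "single class")

  withr::with_seed(95, {
    for (i in 1:50) {
      lab <- sample(c("a", "b"), 30, replace = TRUE)
      if (length(unique(lab)) < 2) next
      pred <- sample(c("a", "b"), 30, replace = TRUE)
      recalls <- vapply(c("a", "b"), function(cl)
        mean(pred[lab == cl] == cl), numeric(1))
      expect_equal(balanced_accuracy(pred, lab), mean(recalls))
    }
  })
})

test_that("ROC threshold selection on separable data is perfect", {
  r <- roc_threshold(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE), "ge")
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  expect_equal(r$auroc, 1.0)
  expect_true(r$threshold > 2 && r$threshold <= 9)

  r2 <- roc_threshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auroc, 1.0)

  # "le" direction mirrors "ge"
  r3 <- roc_threshold(c(1, 2, 9, 10), c(TRUE, TRUE, FALSE, FALSE), "le")
  expect_equal(r3$sensitivity, 1.0)
  expect_equal(r3$specificity, 1.0)

  expect_error(roc_threshold(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoidal AUROC equals the normalised Mann-Whitney U statistic", {
  withr::with_seed(97, {
    for (i in 1:100) {
      n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
      v <- c(rnorm(n1, 1), rnorm(n2))
      if (runif(1) < 0.3) v <- round(v)  # induce ties
      lab <- rep(c(TRUE, FALSE), c(n1, n2))
      auroc <- roc_threshold(v, lab, "ge")$auroc
      u <- suppressWarnings(
        wilcox.test(v[lab], v[!lab], exact = FALSE)$statistic)
      expect_equal(auroc, unname(u) / (n1 * n2), tolerance = 1e-12)
    }
  })
})

test_that("step-1 model separates a separable cohort perfectly", {
  withr::with_seed(103, {
    n <- 60
    f <- cbind(A = c(runif(n / 2, 5, 6), runif(n / 2, 0, 1)),
               B = rnorm(n), C = rnorm(n))
    rownames(f) <- sprintf("S%02d", 1:n)
    lab <- rep(c("P", "H"), each = n / 2)
    m <- fit_step1_model(f, lab, seed = 1, n_boot = 200)
    expect_equal(m$metrics$balanced_accuracy_train, 1.0)
    expect_equal(m$metrics$balanced_accuracy_validation, 1.0)
    expect_equal(m$metrics$auroc_train, 1.0)
    expect_equal(unname(predict(m, f[1:2, ])), c("P", "P"))
  })
})

test_that("step-2 rules recover the planted per-stratum directions", {
  g <- generate_epitope_cohort(seed = 11)
  f <- cap_normalize_features(g$features)
  rules <- fit_step2_rules(f, g$subjects)
  # planted signs: A,E high -> no-CAD in P; A high -> ACS in G; C -> ACS in H
  expect_equal(rules$P[[1]]$ge_calls, "noCAD")
  expect_equal(rules$P[[2]]$ge_calls, "noCAD")
  expect_equal(rules$G[[1]]$ge_calls, "ACS")
  expect_equal(rules$H[[1]]$ge_calls, "ACS")
  for (st in rules) for (r in st) {
    expect_gte(r$sensitivity, 0.5)
    expect_gte(r$specificity, 0.5)
  }
})

test_that("two-step classification applies the stratum rules and is
           invariant to feature order", {
  g <- generate_epitope_cohort(seed = 12)
  f <- cap_normalize_features(g$features)
  m <- fit_two_step_model(f, g$subjects, seed = 2, n_boot = 100)
  calls <- two_step_classify(m, f)
  expect_setequal(unique(calls$perio_call), c("P", "H"))
  expect_true(all(calls$cad_call %in% c("ACS", "noCAD")))

  # permuting feature columns changes nothing
  calls2 <- two_step_classify(m, f[, c("E", "C", "A", "B", "D")])
  expect_identical(calls, calls2)

  # a subject above all no-CAD thresholds in stratum P is called (P, noCAD)
  s <- f[1, , drop = FALSE]
  s[, c("A", "B")] <- 1; s[, "C"] <- 0; s[, "E"] <- 1
  rownames(s) <- "probe"
  pc <- two_step_classify(m, s)
  if (pc$perio_call == "P") expect_equal(pc$cad_call, "noCAD")
})

test_that("shuffled labels give chance-level AUROC", {
  withr::with_seed(107, {
    aurocs <- vapply(1:20, function(i) {
      g <- generate_epitope_cohort(seed = 1000 + i)
      ph <- g$subjects$perio_group %in% c("P", "H")
      f <- cap_normalize_features(g$features[ph, c("A", "B", "C")])
      lab <- sample(g$subjects$perio_group[ph])  # break the association
      m <- fit_step1_model(f, lab, seed = i, n_boot = 50)
      m$metrics$auroc_train
    }, numeric(1))
    expect_gte(median(aurocs), 0.35)
    expect_lte(median(aurocs), 0.65)
  })
})
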