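# Oxygenation indices, visual scores, Spearman/kappa/ROC statistics.

test_that("PaO2/FiO2 arithmetic and domain checks", {
  expect_equal(pf_ratio(100, 0.5), 200)
  expect_equal(pf_ratio(100, 1.0), 100)
  expect_equal(pf_ratio(90, 0.21), 428.5714, tolerance = 1e-4)
  expect_error(pf_ratio(100, 0), "fio2")
})

test_that("A-a gradient follows PA = FiO2*713 - PaCO2/0.8", {
  expect_equal(aa_gradient(1.0, 663, 40), 0)
  expect_equal(aa_gradient(0.21, 90, 40), 9.73, tolerance = 1e-10)
  expect_equal(aa_gradient(0.40, 60, 48), 165.2, tolerance = 1e-10)
  expect_error(aa_gradient(0.21, -5, 40), "positive")
})

test_that("A-a gradient is linear in FiO2 with slope 713 mmHg", {
  g <- sapply(c(0.3, 0.6, 0.9), function(f) aa_gradient(f, 80, 40))
  expect_equal(diff(g) / 0.3, c(713, 713), tolerance = 1e-9)
})

test_that("visual score sums are bounded and validated", {
  expect_equal(visual_score_sum(rep(3L, 8)), 24)
  expect_equal(visual_score_sum(rep(0L, 8)), 0)
  expect_equal(visual_score_sum(c(1, 2, 0, 3, 1, 2, 2, 1)), 12)
  expect_error(visual_score_sum(c(1, 2, 4, 0, 1, 1, 1, 1)), "0..3")
  expect_error(visual_score_sum(rep(1L, 7)), "expected 8")
})

test_that("Spearman rho matches the rank-difference formula and respects monotone maps", {
  expect_equal(spearman_ci(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_ci(1:4, c(40, 30, 20, 10))$rho, -1)
  # n = 5, sum d^2 = 4: rho = 1 - 6*4/(5*24) = 0.8
  r <- spearman_ci(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_true(r$ci[1] < 0.8 && r$ci[2] > 0.8)

  set.seed(41)
  x <- rnorm(30); y <- x + rnorm(30)
  r1 <- spearman_ci(x, y)$rho
  r2 <- spearman_ci(exp(x), y)$rho          # strictly monotone transform
  r3 <- spearman_ci(x, y^3 + 5 * y)$rho
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, r3, tolerance = 1e-12)

  expect_error(spearman_ci(1:3, 1:3), "at least 4")
  expect_error(spearman_ci(rep(1, 5), 1:5), "constant")
})

test_that("kappa matches the printed confusion-table example and the identity case", {
  expect_equal(cohen_kappa(rep(0:3, 4), rep(0:3, 4)), 1)
  # binary confusion [[20,5],[10,15]] over 50: p_o = 0.7, p_e = 0.5
  r1 <- c(rep(0, 25), rep(1, 25))
  r2 <- c(rep(0, 20), rep(1, 5), rep(0, 10), rep(1, 15))
  expect_equal(cohen_kappa(r1, r2, categories = 0:1), 0.4)
  # both raters constant and identical: defined as 1
  expect_equal(cohen_kappa(rep(2, 10), rep(2, 10)), 1)
  expect_error(cohen_kappa(0:3, 0:2), "equal length")
})

test_that("kappa agrees with an independent implementation on random tables", {
  set.seed(42)
  for (i in 1:10) {
    a <- sample(0:3, 200, replace = TRUE)
    b <- ifelse(runif(200) < 0.6, a, sample(0:3, 200, replace = TRUE))
    tab <- table(factor(a, levels = 0:3), factor(b, levels = 0:3))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("weighted kappa penalizes near-misses less than far misses", {
  a <- rep(0:3, each = 25)
  near <- pmin(a + 1, 3)
  far <- (a + 3) %% 4
  expect_gt(cohen_kappa(a, near, weighted = TRUE),
            cohen_kappa(a, far, weighted = TRUE))
})

test_that("AUC matches pair enumeration, the tie rule, and pROC", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  set.seed(43)
  sc <- round(rnorm(60), 1)  # ties likely
  lb <- runif(60) < 0.4
  got <- roc_auc(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("AUC(scores) + AUC(-scores) = 1 and the curve spans (0,0) to (1,1)", {
  set.seed(44)
  sc <- rnorm(40); lb <- runif(40) < 0.5
  r <- roc_auc(sc, lb)
  expect_equal(r$auc + roc_auc(-sc, lb)$auc, 1, tolerance = 1e-12)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  expect_error(roc_auc(sc, rep(TRUE, 40)), "both classes")
})

test_that("dichotomization rules orient scores so informative predictors give AUC > 0.5", {
  truth <- c(120, 150, 180, 250, 300, 400)
  pred <- truth + rnorm(6, 0, 5)
  d <- dichotomize(truth, pred, "pf_ratio")
  expect_equal(d$labels, truth < 200)
  expect_gt(roc_auc(d$scores, d$labels)$auc, 0.9)
  d2 <- dichotomize(c(50, 100, 200, 250), c(50, 100, 200, 250), "aa_gradient")
  expect_equal(d2$labels, c(FALSE, FALSE, TRUE, TRUE))
})
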