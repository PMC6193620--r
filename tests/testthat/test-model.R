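# SVR severity model: standardization, LOPO CV, group analysis, PCA sweep.

# Small frame-level feature set with a known signal: feature 1 equals the
# patient's target, the rest are noise.
make_signal_features <- function(n_patients = 10, frames_each = 3, p = 6,
                                 seed = 1, noise = 0) {
  set.seed(seed)
  ids <- rep(sprintf("P%02d", seq_len(n_patients)), each = frames_each)
  targets <- setNames(seq(100, 400, length.out = n_patients),
                      sprintf("P%02d", seq_len(n_patients)))
  x <- matrix(rnorm(length(ids) * p), ncol = p)
  x[, 1] <- targets[ids] / 100 + rnorm(length(ids), 0, noise)
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, ids = ids, targets = targets)
}

test_that("standardization centers and scales on the training fold only", {
  set.seed(51)
  tr <- matrix(rnorm(200, 5, 3), ncol = 4)
  z <- standardize(tr)
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 4), tolerance = 1e-12)

  tr2 <- cbind(tr, 7)  # constant feature
  z2 <- standardize(tr2)
  expect_true(all(z2[, 5] == 0))

  held <- matrix(colMeans(tr), 1)  # row equal to the training mean
  expect_equal(as.numeric(standardize(tr, held)), rep(0, 4), tolerance = 1e-12)
})

test_that("LOPO produces one prediction per patient and needs 3+ patients", {
  d <- make_signal_features(n_patients = 3)
  cv <- lopo_cv(d$x, d$ids, d$targets)
  expect_equal(nrow(cv), 3)
  expect_setequal(cv$patient_id, unique(d$ids))

  d2 <- make_signal_features(n_patients = 2)
  expect_error(lopo_cv(d2$x, d2$ids, d2$targets), "at least 3")

  bad <- d$x; bad[4, 2] <- NaN
  expect_error(lopo_cv(bad, d$ids, d$targets), "row\\(s\\): 4")
})

test_that("a constant target is predicted as that constant within epsilon", {
  d <- make_signal_features(n_patients = 5, seed = 2)
  const <- setNames(rep(250, 5), names(d$targets))
  cv <- lopo_cv(d$x, d$ids, const)
  expect_true(all(abs(cv$prediction - 250) <= 0.11))  # epsilon fallback 0.1
})

test_that("LOPO recovers the target when a feature encodes it noise-free", {
  # duplicated endpoint targets keep every held-out patient inside the
  # training range (an RBF regressor cannot extrapolate beyond it)
  tg <- c(100, 100, seq(100, 400, length.out = 10), 400, 400)
  ids <- rep(sprintf("P%02d", seq_along(tg)), each = 3)
  targets <- setNames(tg, sprintf("P%02d", seq_along(tg)))
  x <- matrix(targets[ids] / 100, ncol = 1)
  cv <- lopo_cv(x, ids, targets)
  expect_true(all(abs(cv$prediction - cv$truth) <= 0.15 * sd(targets)))
})

test_that("LOPO is deterministic for a fixed input", {
  d <- make_signal_features(seed = 4)
  expect_identical(lopo_cv(d$x, d$ids, d$targets),
                   lopo_cv(d$x, d$ids, d$targets))
})

test_that("shuffling patient targets destroys the AUC (no leakage)", {
  # needs a reasonably large cohort: leave-one-out predictions carry a
  # small O(1/n) anti-correlation with the held-out value even under the null
  d <- make_signal_features(n_patients = 40, frames_each = 2, seed = 10)
  aucs <- sapply(1:20, function(i) {
    set.seed(500 + i)
    perm <- setNames(sample(d$targets), names(d$targets))
    cv <- lopo_cv(d$x, d$ids, perm)
    di <- dichotomize(cv$truth, cv$prediction, "pf_ratio", cutoff = 250)
    roc_auc(di$scores, di$labels)$auc
  })
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("group analysis restricts to the right columns and returns the table shape", {
  d <- make_signal_features(n_patients = 6, frames_each = 2, seed = 6, p = 44)
  fv_names <- names(feature_vector(matrix(sample(0:255, 400, TRUE), 20, 20)))
  colnames(d$x) <- fv_names
  tab <- group_analysis(d$x, d$ids, d$targets, "pf_ratio",
                        groups = c("all", "1", "2", "3"), cutoff = 250)
  expect_equal(tab$group, c("all", "1", "2", "3"))
  expect_equal(tab$n_features, c(44L, 20L, 14L, 10L))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_error(group_analysis(d$x, d$ids, d$targets, "pf_ratio", groups = "9"),
               "unknown feature group")
})

test_that("PCA sweep: full basis explains everything, variances nonincreasing", {
  d <- make_signal_features(n_patients = 6, frames_each = 2, p = 8, seed = 7)
  sw <- pca_sweep(d$x, d$ids, d$targets, "pf_ratio", k_range = NULL)
  expect_equal(sum(sw$var_frac), 1, tolerance = 1e-12)
  expect_equal(sw$cum_var[length(sw$cum_var)], 1, tolerance = 1e-12)
  expect_true(all(diff(sw$var_frac) <= 1e-12))
  expect_error(pca_sweep(d$x, d$ids, d$targets, k_range = 1:9), "k_range")
})

test_that("three latent factors concentrate the variance in three components", {
  set.seed(8)
  n <- 90
  z <- matrix(rnorm(n * 3), n, 3)
  w <- matrix(rnorm(3 * 20), 3, 20)
  x <- z %*% w + matrix(rnorm(n * 20, 0, 0.05), n, 20)
  ids <- rep(sprintf("P%02d", 1:30), each = 3)
  targets <- setNames(tapply(200 + 80 * z[, 1], ids, mean)[sprintf("P%02d", 1:30)],
                      sprintf("P%02d", 1:30))
  sw <- pca_sweep(x, ids, targets, "pf_ratio", k_range = NULL)
  expect_gte(sw$cum_var[3], 0.9)
})
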