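# GLCM computation and the 22 textural features.

stripe_image <- function() {
  # 4x4, rows all [0, 0, 255, 255]: two gray levels at L = 2
  matrix(rep(c(0, 0, 255, 255), 4), 4, 4, byrow = TRUE)
}

test_that("GLCM matches hand-computed P matrices on the two-level stripe image", {
  img <- stripe_image()
  gh <- compute_glcm(img, offset = c(0, 2), levels = 2)
  expect_equal(gh$P, matrix(c(0, 0, 1, 0), 2, 2))  # all 8 pairs are (0, 1)
  gv <- compute_glcm(img, offset = c(2, 0), levels = 2)
  expect_equal(gv$P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(gh$counts), 8)
})

test_that("a constant image concentrates the GLCM in a single entry", {
  g <- compute_glcm(matrix(77L, 6, 6), offset = c(0, 2), levels = 256)
  expect_equal(sum(g$P), 1)
  expect_equal(max(g$P), 1)
  expect_equal(which(g$P == 1), which(g$P > 0))
})

test_that("marginal statistics of the hand examples are exact", {
  img <- stripe_image()
  mh <- marginal_statistics(compute_glcm(img, offset = c(0, 2), levels = 2))
  expect_equal(mh$p_x, c(1, 0))
  expect_equal(mh$p_y, c(0, 1))
  expect_equal(mh$mu_x, 0); expect_equal(mh$mu_y, 1)
  expect_equal(mh$sigma_x, 0)

  mv <- marginal_statistics(compute_glcm(img, offset = c(2, 0), levels = 2))
  expect_equal(mv$mu_x, 0.5); expect_equal(mv$mu_y, 0.5)
  expect_equal(mv$sigma_x, 0.5); expect_equal(mv$sigma_y, 0.5)
  expect_equal(sum(mv$sum_dist), 1)
  expect_equal(sum(mv$diff_dist), 1)
  expect_equal(unname(mv$sum_dist[c("0", "2")]), c(0.5, 0.5))
})

test_that("classical features match hand arithmetic on 2x2 distributions", {
  img <- stripe_image()
  fh <- classical_features(compute_glcm(img, offset = c(0, 2), levels = 2))
  expect_equal(unname(fh[c("A", "H", "CO2", "D", "M", "HO")]),
               c(1, 0, 1, 1, 1, 0.5))
  fv <- classical_features(compute_glcm(img, offset = c(2, 0), levels = 2))
  expect_equal(unname(fv["H"]), log(2), tolerance = 1e-12)
  expect_equal(unname(fv[c("A", "CO2", "D", "HO", "M", "AC")]),
               c(0.5, 0, 0, 1, 0.5, 0.5))
})

test_that("sum/difference features match hand arithmetic", {
  img <- stripe_image()
  sv <- sum_difference_features(compute_glcm(img, offset = c(2, 0), levels = 2))
  expect_equal(unname(sv[c("CO1", "DH", "DV", "SA")]), c(0, 0, 0, 1))
  expect_equal(unname(sv["SH"]), log(2), tolerance = 1e-12)
  sh <- sum_difference_features(compute_glcm(img, offset = c(0, 2), levels = 2))
  expect_equal(unname(sh[c("CO1", "DH", "INV")]), c(1, 0, 0.5))
})

test_that("correlation features: perfect diagonal dependence gives C1 = C2 = 1", {
  img <- stripe_image()
  cf <- correlation_features(compute_glcm(img, offset = c(2, 0), levels = 2))
  expect_equal(unname(cf["C1"]), 1)
  expect_equal(unname(cf["C2"]), 1)
})

test_that("degenerate constant image fires the documented conventions", {
  g <- compute_glcm(matrix(10L, 6, 6), offset = c(0, 2), levels = 256)
  cf <- correlation_features(g)
  expect_equal(unname(cf[c("C1", "C2", "IC2")]), c(0, 0, 0))
  expect_true("zero_marginal_sd" %in% attr(cf, "conventions"))
  fv <- feature_vector(matrix(10L, 12, 12))
  expect_equal(unname(fv[c("H_h", "SH_h", "DH_h", "H_v")]), rep(0, 4))
  expect_equal(unname(fv[c("A_h", "A_v", "M_h")]), rep(1, 3))
})

test_that("every feature matches the brute-force oracle on random images", {
  for (s in 1:10) {
    img <- random_image(8, seed = s)
    for (off in list(c(0, 2), c(2, 0), c(1, 1))) {
      got <- pkg_features(img, off, 8)
      want <- oracle_features(oracle_glcm(img, off, 8))
      expect_equal(got, want, tolerance = 1e-10,
                   info = sprintf("seed %d offset (%d,%d)", s, off[1], off[2]))
    }
  }
})

test_that("duplicate-formula identities CO1 = CO2 and C1 = C2 hold", {
  for (s in 1:20) {
    img <- random_image(10, seed = 100 + s)
    g <- compute_glcm(img, offset = c(0, 2), levels = 16)
    m <- marginal_statistics(g)
    cl <- classical_features(g, m)
    sd_ <- sum_difference_features(g, m)
    co <- correlation_features(g, m)
    expect_equal(unname(sd_["CO1"]), unname(cl["CO2"]), tolerance = 1e-10)
    expect_equal(unname(co["C1"]), unname(co["C2"]), tolerance = 1e-10)
  }
})

test_that("left-right reflection transposes the horizontal GLCM and fixes symmetric features", {
  img <- random_image(12, seed = 7)
  flipped <- img[, ncol(img):1]
  g1 <- compute_glcm(img, offset = c(0, 2), levels = 8)
  g2 <- compute_glcm(flipped, offset = c(0, 2), levels = 8)
  expect_equal(g2$P, t(g1$P), tolerance = 1e-12)
  f1 <- classical_features(g1); f2 <- classical_features(g2)
  sym <- c("CO2", "D", "HO", "A", "H", "M")
  expect_equal(f1[sym], f2[sym], tolerance = 1e-10)
})

test_that("feature bounds hold on random GLCMs", {
  for (s in 1:10) {
    img <- random_image(10, seed = 200 + s)
    g <- compute_glcm(img, offset = c(0, 2), levels = 8)
    m <- marginal_statistics(g)
    cl <- classical_features(g, m)
    co <- correlation_features(g, m)
    expect_gte(cl[["A"]], 0); expect_lte(cl[["A"]], 1)
    expect_gte(cl[["H"]], 0)
    expect_lte(abs(co[["C1"]]), 1 + 1e-12)
    expect_equal(sum(g$P), 1, tolerance = 1e-12)
  }
})

test_that("the 44-vector has the documented length, names and group sizes", {
  img <- random_image(20, seed = 3)
  fv <- feature_vector(img)
  expect_length(fv, 44)
  expect_true(all(grepl("_(h|v)$", names(fv))))
  expect_true(all(is.finite(fv)))
  groups <- glcm_feature_groups()
  expect_equal(lengths(groups), c(`1` = 10L, `2` = 7L, `3` = 5L))
  expect_length(feature_group_columns(names(fv), "all"), 44)
  expect_length(feature_group_columns(names(fv), "2"), 14)
  # horizontal block first, in group order
  expect_equal(names(fv)[1:3], c("H_h", "HO_h", "D_h"))
  expect_equal(names(fv)[23:24], c("H_v", "HO_v"))
})

test_that("anisotropy shows up in the right direction", {
  # horizontal stripes (rows alternate dark/bright): vertical pairs cross
  # stripes, horizontal pairs stay within one
  img <- matrix(rep(c(0, 0, 255, 255), 4), 16, 16)  # column vector recycled
  fv <- feature_vector(img, levels = 8)
  expect_gt(fv[["CO2_v"]], fv[["CO2_h"]])
})

test_that("degenerate inputs raise errors", {
  expect_error(compute_glcm(matrix(0L, 1, 1), offset = c(0, 2)), "no valid pixel pairs")
  expect_error(compute_glcm(matrix(0L, 4, 4), offset = c(0, 2), levels = 7), "divide")
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  expect_error(compute_glcm(matrix(0L, 4, 4), mask = m, offset = c(0, 2)),
               "degenerate GLCM")
})
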