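# Gray-Level Co-occurrence Matrix (GLCM) and the 22 textural features,
# computed along horizontal and vertical 2-pixel offsets to form the
# 44-dimensional per-frame feature vector.
#
# Conventions used throughout:
#   * gray levels are the quantized values 0..L-1; sums over (i, j) use
#     these values directly;
#   * the GLCM is ordered (non-symmetric): each pixel pair (p, p + offset)
#     is counted once;
#   * all entropies use the natural logarithm with 0 * log 0 = 0;
#   * degenerate cases (zero marginal SD, negative information-correlation
#     radicand, single-level ROI) map to finite values by documented rules,
#     recorded in the "conventions" attribute of the feature vector.

#' Compute a gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(p, p + offset)` whose both members fall
#' inside the mask (or anywhere in the frame when `mask` is `NULL`), after
#' quantizing gray values to `levels` gray levels by
#' `level = floor(gray * levels / 256)`.
#'
#' @param frame an [lus_frame()] or integer pixel matrix (values 0..255)
#' @param mask optional [build_roi()] result or logical matrix
#' @param offset integer `c(drow, dcol)` displacement; the defaults used by
#'   the pipeline are `c(0, 2)` (horizontal) and `c(2, 0)` (vertical)
#' @param levels number of gray levels L; must divide 256
#' @return object of class `glcm`: `P` (L x L probability matrix, rows =
#'   first pixel's level), `counts`, `levels`, `offset`
#' @export
compute_glcm <- function(frame, mask = NULL, offset = c(0, 2), levels = 256) {
  px <- frame_pixels(frame)
  stop_if_not(length(offset) == 2 && all(offset == round(offset)),
              "offset must be two integers")
  stop_if_not(is_count(levels) && 256 %% levels == 0, "levels must divide 256")
  L <- as.integer(levels)
  q <- matrix(as.integer(px) %/% (256L %/% L), nrow(px), ncol(px))

  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r0) < 1 || length(c0) < 1 || min(nr, nr - dr) < max(1L, 1L - dr) ||
      min(nc, nc - dc) < max(1L, 1L - dc))
    stop("offset larger than frame: no valid pixel pairs", call. = FALSE)
  src <- q[r0, c0, drop = FALSE]
  dst <- q[r0 + dr, c0 + dc, drop = FALSE]

  if (!is.null(mask)) {
    m <- if (inherits(mask, "roi_mask")) mask$mask else mask
    stop_if_not(is.logical(m) && identical(dim(m), dim(px)),
                "mask shape must equal frame shape")
    keep <- m[r0, c0, drop = FALSE] & m[r0 + dr, c0 + dc, drop = FALSE]
    src <- src[keep]; dst <- dst[keep]
  }
  if (length(src) < 1)
    stop("degenerate GLCM: no valid pixel pairs inside the mask", call. = FALSE)

  counts <- matrix(tabulate(as.numeric(src) * L + dst + 1, nbins = L * L),
                   L, L, byrow = TRUE)
  structure(list(P = counts / sum(counts), counts = counts, levels = L,
                 offset = c(dr, dc)),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> L = %d, offset (%d, %d), %d pairs\n",
              x$levels, x$offset[1], x$offset[2], sum(x$counts)))
  invisible(x)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Marginal statistics of a GLCM
#'
#' Row and column marginals, gray-level sum and difference distributions,
#' their moments, and the entropies feeding the information measures of
#' correlation. Gray levels are the quantized values `0..L-1`; the sum
#' distribution lives on `n = 0..2L-2`, the difference distribution on
#' `n = |i - j| = 0..L-1`.
#'
#' @param glcm a [compute_glcm()] result
#' @return object of class `glcm_marginals`
#' @export
marginal_statistics <- function(glcm) {
  stop_if_not(inherits(glcm, "glcm"), "expected a glcm object")
  P <- glcm$P; L <- glcm$levels
  lv <- 0:(L - 1)
  p_x <- rowSums(P); p_y <- colSums(P)
  mu_x <- sum(lv * p_x); mu_y <- sum(lv * p_y)
  sigma_x <- sqrt(sum((lv - mu_x)^2 * p_x))
  sigma_y <- sqrt(sum((lv - mu_y)^2 * p_y))

  I <- matrix(lv, L, L, byrow = FALSE)  # first pixel's level, constant by row
  J <- matrix(lv, L, L, byrow = TRUE)
  sum_dist <- as.numeric(tapply(as.vector(P), as.vector(I + J), sum))
  diff_dist <- as.numeric(tapply(as.vector(P), as.vector(abs(I - J)), sum))
  names(sum_dist) <- 0:(2 * L - 2)
  names(diff_dist) <- lv

  pxpy <- outer(p_x, p_y)
  pos <- P > 0  # P > 0 implies both marginals > 0
  structure(list(
    levels = L, p_x = p_x, p_y = p_y,
    mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
    mu = sum(I * P),  # mean gray level under P (used by the variance feature)
    sum_dist = sum_dist, diff_dist = diff_dist,
    HX = entropy_nat(p_x), HY = entropy_nat(p_y),
    H1XY = -sum(P[pos] * log(pxpy[pos])),
    H2XY = entropy_nat(pxpy)
  ), class = "glcm_marginals")
}

# Index matrices of a glcm: first pixel's level varies by row.
glcm_IJ <- function(L) {
  lv <- 0:(L - 1)
  list(I = matrix(lv, L, L, byrow = FALSE), J = matrix(lv, L, L, byrow = TRUE))
}

#' Classical GLCM texture descriptors (group 1)
#'
#' Entropy `H = -sum P log P`; homogeneity `HO = sum P / (1 + (i-j)^2)`;
#' dissimilarity `D = sum |i-j| P`; cluster shade `CS` and prominence `CP`
#' (third/fourth moments of `i + j - mu_x - mu_y`); autocorrelation
#' `AC = sum i j P`; contrast `CO2 = sum (i-j)^2 P`; energy `A = sum P^2`;
#' variance `V = sum (i - mu)^2 P` with `mu` the mean gray level under `P`;
#' maximum probability `M = max P`.
#'
#' @param glcm a [compute_glcm()] result
#' @param marg its [marginal_statistics()]; computed if missing
#' @return named numeric vector of the 10 features
#' @export
classical_features <- function(glcm, marg = marginal_statistics(glcm)) {
  P <- glcm$P
  ij <- glcm_IJ(glcm$levels); I <- ij$I; J <- ij$J
  dev <- I + J - marg$mu_x - marg$mu_y
  c(H = entropy_nat(P),
    HO = sum(P / (1 + (I - J)^2)),
    D = sum(abs(I - J) * P),
    CS = sum(dev^3 * P),
    CP = sum(dev^4 * P),
    AC = sum(I * J * P),
    CO2 = sum((I - J)^2 * P),
    A = sum(P^2),
    V = sum((I - marg$mu)^2 * P),
    M = max(P))
}

#' Sum/difference GLCM features (group 2)
#'
#' Features of the distributions of the sum `i + j` and absolute difference
#' `|i - j|` of co-occurring gray levels: inverse difference `INV`, contrast
#' `CO1` (second moment of the difference distribution; algebraically equal
#' to `CO2`), sum average `SA`, sum entropy `SH`, difference entropy `DH`,
#' sum variance `SV = sum (n - SH)^2 s_n` (the sum entropy appears inside
#' the square), difference variance `DV` (variance of `n` under the
#' difference distribution).
#'
#' @inheritParams classical_features
#' @return named numeric vector of the 7 features
#' @export
sum_difference_features <- function(glcm, marg = marginal_statistics(glcm)) {
  P <- glcm$P
  ij <- glcm_IJ(glcm$levels)
  s <- marg$sum_dist; d <- marg$diff_dist
  ns <- as.numeric(names(s)); nd <- as.numeric(names(d))
  SH <- entropy_nat(s)
  c(INV = sum(P / (1 + abs(ij$I - ij$J))),
    CO1 = sum(nd^2 * d),
    SA = sum(ns * s),
    SH = SH,
    DH = entropy_nat(d),
    SV = sum((ns - SH)^2 * s),
    DV = sum(nd^2 * d) - sum(nd * d)^2)
}

#' Correlation-based GLCM features (group 3)
#'
#' `C1` and `C2` are the two printed forms of the gray-level correlation
#' (algebraically identical); `MCC` is the second eigenvalue (by modulus) of
#' the transition-like matrix `Q_ij = sum_k P_ik P_jk / (p_x(i) p_y(k))`,
#' with zero-marginal levels skipped; `IC1` and `IC2` are the information
#' measures of correlation. Degenerate conventions: zero marginal SD gives
#' `C1 = C2 = 0`; fewer than two occupied levels give `MCC = 0`; a zero
#' entropy denominator gives `IC1 = 0`; a negative radicand in `IC2` is
#' clamped to 0. Fired conventions are listed in the `"conventions"`
#' attribute.
#'
#' @inheritParams classical_features
#' @return named numeric vector of the 5 features
#' @export
correlation_features <- function(glcm, marg = marginal_statistics(glcm)) {
  P <- glcm$P; L <- glcm$levels
  ij <- glcm_IJ(L); I <- ij$I; J <- ij$J
  conv <- character(0)

  ss <- marg$sigma_x * marg$sigma_y
  if (ss > 0) {
    C1 <- sum((I - marg$mu_x) * (J - marg$mu_y) * P) / ss
    C2 <- (sum(I * J * P) - marg$mu_x * marg$mu_y) / ss
  } else {
    C1 <- C2 <- 0
    conv <- c(conv, "zero_marginal_sd")
  }

  rows <- which(marg$p_x > 0); kcols <- which(marg$p_y > 0)
  if (length(rows) >= 2 && length(kcols) >= 1) {
    A <- P[rows, kcols, drop = FALSE] / marg$p_x[rows]
    B <- sweep(P[rows, kcols, drop = FALSE], 2, marg$p_y[kcols], "/")
    ev <- eigen(A %*% t(B), only.values = TRUE)$values
    ev <- ev[order(Mod(ev), decreasing = TRUE)]
    MCC <- Re(ev[2])
  } else {
    MCC <- 0
    conv <- c(conv, "mcc_single_level")
  }

  H <- entropy_nat(P)
  denom <- max(marg$HX, marg$HY)
  IC1 <- if (denom > 0) (H - marg$H1XY) / denom else { conv <- c(conv, "ic1_zero_entropy"); 0 }
  rad <- 1 - exp(-2 * (marg$H2XY - H))
  if (rad < 0) conv <- c(conv, "ic2_clamped")
  IC2 <- sqrt(max(0, rad))

  structure(c(C1 = C1, C2 = C2, MCC = MCC, IC1 = IC1, IC2 = IC2),
            conventions = conv)
}

#' Feature groups of the 22 GLCM descriptors
#'
#' Group 1 holds the 10 classical descriptors, group 2 the 7 sum/difference
#' features, group 3 the 5 correlation-based features.
#'
#' @return named list of character vectors of feature names
#' @export
glcm_feature_groups <- function() {
  list(`1` = c("H", "HO", "D", "CS", "CP", "AC", "CO2", "A", "V", "M"),
       `2` = c("INV", "CO1", "SA", "SH", "DH", "SV", "DV"),
       `3` = c("C1", "C2", "MCC", "IC1", "IC2"))
}

#' Per-frame 44-dimensional texture feature vector
#'
#' Computes the GLCM at the horizontal offset `(0, +distance)` and the
#' vertical offset `(+distance, 0)` and evaluates all 22 features for each,
#' concatenated in a fixed order: horizontal direction first, groups 1, 2, 3
#' within each direction. Names carry a `_h` / `_v` suffix.
#'
#' @param frame an [lus_frame()] or pixel matrix
#' @param mask optional ROI mask restricting counted pairs
#' @param levels gray levels L for quantization (default 256: native 8-bit)
#' @param distance pixel offset distance (default 2)
#' @return named numeric vector of length 44; attribute `"conventions"`
#'   lists any degenerate-case rules that fired
#' @export
feature_vector <- function(frame, mask = NULL, levels = 256, distance = 2) {
  dirs <- list(h = c(0, distance), v = c(distance, 0))
  conv <- character(0)
  out <- lapply(names(dirs), function(dn) {
    g <- compute_glcm(frame, mask, offset = dirs[[dn]], levels = levels)
    m <- marginal_statistics(g)
    cf <- correlation_features(g, m)
    conv <<- c(conv, paste0(dn, ":", attr(cf, "conventions")))
    v <- c(classical_features(g, m), sum_difference_features(g, m), cf)
    names(v) <- paste0(names(v), "_", dn)
    v
  })
  structure(unlist(out), conventions = conv[nzchar(sub("^.:", "", conv))])
}

#' Column indices of a feature group inside the 44-vector
#'
#' @param feature_names names of the 44-vector (as from [feature_vector()])
#' @param group `"all"`, `"1"`, `"2"` or `"3"`
#' @return integer vector of column positions (both directions)
#' @export
feature_group_columns <- function(feature_names, group = "all") {
  group <- as.character(group)
  if (group == "all") return(seq_along(feature_names))
  groups <- glcm_feature_groups()
  stop_if_not(group %in% names(groups), "unknown feature group: ", group)
  base <- sub("_[hv]$", "", feature_names)
  which(base %in% groups[[group]])
}
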