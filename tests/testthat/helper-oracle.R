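# Independent brute-force reference for the GLCM and its 22 textural
# features. Written as literal double loops over gray-level pairs, with no
# code shared with the package implementation, so it can serve as an
# oracle.

oracle_glcm <- function(img, offset, L) {
  q <- floor(img * L / 256)
  counts <- matrix(0, L, L)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        i <- q[r, c]; j <- q[r2, c2]
        counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# All 22 features from a probability matrix P, by direct summation.
oracle_features <- function(P) {
  L <- nrow(P)
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  lv <- 0:(L - 1)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sx <- sqrt(sum((lv - mux)^2 * px)); sy <- sqrt(sum((lv - muy)^2 * py))

  H <- INV <- HO <- D <- CS <- CP <- AC <- CO2 <- A <- V <- M <- 0
  mu <- 0
  for (i in 1:L) for (j in 1:L) mu <- mu + (i - 1) * P[i, j]
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]; ii <- i - 1; jj <- j - 1
    if (p > 0) H <- H - p * log(p)
    INV <- INV + p / (1 + abs(ii - jj))
    HO <- HO + p / (1 + (ii - jj)^2)
    D <- D + abs(ii - jj) * p
    CS <- CS + (ii + jj - mux - muy)^3 * p
    CP <- CP + (ii + jj - mux - muy)^4 * p
    AC <- AC + ii * jj * p
    CO2 <- CO2 + (ii - jj)^2 * p
    A <- A + p^2
    V <- V + (ii - mu)^2 * p
    if (p > M) M <- p
  }

  # sum / difference distributions
  s <- numeric(2 * L - 1)  # n = 0 .. 2L-2
  d <- numeric(L)          # n = 0 .. L-1
  for (i in 1:L) for (j in 1:L) {
    s[(i - 1) + (j - 1) + 1] <- s[(i - 1) + (j - 1) + 1] + P[i, j]
    d[abs(i - j) + 1] <- d[abs(i - j) + 1] + P[i, j]
  }
  CO1 <- sum((0:(L - 1))^2 * d)
  SA <- sum((0:(2 * L - 2)) * s)
  SH <- 0; for (v in s) if (v > 0) SH <- SH - v * log(v)
  DH <- 0; for (v in d) if (v > 0) DH <- DH - v * log(v)
  SV <- sum(((0:(2 * L - 2)) - SH)^2 * s)
  DV <- sum((0:(L - 1))^2 * d) - sum((0:(L - 1)) * d)^2

  if (sx * sy > 0) {
    C1 <- 0
    for (i in 1:L) for (j in 1:L)
      C1 <- C1 + (i - 1 - mux) * (j - 1 - muy) * P[i, j]
    C1 <- C1 / (sx * sy)
    C2 <- (AC - mux * muy) / (sx * sy)
  } else C1 <- C2 <- 0

  keep_i <- which(px > 0); keep_k <- which(py > 0)
  if (length(keep_i) >= 2) {
    Q <- matrix(0, length(keep_i), length(keep_i))
    for (a in seq_along(keep_i)) for (b in seq_along(keep_i)) {
      i <- keep_i[a]; j <- keep_i[b]
      acc <- 0
      for (k in keep_k) acc <- acc + P[i, k] * P[j, k] / (px[i] * py[k])
      Q[a, b] <- acc
    }
    ev <- eigen(Q, only.values = TRUE)$values
    ev <- ev[order(Mod(ev), decreasing = TRUE)]
    MCC <- Re(ev[2])
  } else MCC <- 0

  HX <- 0; for (v in px) if (v > 0) HX <- HX - v * log(v)
  HY <- 0; for (v in py) if (v > 0) HY <- HY - v * log(v)
  H1 <- 0; H2 <- 0
  for (i in 1:L) for (j in 1:L) {
    pp <- px[i] * py[j]
    if (P[i, j] > 0) H1 <- H1 - P[i, j] * log(pp)
    if (pp > 0) H2 <- H2 - pp * log(pp)
  }
  IC1 <- if (max(HX, HY) > 0) (H - H1) / max(HX, HY) else 0
  IC2 <- sqrt(max(0, 1 - exp(-2 * (H2 - H))))

  c(H = H, HO = HO, D = D, CS = CS, CP = CP, AC = AC, CO2 = CO2, A = A,
    V = V, M = M,
    INV = INV, CO1 = CO1, SA = SA, SH = SH, DH = DH, SV = SV, DV = DV,
    C1 = C1, C2 = C2, MCC = MCC, IC1 = IC1, IC2 = IC2)
}

# Package-side 22-feature vector from an image, for comparison with the
# oracle (single direction).
pkg_features <- function(img, offset, L) {
  g <- compute_glcm(img, offset = offset, levels = L)
  m <- marginal_statistics(g)
  v <- c(classical_features(g, m), sum_difference_features(g, m),
         correlation_features(g, m))
  attributes(v) <- list(names = names(v))
  v
}

random_image <- function(n = 8, seed = 1) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}
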