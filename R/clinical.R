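# Oxygenation indices, visual scoring, and the evaluation statistics:
# Spearman correlation with Fisher-z confidence interval, Cohen's kappa,
# ROC/AUC by the Mann-Whitney pair-counting estimator.

#' Oxygenation ratio PaO2/FiO2
#'
#' @param pao2 arterial oxygen partial pressure, mmHg
#' @param fio2 inspired oxygen fraction in (0, 1]
#' @return PaO2/FiO2 in mmHg
#' @export
pf_ratio <- function(pao2, fio2) {
  stop_if_not(all(fio2 > 0 & fio2 <= 1), "fio2 must lie in (0, 1]")
  stop_if_not(all(pao2 > 0), "pao2 must be positive")
  pao2 / fio2
}

#' Alveolar-arterial oxygen gradient
#'
#' `A-a = PA - PaO2` with the alveolar partial pressure
#' `PA = FiO2 * (760 - 47) - PaCO2 / 0.8` (sea-level barometric pressure
#' minus water vapor pressure; respiratory quotient 0.8). The gradient may
#' be negative for extreme inputs and is returned as-is.
#'
#' @param fio2 inspired oxygen fraction in (0, 1]
#' @param pao2 arterial oxygen partial pressure, mmHg
#' @param paco2 arterial carbon dioxide partial pressure, mmHg
#' @return A-a gradient in mmHg
#' @export
aa_gradient <- function(fio2, pao2, paco2) {
  stop_if_not(all(fio2 > 0 & fio2 <= 1), "fio2 must lie in (0, 1]")
  stop_if_not(all(pao2 > 0) && all(paco2 > 0), "pao2 and paco2 must be positive")
  fio2 * (760 - 47) - paco2 / 0.8 - pao2
}

#' Per-patient visual score sum
#'
#' Each of the standard views receives a 0-3 severity grade; their sum
#' (0-24 for eight views) is the patient's visual lung ultrasound score.
#'
#' @param grades integer vector of per-frame grades in 0..3
#' @param views_per_patient required number of grades (default 8)
#' @return integer sum
#' @export
visual_score_sum <- function(grades, views_per_patient = 8) {
  stop_if_not(length(grades) == views_per_patient,
              "expected ", views_per_patient, " grades, got ", length(grades))
  stop_if_not(all(grades %in% 0:3), "grades must be integers in 0..3")
  sum(as.integer(grades))
}

#' Spearman rank correlation with confidence interval
#'
#' Rho uses average ranks for ties; the two-sided p value comes from the
#' t approximation (via [stats::cor.test()]); the confidence interval from
#' the Fisher z transform of rho with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y numeric vectors of equal length >= 4
#' @param conf_level confidence level (default 0.95)
#' @return list with `rho`, `ci` (length-2 vector), `p`, `n`
#' @export
spearman_ci <- function(x, y, conf_level = 0.95) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  stop_if_not(length(x) >= 4, "need at least 4 observations")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "Spearman correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  z <- atanh(clip(rho, -1 + 1e-15, 1 - 1e-15))
  se <- 1 / sqrt(length(x) - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rho = rho, ci = tanh(c(z - q * se, z + q * se)), p = ct$p.value,
       n = length(x))
}

#' Cohen's kappa between two raters
#'
#' Unweighted by default: `kappa = (p_o - p_e) / (1 - p_e)` over the
#' confusion table of the two raters' categorical grades. Linear weights
#' are available behind the `weighted` flag. When both raters are constant
#' and identical (expected agreement 1), kappa is defined as 1.
#'
#' @param rater1,rater2 equal-length vectors of grades
#' @param categories the category set (default grades 0..3)
#' @param weighted use linear disagreement weights?
#' @return kappa in \code{[-1, 1]}
#' @export
cohen_kappa <- function(rater1, rater2, categories = 0:3, weighted = FALSE) {
  stop_if_not(length(rater1) == length(rater2), "rater vectors must have equal length")
  stop_if_not(length(rater1) > 0, "empty rater vectors")
  stop_if_not(all(rater1 %in% categories) && all(rater2 %in% categories),
              "grades outside the category set")
  f1 <- factor(rater1, levels = categories)
  f2 <- factor(rater2, levels = categories)
  tab <- table(f1, f2) / length(rater1)
  k <- length(categories)
  w <- if (weighted) 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  else diag(k)
  p_o <- sum(w * tab)
  p_e <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (1 - p_e < .Machine$double.eps) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney pair-counting estimator (ties count one half),
#' equivalently the rank-sum formula; the curve is swept over all score
#' thresholds. Higher scores are taken to indicate the positive class, so
#' scores for "lower is worse" indices (e.g. predicted PaO2/FiO2 against
#' the < 200 rule) should be negated by the caller; [dichotomize()] and the
#' pipeline handle this orientation.
#'
#' @param scores numeric scores
#' @param labels logical (or 0/1) vector, `TRUE` = positive class
#' @return list with `auc` and `curve` (data frame of `threshold`, `fpr`,
#'   `tpr`)
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stop_if_not(length(scores) == length(labels), "scores and labels must match")
  stop_if_not(any(labels) && any(!labels), "both classes must be present")
  stop_if_not(all(is.finite(scores)), "non-finite scores")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[!labels] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(scores[labels] >= t), numeric(1))
  )
  list(auc = auc, curve = curve)
}

#' Dichotomize an oxygenation index for ROC analysis
#'
#' The positive class is "worse respiratory status": PaO2/FiO2 below 200,
#' or A-a gradient above 150. Returns the labels together with scores
#' oriented so that higher score predicts the positive class (predictions
#' of PaO2/FiO2 are negated).
#'
#' @param values true index values
#' @param scores raw scores (e.g. LOPO predictions of the index)
#' @param index `"pf_ratio"` or `"aa_gradient"`
#' @param cutoff dichotomization cutoff; defaults 200 (pf) / 150 (A-a)
#' @return list with `labels` (logical) and `scores` (oriented)
#' @export
dichotomize <- function(values, scores, index = c("pf_ratio", "aa_gradient"),
                        cutoff = NULL) {
  index <- match.arg(index)
  if (is.null(cutoff)) cutoff <- if (index == "pf_ratio") 200 else 150
  if (index == "pf_ratio") list(labels = values < cutoff, scores = -scores)
  else list(labels = values > cutoff, scores = scores)
}
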