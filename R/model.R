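# Support vector regression of oxygenation indices from texture features,
# with leave-one-patient-out cross-validation (LOPO), feature-group
# restriction, and principal-component feature reduction. Training always
# happens at frame level (every frame inherits its patient's index as
# target); per-patient predictions are the mean over that patient's frames.

#' Z-score features using training-set statistics
#'
#' @param train numeric matrix whose column means/SDs define the scaling
#' @param apply_to matrix to transform (defaults to `train`)
#' @return matrix of z-scores; zero-SD (constant) training columns map to 0
#' @export
standardize <- function(train, apply_to = train) {
  stop_if_not(is.matrix(train) && nrow(train) > 0, "train must be a non-empty matrix")
  stop_if_not(ncol(train) == ncol(apply_to), "column mismatch")
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  if (nrow(train) == 1) sdv[] <- 0
  z <- sweep(apply_to, 2, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  z
}

#' SVR model configuration
#'
#' Hyperparameters of the radial-basis support vector regressor. The
#' epsilon tube scales with the spread of the training targets
#' (`epsilon = epsilon_factor * SD(targets)`); gamma defaults to
#' `1 / (n_features * mean feature variance)` of the (standardized)
#' training matrix.
#'
#' @param cost SVR cost parameter C
#' @param epsilon_factor multiple of the training-target SD used as epsilon
#' @param gamma RBF width; `NULL` for the variance-scaled default
#' @return list of class `svr_config`
#' @export
svr_config <- function(cost = 1, epsilon_factor = 0.1, gamma = NULL) {
  structure(list(cost = cost, epsilon_factor = epsilon_factor, gamma = gamma),
            class = "svr_config")
}

# The regression target is standardized inside the fit (and predictions
# back-transformed) so that the cost parameter keeps its meaning regardless
# of the index's physical scale; the epsilon tube epsilon_factor * SD(y)
# becomes epsilon_factor on the standardized scale. A constant target has
# nothing to learn and is returned as-is.
fit_svr <- function(x, y, config) {
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0)
    return(structure(list(constant = mu), class = "neolus_svr"))
  gamma <- config$gamma
  if (is.null(gamma)) {
    v <- mean(apply(x, 2, stats::var))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  fit <- e1071::svm(x = x, y = (y - mu) / sdy, type = "eps-regression",
                    kernel = "radial", cost = config$cost,
                    epsilon = config$epsilon_factor, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, mu = mu, sd = sdy), class = "neolus_svr")
}

predict_svr <- function(object, newdata) {
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  object$mu + object$sd * stats::predict(object$fit, newdata)
}

#' Leave-one-patient-out SVR cross-validation
#'
#' For each patient, an RBF support vector regressor is trained on all other
#' patients' frames (each frame's target is its patient's index value) and
#' used to predict the held-out patient's frames; the frame predictions are
#' averaged into one per-patient prediction. Standardization is fitted
#' inside each training fold, so no information from the held-out patient
#' leaks into scaling.
#'
#' @param features numeric matrix, one row per frame
#' @param patient_ids character/factor vector, one entry per frame
#' @param targets named numeric vector of per-patient index values (names =
#'   patient ids)
#' @param config an [svr_config()]
#' @return data frame of class `cv_result`: `patient_id`, `truth`,
#'   `prediction`, one row per patient
#' @export
lopo_cv <- function(features, patient_ids, targets, config = svr_config()) {
  stop_if_not(is.matrix(features), "features must be a matrix")
  stop_if_not(nrow(features) == length(patient_ids), "one patient id per frame required")
  bad <- which(!apply(features, 1, function(r) all(is.finite(r))))
  stop_if_not(length(bad) == 0,
              "non-finite features in frame row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  patients <- unique(as.character(patient_ids))
  stop_if_not(length(patients) >= 3, "leave-one-patient-out needs at least 3 patients")
  stop_if_not(all(patients %in% names(targets)), "targets must be named by patient id")

  preds <- vapply(patients, function(p) {
    hold <- patient_ids == p
    ztr <- standardize(features[!hold, , drop = FALSE])
    zte <- standardize(features[!hold, , drop = FALSE], features[hold, , drop = FALSE])
    fit <- fit_svr(ztr, targets[as.character(patient_ids[!hold])], config)
    mean(predict_svr(fit, zte))
  }, numeric(1))

  structure(data.frame(patient_id = patients,
                       truth = unname(targets[patients]),
                       prediction = unname(preds),
                       stringsAsFactors = FALSE),
            class = c("cv_result", "data.frame"))
}

#' Per-group LOPO performance (AUC)
#'
#' Restricts the 44-dimensional feature vector to one of the three feature
#' groups (both directions) or keeps all features, runs [lopo_cv()], then
#' dichotomizes the true index at the configured cutoff and scores the
#' continuous per-patient predictions by ROC AUC.
#'
#' @param features frame-level feature matrix with the 44-vector's column
#'   names
#' @param patient_ids per-frame patient ids
#' @param targets named per-patient index values
#' @param index `"pf_ratio"` or `"aa_gradient"` (sets cutoff and score
#'   orientation)
#' @param groups subset of `c("all", "1", "2", "3")`
#' @param cutoff dichotomization cutoff override
#' @param config an [svr_config()]
#' @return data frame: `group`, `n_features`, `auc`
#' @export
group_analysis <- function(features, patient_ids, targets,
                           index = c("pf_ratio", "aa_gradient"),
                           groups = c("all", "1", "2", "3"),
                           cutoff = NULL, config = svr_config()) {
  index <- match.arg(index)
  rows <- lapply(groups, function(g) {
    idx <- feature_group_columns(colnames(features), g)
    cv <- lopo_cv(features[, idx, drop = FALSE], patient_ids, targets, config)
    d <- dichotomize(cv$truth, cv$prediction, index, cutoff)
    data.frame(group = g, n_features = length(idx),
               auc = roc_auc(d$scores, d$labels)$auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' PCA explained-variance curve and AUC-versus-k sweep
#'
#' The explained-variance curve is reported from a PCA of all standardized
#' frames (the descriptive curve); the predictive sweep keeps PCA strictly
#' inside each LOPO training fold: standardize, fit PCA, project onto the
#' first `k` components (descending variance), train the SVR on the
#' projected features and predict the held-out patient, then compute the
#' AUC at the index cutoff for each `k`.
#'
#' @inheritParams group_analysis
#' @param k_range integer vector of component counts to sweep; `NULL` skips
#'   the predictive sweep and returns only the variance curve
#' @return list of class `pca_sweep`: `var_frac` (per-component explained
#'   variance fractions, descending), `cum_var`, `auc_by_k` (data frame `k`,
#'   `auc`, or `NULL`)
#' @export
pca_sweep <- function(features, patient_ids, targets,
                      index = c("pf_ratio", "aa_gradient"),
                      k_range = 1:11, cutoff = NULL, config = svr_config()) {
  index <- match.arg(index)
  stop_if_not(is.null(k_range) ||
                (all(k_range >= 1) && all(k_range <= ncol(features))),
              "k_range must lie in 1..", ncol(features))
  pc_all <- stats::prcomp(standardize(features), center = FALSE, scale. = FALSE)
  var_frac <- pc_all$sdev^2 / sum(pc_all$sdev^2)

  auc_by_k <- NULL
  if (!is.null(k_range)) {
    patients <- unique(as.character(patient_ids))
    stop_if_not(length(patients) >= 3, "leave-one-patient-out needs at least 3 patients")
    # One PCA per fold, reused for every k.
    folds <- lapply(patients, function(p) {
      hold <- patient_ids == p
      ztr <- standardize(features[!hold, , drop = FALSE])
      zte <- standardize(features[!hold, , drop = FALSE], features[hold, , drop = FALSE])
      pc <- stats::prcomp(ztr, center = FALSE, scale. = FALSE)
      list(tr = ztr %*% pc$rotation, te = zte %*% pc$rotation,
           y = targets[as.character(patient_ids[!hold])])
    })
    auc_by_k <- do.call(rbind, lapply(k_range, function(k) {
      preds <- vapply(folds, function(f) {
        fit <- fit_svr(f$tr[, seq_len(k), drop = FALSE], f$y, config)
        mean(predict_svr(fit, f$te[, seq_len(k), drop = FALSE]))
      }, numeric(1))
      d <- dichotomize(unname(targets[patients]), preds, index, cutoff)
      data.frame(k = k, auc = roc_auc(d$scores, d$labels)$auc)
    }))
  }
  structure(list(var_frac = var_frac, cum_var = cumsum(var_frac),
                 auc_by_k = auc_by_k),
            class = "pca_sweep")
}
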