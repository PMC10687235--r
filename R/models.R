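# Risk models: L2-penalized logistic regression with cross-validated
# penalty, gradient-boosted clinical model, stacking fusion, and
# coefficient-table evaluators for published risk scores.

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) stop("features must be a matrix or data.frame")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

# Stratified fold ids; k is capped by the minority class size so every
# fold holds both classes.
stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_safe_set(seed)
  on.exit(.Random.seed_safe_restore(old), add = TRUE)
  k_eff <- max(2L, min(k, sum(y == 1), sum(y == 0)))
  if (k_eff < k)
    warning("folds merged: k reduced to ", k_eff,
            " so each fold keeps both classes")
  fold <- integer(length(y))
  for (g in c(0, 1)) {
    idx <- sample(which(y == g))
    fold[idx] <- rep_len(seq_len(k_eff), length(idx))
  }
  fold
}

#' L2-penalized logistic regression with cross-validated penalty
#'
#' Fits ridge logistic regression over a penalty grid, selecting the
#' penalty that maximizes mean validation AUROC across stratified
#' k-fold cross-validation (ties broken toward the smaller penalty),
#' then refits on the full training data.  Deterministic given the
#' seed (which controls only fold assignment).
#'
#' @param x Feature matrix or data.frame (numeric columns used).
#' @param y Binary labels.
#' @param penalty_grid Candidate L2 penalties (glmnet lambda).
#' @param k Number of CV folds (default 10; capped at the minority
#'   class size, with a warning, so no fold is single-class).
#' @param seed Integer seed for fold assignment.
#' @return Object of class `risk_model` (kind `l2_logistic`).
#' @export
fit_l2_logistic_cv <- function(x, y, penalty_grid = 10^seq(2, -4, -0.5),
                               k = 10, seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required to fit")
  grid <- sort(unique(penalty_grid), decreasing = TRUE)
  fold <- stratified_folds(y, k, seed)
  k_eff <- max(fold)
  cv_auc <- matrix(NA_real_, k_eff, length(grid))
  for (f in seq_len(k_eff)) {
    tr <- fold != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 0,
                          lambda = grid, standardize = TRUE)
    pr <- stats::predict(fit, x[!tr, , drop = FALSE], s = grid,
                         type = "response")
    cv_auc[f, ] <- apply(pr, 2, function(p) auroc(p, y[!tr]))
  }
  mean_auc <- colMeans(cv_auc)
  best_auc <- max(mean_auc)
  # ties (within numerical noise) go to the smallest penalty
  best <- max(which(mean_auc >= best_auc - 1e-12))
  lambda <- grid[best]
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = grid, standardize = TRUE)
  structure(list(kind = "l2_logistic", fit = fit, lambda = lambda,
                 feature_names = colnames(x),
                 cv = data.frame(lambda = grid, mean_auroc = mean_auc),
                 seed = seed, fitted = TRUE),
            class = "risk_model")
}

#' Predict risk probabilities from a fitted model
#'
#' @param model A `risk_model`.
#' @param x New feature matrix or data.frame with the training columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_risk <- function(model, x) {
  if (!inherits(model, "risk_model") || !isTRUE(model$fitted))
    stop("model must be a fitted risk_model")
  x <- as_feature_matrix(x)
  missing_cols <- setdiff(model$feature_names, colnames(x))
  if (length(missing_cols) > 0)
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  if (model$kind == "l2_logistic") {
    as.numeric(stats::predict(model$fit, x, s = model$lambda,
                              type = "response"))
  } else if (model$kind == "gbm") {
    dm <- xgboost::xgb.DMatrix(x, missing = NA)
    as.numeric(stats::predict(model$fit, dm))
  } else {
    stop("unknown model kind: ", model$kind)
  }
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> kind=%s, %d features\n", x$kind,
              length(x$feature_names)))
  invisible(x)
}

#' Bivariate segmentation-based risk model
#'
#' Ridge logistic regression on exactly the two automated
#' body-composition features: mean muscle radiodensity and the VAT/SAT
#' area ratio.
#'
#' @param muscle_hu Mean muscle radiodensity per patient (HU).
#' @param vat_sat Per-patient VAT/SAT area ratio.
#' @inheritParams fit_l2_logistic_cv
#' @return A `risk_model`.
#' @export
segmentation_only_model <- function(muscle_hu, vat_sat, y, k = 10,
                                    seed = 1) {
  x <- cbind(mean_muscle_hu = muscle_hu, vat_sat_ratio = vat_sat)
  fit_l2_logistic_cv(x, y, k = k, seed = seed)
}

#' Gradient-boosted clinical risk model
#'
#' Gradient-boosted trees (xgboost) on the EMR feature matrix, with
#' native missing-value passthrough (no imputation needed beyond the
#' targeted medians of the pipeline).  Hyperparameters are selected by
#' stratified k-fold cross-validated AUROC over a small search grid,
#' with early stopping choosing the boosting round count.
#'
#' @param x Feature matrix or data.frame; NA allowed.
#' @param y Binary labels.
#' @param search_grid data.frame of candidate parameter rows with
#'   columns `max_depth` and `eta`.
#' @param nrounds_max Maximum boosting rounds.
#' @param k CV folds.
#' @param seed Integer seed.
#' @return A `risk_model` (kind `gbm`).
#' @export
clinical_gbm <- function(x, y,
                         search_grid = expand.grid(max_depth = c(2L, 3L),
                                                   eta = c(0.05, 0.1)),
                         nrounds_max = 400, k = 10, seed = 1) {
  x <- as_feature_matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required to fit")
  dm <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  fold <- stratified_folds(y, k, seed)
  folds <- split(seq_along(y), fold)
  best <- NULL
  for (i in seq_len(nrow(search_grid))) {
    params <- list(objective = "binary:logistic",
                   eval_metric = "auc",
                   max_depth = search_grid$max_depth[i],
                   eta = search_grid$eta[i],
                   nthread = 1, seed = seed)
    cv <- xgboost::xgb.cv(params = params, data = dm,
                          nrounds = nrounds_max, folds = folds,
                          early_stopping_rounds = 20, verbose = 0)
    log <- cv$evaluation_log
    it <- which.max(log$test_auc_mean)
    auc <- log$test_auc_mean[it]
    if (is.null(best) || auc > best$auc + 1e-12) {
      best <- list(params = params, nrounds = it, auc = auc)
    }
  }
  fit <- xgboost::xgb.train(params = best$params, data = dm,
                            nrounds = best$nrounds, verbose = 0)
  structure(list(kind = "gbm", fit = fit,
                 feature_names = colnames(x),
                 best_params = best$params, nrounds = best$nrounds,
                 cv_auroc = best$auc, seed = seed, fitted = TRUE),
            class = "risk_model")
}

#' Stacking fusion of component risk outputs
#'
#' Meta-model: ridge logistic regression on the component models'
#' predicted risks (two or three columns), with the penalty chosen by
#' stratified k-fold cross-validated AUROC.
#'
#' @param risks Matrix or data.frame with one column of predicted risk
#'   per component model.
#' @inheritParams fit_l2_logistic_cv
#' @return A `risk_model`.
#' @export
stack_models <- function(risks, y, k = 10, seed = 1) {
  risks <- as_feature_matrix(risks)
  if (ncol(risks) < 2) stop("stacking needs at least two components")
  fit_l2_logistic_cv(risks, y, k = k, seed = seed)
}

#' Concatenation fusion of clinical covariates and segmentation features
#'
#' Gradient-boosted model on the published-score covariates
#' concatenated with the two automated body-composition features.
#'
#' @param covariates data.frame of clinical covariates (e.g. the PCE
#'   inputs).
#' @param muscle_hu,vat_sat Body-composition features per patient.
#' @inheritParams clinical_gbm
#' @return A `risk_model` (kind `gbm`).
#' @export
concat_fusion <- function(covariates, muscle_hu, vat_sat, y, k = 10,
                          seed = 1, ...) {
  x <- cbind(as_feature_matrix(covariates),
             mean_muscle_hu = muscle_hu, vat_sat_ratio = vat_sat)
  clinical_gbm(x, y, k = k, seed = seed, ...)
}

# ---- Published baseline scores (coefficient-table evaluators) --------

#' Read a baseline risk-score coefficient table
#'
#' Loads a Cox-style published risk score from a versioned TSV config:
#' rows of (covariate, transform, coefficient) plus the special rows
#' `.baseline_survival` and `.mean_lp`.  Covariate names may be
#' products `a:b` with per-factor transforms `log` or `identity`
#' separated by `:`.  The derived covariates `sbp_treated` /
#' `sbp_untreated` are resolved from `sbp` and `bp_treated` (the
#' untreated/treated arm contributes a neutral factor of 1 before the
#' log).  The package ships 10-year atherosclerotic-risk pooled-cohort
#' coefficient sets for white men and women, with a bundled worked
#' example per config.
#'
#' @param name Config name, e.g. "pce_white_male"; or a file path to a
#'   TSV in the same layout.
#' @return Object of class `baseline_score_spec`.
#' @export
read_baseline_score <- function(name = "pce_white_male") {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".tsv"), package = "ihdrisk")
  if (path == "" || !file.exists(path))
    stop("no such baseline score config: ", name)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("covariate", "transform", "coefficient")
  if (!all(need %in% names(tab)))
    stop("baseline config needs columns: ", paste(need, collapse = ", "))
  s0 <- tab$coefficient[tab$covariate == ".baseline_survival"]
  mean_lp <- tab$coefficient[tab$covariate == ".mean_lp"]
  if (length(s0) != 1 || length(mean_lp) != 1)
    stop("config must contain .baseline_survival and .mean_lp rows")
  terms <- tab[!startsWith(tab$covariate, "."), , drop = FALSE]
  structure(list(name = basename(path), terms = terms, s0 = s0,
                 mean_lp = mean_lp), class = "baseline_score_spec")
}

# Resolve one covariate factor value from a named feature vector.
resolve_covariate <- function(nm, feats) {
  if (nm %in% names(feats)) return(as.numeric(feats[[nm]]))
  if (nm == "sbp_treated" || nm == "sbp_untreated") {
    if (!all(c("sbp", "bp_treated") %in% names(feats)))
      stop("covariate '", nm, "' needs sbp and bp_treated")
    treated <- as.numeric(feats[["bp_treated"]]) == 1
    want <- (nm == "sbp_treated") == treated
    return(if (want) as.numeric(feats[["sbp"]]) else 1)
  }
  stop("unresolvable covariate: ", nm)
}

#' Evaluate a published baseline risk score
#'
#' Deterministic evaluation of the coefficient-table score:
#' `risk = 1 - S0 ^ exp(lp - mean_lp)` with
#' `lp = sum_j coef_j * prod_f transform(x_f)`.  Covariates must be
#' resolvable (run targeted median imputation first when inputs may be
#' missing).
#'
#' @param spec A `baseline_score_spec` from [read_baseline_score].
#' @param features Named list/vector, or data.frame (one row per
#'   patient), with the covariates the config references.
#' @return Risk probability in (0, 1), vectorized over data.frame
#'   rows.
#' @export
baseline_risk <- function(spec, features) {
  stopifnot(inherits(spec, "baseline_score_spec"))
  if (is.data.frame(features)) {
    return(vapply(seq_len(nrow(features)), function(i)
      baseline_risk(spec, as.list(features[i, , drop = FALSE])),
      numeric(1)))
  }
  lp <- 0
  for (i in seq_len(nrow(spec$terms))) {
    covs <- strsplit(spec$terms$covariate[i], ":", fixed = TRUE)[[1]]
    trans <- strsplit(spec$terms$transform[i], ":", fixed = TRUE)[[1]]
    if (length(trans) != length(covs))
      stop("transform arity mismatch for term ", spec$terms$covariate[i])
    val <- 1
    for (j in seq_along(covs)) {
      v <- resolve_covariate(covs[j], features)
      if (is.na(v)) stop("covariate is missing after imputation: ", covs[j])
      v <- switch(trans[j],
                  log = log(v),
                  identity = v,
                  stop("unknown transform: ", trans[j]))
      val <- val * v
    }
    lp <- lp + spec$terms$coefficient[i] * val
  }
  1 - spec$s0^exp(lp - spec$mean_lp)
}

#' SHAP feature-attribution summary for a gradient-boosted model
#'
#' Thin interface over the tree-model SHAP implementation built into
#' xgboost (`predcontrib` prediction): per-patient additive feature
#' attributions on the log-odds scale, summarized per feature and
#' ranked by mean absolute attribution.  Attributions plus the base
#' value reconstruct the margin prediction (additivity).
#'
#' @param model A `risk_model` of kind `gbm`.
#' @param x Feature matrix or data.frame.
#' @return data.frame(feature, mean_abs_shap, mean_shap) sorted by
#'   mean_abs_shap, with attribute `contributions` (the per-patient
#'   matrix including the BIAS column).
#' @export
shap_summary <- function(model, x) {
  if (!inherits(model, "risk_model") || model$kind != "gbm")
    stop("SHAP attribution here supports gradient-boosted risk models only")
  x <- as_feature_matrix(x)[, model$feature_names, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(x, missing = NA)
  contrib <- stats::predict(model$fit, dm, predcontrib = TRUE)
  shap <- contrib[, intersect(colnames(contrib), model$feature_names),
                  drop = FALSE]
  out <- data.frame(feature = colnames(shap),
                    mean_abs_shap = colMeans(abs(shap)),
                    mean_shap = colMeans(shap))
  out <- out[order(-out$mean_abs_shap), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contributions") <- contrib
  out
}
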