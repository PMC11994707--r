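#' Pearson correlation filter for radiomics features
#'
#' Z-scores each feature on the training samples, then keeps features whose
#' Pearson correlation with the continuous target (the CS polarity) satisfies
#' `|r| > r_thresh` and `p < p_thresh`, both strict; p-values are unadjusted,
#' from the exact t distribution (identical to `cor.test`). The training
#' means and standard deviations of the retained features are recorded so the
#' same frozen transform can be applied to validation data without leakage.
#'
#' @param features samples x features numeric matrix (or data.frame with an
#'   `id` first column).
#' @param target numeric target per sample (same order as rows).
#' @param r_thresh,p_thresh strict thresholds.
#' @return list with `z` (z-scored retained features), `features` (names),
#'   `stats` (data.frame `feature`, `mean`, `sd`, `r`, `p` for retained
#'   features), `all_r`, `all_p` (per input feature).
#' @export
pearson_filter <- function(features, target, r_thresh = 0.3,
                           p_thresh = 0.05) {
  features <- feature_matrix(features)
  if (nrow(features) < 3) stop("need at least 3 samples")
  if (length(target) != nrow(features) || anyNA(target))
    stop("target must be defined for every sample")
  mu <- colMeans(features)
  sds <- apply(features, 2L, stats::sd)
  usable <- sds > 0
  z <- sweep(sweep(features, 2L, mu, "-"), 2L, pmax(sds, 1e-300), "/")
  res <- row_cor_test(t(z[, usable, drop = FALSE]), target, "pearson")
  r <- p <- rep(NA_real_, ncol(features))
  r[usable] <- res$r
  p[usable] <- res$p
  keep <- usable & !is.na(r) & abs(r) > r_thresh & p < p_thresh
  if (!any(keep))
    stop("no feature passed |r| > ", r_thresh, " and p < ", p_thresh,
         "; consider relaxing the thresholds")
  kept <- colnames(features)[keep]
  list(z = z[, kept, drop = FALSE],
       features = kept,
       stats = data.frame(feature = kept, mean = mu[kept], sd = sds[kept],
                          r = r[keep], p = p[keep], row.names = NULL,
                          stringsAsFactors = FALSE),
       all_r = stats::setNames(r, colnames(features)),
       all_p = stats::setNames(p, colnames(features)))
}

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    rn <- NULL
    if (!is.null(features$id)) {
      rn <- features$id
      features <- features[, setdiff(names(features), "id"), drop = FALSE]
    } else if (is.character(features[[1L]])) {
      rn <- features[[1L]]
      features <- features[, -1L, drop = FALSE]
    }
    features <- as.matrix(features)
    if (!is.null(rn)) rownames(features) <- rn
  }
  storage.mode(features) <- "double"
  features
}

#' LASSO with leave-one-out cross-validation
#'
#' L1-penalized linear regression of the continuous target on the (already
#' z-scored) filtered features, on a 100-point log-spaced lambda grid down to
#' `1e-3 * lambda_max`; the optimal lambda minimizes the leave-one-out mean
#' squared prediction error. Features with exactly zero coefficients at the
#' optimum are unselected. The intercept is unpenalized.
#'
#' @param z samples x features matrix, z-scored (e.g. `pearson_filter()$z`).
#' @param target numeric response.
#' @param nlambda,lambda_min_ratio lambda grid shape.
#' @param lambda optional explicit descending lambda grid overriding the
#'   automatic one (e.g. ending in 0 to reach the unpenalized limit).
#' @param family `"gaussian"` for the continuous polarity (default) or
#'   `"binomial"` for the dichotomized group.
#' @return list `coefficients` (named, selected features only), `intercept`,
#'   `lambda`, `selected`, `cv_error` (LOO MSE at the optimum), `glmnet_fit`.
#' @export
lasso_fit <- function(z, target, nlambda = 100, lambda_min_ratio = 1e-3,
                      lambda = NULL, family = "gaussian") {
  z <- as.matrix(z)
  if (nrow(z) < 3) stop("need at least 3 samples")
  n <- nrow(z)
  single <- ncol(z) == 1L
  if (single) {
    # glmnet needs >= 2 columns; a zero column can never be selected
    z <- cbind(z, `.zero_pad` = 0)
  }
  cv <- if (is.null(lambda)) {
    glmnet::cv.glmnet(z, target, alpha = 1, family = family,
                      nfolds = n, grouped = FALSE,
                      standardize = FALSE, nlambda = nlambda,
                      lambda.min.ratio = lambda_min_ratio)
  } else {
    glmnet::cv.glmnet(z, target, alpha = 1, family = family,
                      nfolds = n, grouped = FALSE,
                      standardize = FALSE, lambda = lambda)
  }
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1L]
  beta <- co[-1L]
  if (single) beta <- beta[setdiff(names(beta), ".zero_pad")]
  selected <- names(beta)[beta != 0]
  list(coefficients = beta[selected],
       intercept = unname(co[1L]),
       lambda = cv$lambda.min,
       selected = selected,
       cv_error = cv$cvm[cv$lambda == cv$lambda.min][1L],
       glmnet_fit = cv)
}

#' Radiomics score from a fitted RCSP model
#'
#' `RadScore = intercept + sum_f coef_f * z_f`, where `z_f` is the feature
#' value standardized with the training mean and sd frozen in the model.
#'
#' @param features samples x features matrix/data.frame containing at least
#'   the selected features.
#' @param model an `rcsp_model` (or the list from [train_rcsp()]).
#' @return named numeric vector of per-sample RadScores.
#' @export
radscore <- function(features, model) {
  features <- feature_matrix(features)
  sel <- names(model$lasso_coefficients)
  miss <- setdiff(sel, colnames(features))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  fs <- model$feature_stats
  z <- sweep(sweep(features[, sel, drop = FALSE], 2L,
                   fs$mean[match(sel, fs$feature)], "-"),
             2L, fs$sd[match(sel, fs$feature)], "/")
  drop(model$lasso_intercept + z %*% model$lasso_coefficients)
}

#' Univariate Cox screen for clinical covariates
#'
#' Keeps covariates whose univariate Cox Wald p-value is below `p_thresh`
#' (0.15 by convention for this permissive screen). Constant covariates
#' cannot be fit and are excluded with a warning. An empty result is allowed:
#' the RiskScore then reduces to the RadScore term alone.
#'
#' @param clinical data.frame of candidate covariates (samples in rows,
#'   matching `st`).
#' @param st a survival table for the same samples.
#' @param p_thresh retention threshold.
#' @return character vector of retained covariate names.
#' @export
clinical_cox_filter <- function(clinical, st, p_thresh = 0.15) {
  st <- as_survival_table(st)
  keep <- character(0)
  for (v in names(clinical)) {
    st2 <- st
    st2[[v]] <- clinical[[v]]
    fit <- tryCatch(cox_fit(st2, v),
                    error = function(e) {
                      warning("covariate '", v, "' skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit) && fit$p[1L] < p_thresh) keep <- c(keep, v)
  }
  keep
}

#' Train the two-stage RCSP model
#'
#' Stage 1: Pearson-filter the features against the continuous CS polarity,
#' fit the LASSO with LOOCV, and freeze the RadScore (selected features,
#' coefficients, training z-scoring statistics). Stage 2: screen clinical
#' covariates by univariate Cox (p < 0.15), then fit a multivariable Cox
#' model on the RadScore plus retained covariates; the linear predictor
#' \deqn{RiskScore = \hat\beta_{RadScore} RadScore + \sum_j \hat\beta_j
#' X_j^{(clinical)}}
#' is frozen together with the training-median threshold (ties at the
#' threshold go to the low-risk group).
#'
#' @param features training samples x features matrix/data.frame.
#' @param target continuous CS polarity per training sample.
#' @param st training survival table (rows aligned with `features`).
#' @param clinical optional data.frame of clinical covariates (rows aligned);
#'   `NULL` for the radiomics-only model.
#' @param r_thresh,p_thresh Pearson-filter thresholds.
#' @param cox_p_thresh clinical screen threshold.
#' @return object of class `rcsp_model`: feature stats, LASSO coefficients
#'   and lambda, clinical betas, `beta_radscore`, `risk_threshold`, plus
#'   training scores.
#' @export
train_rcsp <- function(features, target, st, clinical = NULL,
                       r_thresh = 0.3, p_thresh = 0.05,
                       cox_p_thresh = 0.15) {
  features <- feature_matrix(features)
  st <- as_survival_table(st)
  flt <- pearson_filter(features, target, r_thresh, p_thresh)
  las <- lasso_fit(flt$z[, flt$features, drop = FALSE], target)
  model <- structure(list(
    feature_stats = flt$stats,
    filtered_features = flt$features,
    lasso_coefficients = las$coefficients,
    lasso_intercept = las$intercept,
    lambda = las$lambda,
    clinical_covariates = character(0),
    clinical_betas = numeric(0),
    beta_radscore = NA_real_,
    risk_threshold = NA_real_), class = "rcsp_model")
  rs <- radscore(features, model)

  retained <- if (!is.null(clinical))
    clinical_cox_filter(clinical, st, cox_p_thresh) else character(0)
  st2 <- st
  st2$RadScore <- rs
  for (v in retained) st2[[v]] <- clinical[[v]]
  cox <- cox_fit(st2, c("RadScore", retained))
  model$clinical_covariates <- retained
  model$clinical_betas <- stats::setNames(cox$beta[-1L], retained)
  model$beta_radscore <- cox$beta[1L]
  model$cox_table <- cox
  risk <- riskscore_from(model, rs,
                         if (length(retained))
                           clinical[, retained, drop = FALSE] else NULL)
  model$risk_threshold <- stats::median(risk)
  model$training_radscore <- rs
  model$training_riskscore <- risk
  model
}

riskscore_from <- function(model, rs, clinical) {
  risk <- model$beta_radscore * rs
  for (v in model$clinical_covariates) {
    x <- clinical[[v]]
    if (is.null(x)) stop("clinical covariate '", v, "' missing")
    if (!is.numeric(x)) x <- as.numeric(as.factor(x))
    risk <- risk + model$clinical_betas[[v]] * x
  }
  risk
}

#' @export
print.rcsp_model <- function(x, ...) {
  cat("rcsp_model: ", length(x$filtered_features), " filtered -> ",
      length(x$lasso_coefficients), " LASSO-selected features (lambda = ",
      format(x$lambda, digits = 4), ")\n", sep = "")
  cat("  beta_RadScore = ", format(x$beta_radscore, digits = 4),
      "; clinical covariates: ",
      if (length(x$clinical_covariates))
        paste(x$clinical_covariates, collapse = ", ") else "(none)",
      "\n  risk threshold (training median) = ",
      format(x$risk_threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Apply a frozen RCSP model to a validation cohort
#'
#' Computes validation RadScores with the training z-scoring statistics and
#' coefficients, the RiskScore with the stored Cox betas, splits the cohort
#' at the stored training-median threshold (high iff score > threshold), and
#' compares survival between risk groups by Kaplan-Meier and log-rank. No
#' training statistic is recomputed from validation data.
#'
#' @param model an `rcsp_model`.
#' @param features validation samples x features matrix/data.frame.
#' @param st validation survival table.
#' @param clinical validation clinical covariates (must contain the model's
#'   retained covariates, if any).
#' @return list `radscore`, `riskscore`, `risk_group`, `km`, `logrank`.
#' @export
apply_model <- function(model, features, st, clinical = NULL) {
  stopifnot(inherits(model, "rcsp_model"))
  st <- as_survival_table(st)
  rs <- radscore(features, model)
  risk <- riskscore_from(model, rs, clinical)
  grp <- ifelse(risk > model$risk_threshold, "high_risk", "low_risk")
  st$group <- grp
  if (length(unique(grp)) < 2) {
    warning("all samples fall in one risk group; log-rank p = 1")
    lr <- list(chi2 = 0, p = 1)
    km <- km_curve(st, by = NULL)
  } else {
    lr <- logrank(st, by = "group")
    km <- km_curve(st, by = "group")
  }
  list(radscore = rs, riskscore = risk, risk_group = grp,
       km = km, logrank = lr)
}

#' ROC area under the curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' scores above a random negative, ties counting one half.
#'
#' @param score numeric predictions.
#' @param labels binary labels (logical, 0/1, or a factor/character with two
#'   levels; the second sorted level is "positive").
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(score, labels) {
  if (is.character(labels) || is.factor(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2) stop("labels must have exactly two classes")
    labels <- as.character(labels) == lev[2L]
  }
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize / restore an RCSP model as JSON
#'
#' Stores everything needed for exact reapplication: selected features with
#' coefficients and training statistics, Cox betas and the frozen threshold.
#'
#' @param model an `rcsp_model`.
#' @param path JSON file path.
#' @return `write_rcsp_model`: invisibly the path; `read_rcsp_model`: the
#'   restored `rcsp_model`.
#' @export
write_rcsp_model <- function(model, path) {
  stopifnot(inherits(model, "rcsp_model"))
  jsonlite::write_json(list(
    feature_stats = model$feature_stats,
    filtered_features = model$filtered_features,
    lasso_coefficients = as.list(model$lasso_coefficients),
    lasso_intercept = model$lasso_intercept,
    lambda = model$lambda,
    clinical_covariates = model$clinical_covariates,
    clinical_betas = as.list(model$clinical_betas),
    beta_radscore = model$beta_radscore,
    risk_threshold = model$risk_threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rcsp_model
#' @export
read_rcsp_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    feature_stats = as.data.frame(j$feature_stats),
    filtered_features = j$filtered_features,
    lasso_coefficients = unlist(j$lasso_coefficients),
    lasso_intercept = j$lasso_intercept,
    lambda = j$lambda,
    clinical_covariates = as.character(j$clinical_covariates),
    clinical_betas = if (length(j$clinical_betas))
      unlist(j$clinical_betas) else numeric(0),
    beta_radscore = j$beta_radscore,
    risk_threshold = j$risk_threshold), class = "rcsp_model")
}
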