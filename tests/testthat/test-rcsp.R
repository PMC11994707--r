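test_that("pearson filter retains by strict |r| and p thresholds", {
  set.seed(1)
  n <- 30
  z <- rnorm(n)
  x <- cbind(exact = z, noisy = z + rnorm(n, 0, 0.5),
             junk = rnorm(n))
  flt <- pearson_filter(x, z)
  expect_true(all(c("exact", "noisy") %in% flt$features))
  expect_false("junk" %in% flt$features)
  # z-scored columns have mean 0 and sd 1 on the training set
  expect_lt(max(abs(colMeans(flt$z))), 1e-9)
  expect_lt(max(abs(apply(flt$z, 2, sd) - 1)), 1e-9)
  # strictness: setting the threshold to a feature's own |r| drops it
  r_noisy <- flt$stats$r[flt$stats$feature == "noisy"]
  flt2 <- pearson_filter(x, z, r_thresh = abs(r_noisy))
  expect_false("noisy" %in% flt2$features)
  noise_only <- x[, "junk", drop = FALSE]
  expect_error(pearson_filter(cbind(noise_only, junk2 = rnorm(n)), z,
                              r_thresh = 0.999),
               "no feature passed")
})

test_that("filter r and p agree with cor.test", {
  set.seed(2)
  n <- 25
  z <- rnorm(n)
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  x[, 1] <- z + rnorm(n, 0, 1)
  flt <- pearson_filter(x, z, r_thresh = 0, p_thresh = 1.01)
  for (j in colnames(x)) {
    ct <- cor.test(x[, j], z)
    expect_equal(unname(flt$all_r[j]), unname(ct$estimate),
                 tolerance = 1e-12)
    expect_equal(unname(flt$all_p[j]), ct$p.value, tolerance = 1e-12)
  }
})

test_that("LASSO path obeys the orthonormal closed form", {
  set.seed(3)
  n <- 40; p <- 5
  raw <- matrix(rnorm(n * p), n, p)
  q <- qr.Q(qr(scale(raw, scale = FALSE)))
  x <- sqrt(n) * q                      # X'X = n I, columns mean ~ 0
  colnames(x) <- paste0("f", 1:p)
  beta_true <- c(2, -1.5, 0.8, 0, 0)
  y <- drop(x %*% beta_true) + rnorm(n, 0, 0.1)
  fit <- lasso_fit(x, y)
  path <- fit$glmnet_fit$glmnet.fit
  ols <- drop(crossprod(x, y - mean(y))) / n
  for (s in seq(1, length(path$lambda), by = 10)) {
    lam <- path$lambda[s]
    expect_equal(as.vector(path$beta[, s]), unname(soft(ols, lam)),
                 tolerance = 1e-3)
  }
  # selected-set size is non-increasing in lambda on the grid
  sizes <- colSums(as.matrix(path$beta) != 0)
  expect_true(all(diff(sizes[order(path$lambda)]) <= 0))
  # at the largest lambda everything is shrunk away
  expect_equal(sum(path$beta[, 1] != 0), 0)
})

test_that("unpenalized single-feature LASSO equals the OLS slope", {
  set.seed(4)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "f"))
  y <- 2.5 * x[, 1]
  # an explicit grid ending in 0: LOOCV picks the unpenalized fit on
  # noiseless data, whose coefficient is exactly the OLS slope
  fit <- lasso_fit(x, y, lambda = c(2^(3:-6), 0))
  expect_equal(fit$lambda, 0)
  expect_equal(unname(fit$coefficients["f"]),
               unname(coef(lm(y ~ x))[2]), tolerance = 1e-6)
})

test_that("radscore is the frozen linear combination", {
  model <- structure(list(
    feature_stats = data.frame(feature = "f1", mean = 2, sd = 2),
    lasso_coefficients = c(f1 = 1), lasso_intercept = 0.25),
    class = "rcsp_model")
  x <- matrix(c(7), 1, dimnames = list("s1", "f1"))  # z = 2.5
  expect_equal(unname(radscore(x, model)), 0.25 + 2.5)
  # all-zero coefficients give a constant score
  model0 <- structure(list(
    feature_stats = data.frame(feature = character(0), mean = numeric(0),
                               sd = numeric(0)),
    lasso_coefficients = setNames(numeric(0), character(0)),
    lasso_intercept = 1.5), class = "rcsp_model")
  xs <- matrix(rnorm(6), 3, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(radscore(xs, model0)), rep(1.5, 3))
  expect_error(radscore(xs, model), "missing feature")
})

test_that("RadScore recovers the planted polarity at criterion settings", {
  mk <- make_truth(41, seed = 77, feature_noise_sd = 0.2)
  ft <- generate_feature_table(mk$truth, mk$cfg)
  z <- mk$truth$patient_polarity
  flt <- pearson_filter(ft$features, z)
  las <- lasso_fit(flt$z, z)
  model <- structure(list(feature_stats = flt$stats,
                          lasso_coefficients = las$coefficients,
                          lasso_intercept = las$intercept),
                     class = "rcsp_model")
  expect_gte(cor(radscore(ft$features, model), z), 0.9)
  expect_gte(sum(ft$truth$informative_feature_ids %in% las$selected), 4)
})

test_that("clinical Cox screen keeps informative and rejects constant
           covariates", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  st <- as_survival_table(
    data.frame(time = rexp(n, 0.2 * exp(x)), event = 1))
  clin <- data.frame(lp = x, flat = rep(1, n))
  expect_warning(kept <- clinical_cox_filter(clin, st), "flat")
  expect_identical(kept, "lp")
})

test_that("training, freezing and applying the RCSP model is leak-free", {
  mk_cohort <- function(n, seed) {
    mk <- make_truth(n, seed = seed, feature_noise_sd = 0.2)
    ft <- generate_feature_table(mk$truth, mk$cfg)
    sv <- generate_survival(mk$truth, mk$cfg)
    list(z = mk$truth$patient_polarity, features = ft$features,
         st = as_survival_table(sv))
  }
  tr <- mk_cohort(41, 101)
  va <- mk_cohort(65, 102)
  clin <- data.frame(grade = round(2 - tr$z + rnorm(41, 0, 0.5)))
  model <- train_rcsp(tr$features, tr$z, tr$st, clinical = clin)
  expect_s3_class(model, "rcsp_model")
  expect_equal(unname(model$beta_radscore * model$training_radscore +
                        if (length(model$clinical_covariates))
                          model$clinical_betas[["grade"]] * clin$grade
                        else 0),
               unname(model$training_riskscore), tolerance = 1e-12)

  # self-application reproduces the training stratification
  self <- apply_model(model, tr$features, tr$st,
                      clinical = clin)
  expect_identical(self$risk_group,
                   ifelse(model$training_riskscore > model$risk_threshold,
                          "high_risk", "low_risk"))

  # applying to permuted validation rows never touches training state
  va_clin <- data.frame(grade = round(2 - va$z + rnorm(65, 0, 0.5)))
  before <- digest_model(model)
  res <- apply_model(model, va$features, va$st, clinical = va_clin)
  perm <- sample(65)
  res_p <- apply_model(model, va$features[perm, ],
                       va$st[perm, ], clinical = va_clin[perm, ,
                                                         drop = FALSE])
  expect_identical(digest_model(model), before)
  expect_equal(unname(res_p$riskscore), unname(res$riskscore[perm]),
               tolerance = 1e-12)
  expect_equal(res_p$logrank$p, res$logrank$p, tolerance = 1e-12)
})

test_that("degenerate RiskScore designs are caught or degrade loudly", {
  mk <- make_truth(41, seed = 103, feature_noise_sd = 0.2)
  ft <- generate_feature_table(mk$truth, mk$cfg)
  sv <- as_survival_table(generate_survival(mk$truth, mk$cfg))
  model <- train_rcsp(ft$features, mk$truth$patient_polarity, sv)
  # empty clinical list: RiskScore proportional to RadScore
  expect_length(model$clinical_covariates, 0)
  expect_equal(unname(model$training_riskscore),
               unname(model$beta_radscore * model$training_radscore),
               tolerance = 1e-12)
  # RadScore duplicated as a clinical covariate is collinear
  rs <- radscore(ft$features, model)
  expect_error(
    suppressWarnings(train_rcsp(ft$features, mk$truth$patient_polarity, sv,
                                clinical = data.frame(dup = rs),
                                cox_p_thresh = 1.01)),
    "converge|collinear|constant")
  # constant-score model puts everyone in one group
  model0 <- model
  model0$lasso_coefficients <- setNames(numeric(0), character(0))
  model0$beta_radscore <- 1
  model0$risk_threshold <- model0$lasso_intercept + 1
  expect_warning(res0 <- apply_model(model0, ft$features, sv),
                 "one risk group")
  expect_equal(res0$logrank$p, 1)
})

test_that("the model JSON round-trips exactly", {
  mk <- make_truth(41, seed = 104, feature_noise_sd = 0.2)
  ft <- generate_feature_table(mk$truth, mk$cfg)
  sv <- as_survival_table(generate_survival(mk$truth, mk$cfg))
  model <- train_rcsp(ft$features, mk$truth$patient_polarity, sv)
  path <- withr::local_tempfile(fileext = ".json")
  write_rcsp_model(model, path)
  back <- read_rcsp_model(path)
  expect_equal(back$lasso_coefficients, model$lasso_coefficients)
  expect_equal(back$risk_threshold, model$risk_threshold)
  expect_equal(unname(radscore(ft$features, back)),
               unname(radscore(ft$features, model)), tolerance = 1e-12)
})

test_that("roc_auc follows the rank formulation", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  s <- rnorm(50)
  l <- rbinom(50, 1, 0.5)
  if (sum(l) %in% c(0, 50)) l[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1, tolerance = 1e-12)
  # ties contribute one half
  expect_equal(roc_auc(c(1, 1), c(0, 1)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("RadScore separates the planted polarity groups by ROC", {
  mk <- make_truth(41, seed = 105, feature_noise_sd = 0.2)
  ft <- generate_feature_table(mk$truth, mk$cfg)
  z <- mk$truth$patient_polarity
  flt <- pearson_filter(ft$features, z)
  las <- lasso_fit(flt$z, z)
  model <- structure(list(feature_stats = flt$stats,
                          lasso_coefficients = las$coefficients,
                          lasso_intercept = las$intercept),
                     class = "rcsp_model")
  rs <- radscore(ft$features, model)
  expect_gt(roc_auc(rs, mk$truth$true_groups == "high"), 0.85)
})
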