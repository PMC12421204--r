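# L1-penalized feature selection, class-weighted nu-SVC with probabilistic
# output, stratified cross-validation, and grouped feature importance.

#' Model configuration
#'
#' @param nu nu-SVC complexity parameter in (0, 1): an upper bound on the
#'   margin-error fraction and a lower bound on the support-vector fraction.
#' @param kernel `"radial"` (Gaussian RBF) or `"linear"`.
#' @param gamma RBF bandwidth; `NULL` applies the `1 / (m * mean feature
#'   variance)` rule on the selected training matrix.
#' @param C_sel L1 selection penalty strength (`lambda = 1 / C_sel`); `NULL`
#'   picks the penalty by internal stratified cross-validation.
#' @param folds Number of stratified CV folds (>= 2).
#' @param screen Univariate screening width applied before the L1 fit when
#'   the feature count exceeds it (sure-independence-style pre-filter).
#' @param seed Seed recorded with CV results.
#' @return An object of class `model_config`.
#' @export
model_config <- function(nu = 0.5, kernel = c("radial", "linear"),
                         gamma = NULL, C_sel = NULL, folds = 5,
                         screen = 500, seed = 1) {
  kernel <- match.arg(kernel)
  if (!is.numeric(nu) || nu <= 0 || nu >= 1)
    stop("`nu` must lie in (0, 1)", call. = FALSE)
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  structure(list(nu = nu, kernel = kernel, gamma = gamma, C_sel = C_sel,
                 folds = as.integer(folds), screen = as.integer(screen),
                 seed = seed),
            class = "model_config")
}

#' Inverse-frequency class weights
#'
#' `w_i = n / (2 n_i)`: weights inversely proportional to class frequency,
#' both equal to 1 under balance, penalizing minority-class misclassification
#' more heavily.
#'
#' @param labels Vector of 0/1 outcome labels with both classes present.
#' @return Named numeric vector `c("0" = w0, "1" = w1)`.
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("both classes must be present to compute class weights", call. = FALSE)
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Train-fold imputation and standardization
#'
#' Fits per-column train medians (imputation) and train mean/SD (z-scoring)
#' and applies them to the training matrix and, verbatim, to an optional
#' held-out matrix -- no information flows from `apply_to` into the fitted
#' parameters. Zero-SD columns map to 0.
#'
#' @param train Numeric matrix (or `feature_matrix`) to fit on.
#' @param apply_to Optional matrix with the same columns.
#' @return List with `train`, `apply` (standardized dense matrices),
#'   `medians`, `centers`, `scales`.
#' @export
impute_and_standardize <- function(train, apply_to = NULL) {
  Xt <- if (inherits(train, "feature_matrix")) train$X else as.matrix(train)
  Xa <- if (inherits(apply_to, "feature_matrix")) apply_to$X else
    if (!is.null(apply_to)) as.matrix(apply_to) else NULL
  if (!is.null(Xa) && !identical(colnames(Xt), colnames(Xa)))
    stop("schema error: train and apply_to must share column names",
         call. = FALSE)
  med <- cpp_col_medians(Xt)
  med[is.na(med)] <- 0                      # all-missing column: impute zero
  fill <- function(X) {
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- med[idx[, 2]]
    X
  }
  Xt <- fill(Xt)
  ctr <- colMeans(Xt)
  scl <- sqrt(pmax(0, (colSums(Xt^2) - nrow(Xt) * ctr^2) / (nrow(Xt) - 1)))
  scl[!is.finite(scl) | scl == 0] <- Inf    # zero-SD columns -> 0 after scaling
  Zt <- sweep(sweep(Xt, 2, ctr), 2, scl, "/")
  Za <- NULL
  if (!is.null(Xa)) {
    Xa <- fill(Xa)
    Za <- sweep(sweep(Xa, 2, ctr), 2, scl, "/")
  }
  list(train = Zt, apply = Za, medians = med, centers = ctr, scales = scl)
}

expand_obs_weights <- function(labels, weights) {
  if (is.null(weights)) weights <- class_weights(labels)
  unname(weights[as.character(as.integer(labels))])
}

#' Sparse linear feature selection with an L1 penalty
#'
#' Fits a class-weighted, L1-penalized sparse linear classifier
#' (lasso-penalized logistic regression) on the standardized feature matrix
#' and returns the features with nonzero coefficients. When the feature count
#' exceeds `screen`, a univariate weighted-difference screen keeps the
#' strongest `screen` candidates first. An empty selection falls back to the
#' 20 largest-|coefficient| features at the weakest penalty of the path
#' (reported via a warning).
#'
#' @param X Dense standardized numeric matrix (n x l), no missing values.
#' @param y 0/1 labels.
#' @param C_sel Penalty strength: the lasso penalty is `lambda = 1 / C_sel`,
#'   so larger `C_sel` (weaker penalty) selects at least as many features.
#'   `NULL` (default) chooses `lambda` by internal stratified 5-fold CV.
#' @param weights Class weights as from [class_weights()]; `NULL` computes
#'   them from `y`.
#' @param screen Screening width (see above).
#' @return Object of class `l1_selection`: list with `selected` (column
#'   indices), `coef` (named nonzero coefficients), `lambda`, `fallback`.
#' @export
l1_select <- function(X, y, C_sel = NULL, weights = NULL, screen = 500) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < 2L) stop("degenerate X: need at least 2 rows", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  w <- expand_obs_weights(y, weights)

  keep <- seq_len(ncol(X))
  if (!is.null(screen) && ncol(X) > screen) {
    sc <- screen_score(X, y, w)
    keep <- order(sc, decreasing = TRUE)[seq_len(screen)]
    keep <- sort(keep)
  }
  Xs <- X[, keep, drop = FALSE]

  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1, weights = w,
                        standardize = FALSE, nlambda = 60)
  if (is.null(C_sel)) {
    foldid <- stratified_folds(y, 5)
    cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                            weights = w, standardize = FALSE, foldid = foldid,
                            nlambda = 60)
    lambda <- cv$lambda.min
  } else {
    if (C_sel <= 0) stop("`C_sel` must be > 0", call. = FALSE)
    lambda <- 1 / C_sel
  }
  beta <- drop(as.matrix(coef(fit, s = lambda)))[-1]   # drop intercept
  nz <- which(beta != 0)
  fallback <- FALSE
  if (!length(nz)) {
    beta <- drop(as.matrix(coef(fit, s = min(fit$lambda))))[-1]
    nz <- order(abs(beta), decreasing = TRUE)[seq_len(min(20, sum(beta != 0)))]
    nz <- nz[beta[nz] != 0]
    fallback <- TRUE
    warning("empty L1 selection; falling back to the top-|coefficient| ",
            "features at the weakest penalty", call. = FALSE)
  }
  sel <- keep[nz]
  cf <- beta[nz]
  names(cf) <- colnames(X)[sel]
  structure(list(selected = sel, coef = cf, lambda = lambda,
                 fallback = fallback),
            class = "l1_selection")
}

# weighted standardized mean-difference screening score
screen_score <- function(X, y, w) {
  w1 <- w * (y == 1); w0 <- w * (y == 0)
  m1 <- drop(crossprod(X, w1)) / sum(w1)
  m0 <- drop(crossprod(X, w0)) / sum(w0)
  v <- apply(X, 2, var)
  v[v == 0] <- Inf
  abs(m1 - m0) / sqrt(v)
}

#' Fit a class-weighted nu-SVC with probabilistic output
#'
#' Fits a nu-parameterized soft-margin kernel classifier. Class weights
#' (libsvm ignores per-class weights in the nu formulation) are applied by
#' integer replication of rows in proportion to their class weight. A
#' Platt-style sigmoid is fitted on the training decision values to produce
#' probabilities. The margin-error and support-vector fractions of the fit
#' are stored; every successful fit satisfies
#' `margin-error fraction <= nu <= support-vector fraction`.
#'
#' @param X Dense standardized numeric matrix of the selected features.
#' @param y 0/1 labels (both classes present).
#' @param config A [model_config()].
#' @param weights Class weights (`NULL`: unweighted fit).
#' @return Object of class `nu_svc_fit` with elements `svm`, `platt`,
#'   `orient`, `sv_fraction`, `margin_error_fraction`, `nu`.
#' @export
fit_nu_svc <- function(X, y, config = model_config(), weights = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("both classes must be present", call. = FALSE)

  rep0 <- 1L; rep1 <- 1L
  if (!is.null(weights)) {
    r <- weights[["1"]] / weights[["0"]]
    if (r >= 1) rep1 <- max(1L, as.integer(round(r)))
    else rep0 <- max(1L, as.integer(round(1 / r)))
  }
  idx <- c(rep(which(y == 0L), rep0), rep(which(y == 1L), rep1))
  Xe <- X[idx, , drop = FALSE]
  ye <- y[idx]
  ne <- length(ye)
  nu_max <- 2 * min(sum(ye == 0L), sum(ye == 1L)) / ne
  if (config$nu >= nu_max)
    stop(sprintf("infeasible nu = %.3f for this class balance; nu must be < %.3f",
                 config$nu, nu_max), call. = FALSE)

  gamma <- config$gamma
  if (is.null(gamma)) {
    mv <- mean(apply(X, 2, var))
    if (!is.finite(mv) || mv <= 0) mv <- 1
    gamma <- 1 / (ncol(X) * mv)
  }
  fit <- e1071::svm(Xe, factor(ye, levels = c(0, 1)),
                    type = "nu-classification", kernel = config$kernel,
                    nu = config$nu, gamma = gamma, scale = FALSE)

  pr <- predict(fit, Xe, decision.values = TRUE)
  dec <- attr(pr, "decision.values")
  # decision > 0 votes for the first label of the column name "A/B"
  first <- strsplit(colnames(dec)[1], "/")[[1]][1]
  orient <- if (first == "1") 1 else -1
  # margin errors (active slack) have their multiplier at the upper bound;
  # free support vectors sit strictly inside (0, C)
  cmax <- max(abs(fit$coefs))
  margin_err <- sum(abs(fit$coefs) >= cmax * (1 - 1e-9)) / ne
  sv_frac <- fit$tot.nSV / ne

  dec_orig <- orient * attr(predict(fit, X, decision.values = TRUE),
                            "decision.values")[, 1]
  platt <- platt_fit(dec_orig, y)

  structure(list(svm = fit, platt = platt, orient = orient, gamma = gamma,
                 nu = config$nu, sv_fraction = sv_frac,
                 margin_error_fraction = margin_err,
                 n_support = fit$tot.nSV),
            class = "nu_svc_fit")
}

# Platt (1999)-style sigmoid calibration on decision values, with the
# prior-corrected targets t1 = (N1+1)/(N1+2), t0 = 1/(N0+2)
platt_fit <- function(dec, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  t <- ifelse(y == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  softplus <- function(u) ifelse(u > 30, u, log1p(exp(pmin(u, 30))))
  nll <- function(p) {
    z <- p[1] * dec + p[2]
    # numerically stable cross-entropy
    sum((1 - t) * z + softplus(-z))
  }
  opt <- optim(c(1, 0), nll, method = "BFGS")
  list(a = opt$par[1], b = opt$par[2])
}

platt_apply <- function(platt, dec) plogis(platt$a * dec + platt$b)

#' @export
predict.nu_svc_fit <- function(object, newdata, ...) {
  dec <- object$orient *
    attr(predict(object$svm, as.matrix(newdata), decision.values = TRUE),
         "decision.values")[, 1]
  unname(platt_apply(object$platt, dec))
}

#' Train the full mortality model on a raw feature matrix
#'
#' Chains the training-side operations: median imputation and z-scoring,
#' class-weighted L1 feature selection, and a class-weighted nu-SVC with
#' Platt-calibrated probabilities. All fitted parameters are reused verbatim
#' at prediction time.
#'
#' @param x A `feature_matrix` (or raw numeric matrix with column names).
#' @param labels 0/1 outcomes (taken from `x` when it is a `feature_matrix`).
#' @param config A [model_config()].
#' @return Object of class `mortality_model`.
#' @export
train_mortality_model <- function(x, labels = NULL, config = model_config()) {
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  y <- if (is.null(labels) && inherits(x, "feature_matrix")) x$label else
    as.integer(labels)
  tr <- impute_and_standardize(X)
  w <- class_weights(y)
  sel <- l1_select(tr$train, y, C_sel = config$C_sel, weights = w,
                   screen = config$screen)
  fit <- fit_nu_svc(tr$train[, sel$selected, drop = FALSE], y, config, w)
  structure(list(feature_names = colnames(X), medians = tr$medians,
                 centers = tr$centers, scales = tr$scales,
                 selection = sel, fit = fit, weights = w, config = config),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat(sprintf("<mortality_model> %d/%d features selected, nu=%.2f (%s kernel), SV frac %.2f\n",
              length(x$selection$selected), length(x$feature_names),
              x$config$nu, x$config$kernel, x$fit$sv_fraction))
  invisible(x)
}

#' Predicted mortality probability
#'
#' Applies the stored imputation, standardization, selection, and calibrated
#' classifier to new patients. Probabilities lie in `[0, 1]` and are monotone
#' in the classifier's decision value.
#'
#' @param model A `mortality_model`.
#' @param x Raw feature matrix (or `feature_matrix`) with the training
#'   columns.
#' @return Numeric vector of `Pr(expired)` per patient.
#' @export
predict_proba <- function(model, x) {
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  if (!identical(colnames(X), model$feature_names))
    stop("schema error: feature columns do not match the training schema",
         call. = FALSE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- model$medians[idx[, 2]]
  Z <- sweep(sweep(X, 2, model$centers), 2, model$scales, "/")
  predict(model$fit, Z[, model$selection$selected, drop = FALSE])
}

#' @export
predict.mortality_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' Stratified fold assignment
#'
#' Deals the shuffled members of each class round-robin over folds, so every
#' fold preserves the class proportion within one sample.
#'
#' @param labels 0/1 labels.
#' @param folds Number of folds.
#' @return Integer fold id per observation.
#' @export
stratified_folds <- function(labels, folds) {
  labels <- as.integer(labels)
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < folds)
      stop(sprintf("stratification error: class %d has %d members for %d folds",
                   cl, length(ix), folds), call. = FALSE)
    id[ix[sample.int(length(ix))]] <- rep_len(seq_len(folds), length(ix))
  }
  id
}

#' Area under the ROC curve
#'
#' @param labels 0/1 outcomes.
#' @param prob Predicted probability (or any score monotone in it).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, prob) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = prob,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Stratified k-fold cross-validated evaluation
#'
#' Per fold: imputation/standardization, L1 selection, and the nu-SVC fit all
#' use the training folds only; the held-out fold is scored with the fitted
#' transforms. Reports per-fold AUC, their mean, and the pooled AUC of the
#' out-of-fold probabilities.
#'
#' @param x A `feature_matrix`.
#' @param labels 0/1 outcomes (default: from `x`).
#' @param config A [model_config()]; `config$seed` seeds the fold assignment.
#' @return Object of class `cv_result`: `fold` assignment, `oof_prob`,
#'   `fold_auc`, `mean_auc`, `pooled_auc`, `selected` (per fold), `seed`.
#' @export
stratified_cv <- function(x, labels = NULL, config = model_config()) {
  y <- if (is.null(labels) && inherits(x, "feature_matrix")) x$label else
    as.integer(labels)
  X <- if (inherits(x, "feature_matrix")) x$X else as.matrix(x)
  if (!is.null(config$seed)) set.seed(config$seed)
  fold <- stratified_folds(y, config$folds)
  oof <- rep(NA_real_, length(y))
  fold_auc <- numeric(config$folds)
  selected <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr_ix <- fold != f
    tr <- impute_and_standardize(X[tr_ix, , drop = FALSE],
                                 X[!tr_ix, , drop = FALSE])
    ytr <- y[tr_ix]
    w <- class_weights(ytr)
    sel <- l1_select(tr$train, ytr, C_sel = config$C_sel, weights = w,
                     screen = config$screen)
    fit <- fit_nu_svc(tr$train[, sel$selected, drop = FALSE], ytr, config, w)
    p <- predict(fit, tr$apply[, sel$selected, drop = FALSE])
    oof[!tr_ix] <- p
    fold_auc[f] <- auc_score(y[!tr_ix], p)
    selected[[f]] <- sel$selected
  }
  structure(list(fold = fold, oof_prob = oof, fold_auc = fold_auc,
                 mean_auc = mean(fold_auc),
                 pooled_auc = auc_score(y, oof),
                 selected = selected, labels = y, seed = config$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: mean AUC %.3f (folds: %s), pooled AUC %.3f\n",
              length(x$fold_auc), x$mean_auc,
              paste(sprintf("%.3f", x$fold_auc), collapse = ", "),
              x$pooled_auc))
  invisible(x)
}

#' Aggregate feature importance by vital and technique
#'
#' Parses each selected feature name into its (vital, technique) cell and
#' sums the importance mass (|coefficient| of the linear selection fit) per
#' cell. Cell sums conserve the total importance.
#'
#' @param importance Named numeric vector of per-feature importance (e.g.
#'   `abs(selection$coef)`), or an `l1_selection` / `mortality_model`.
#' @return Object of class `importance_table`: vitals x techniques matrix
#'   (fft, psd, ac, wt, stat, sudden), all entries >= 0.
#' @export
aggregate_importance <- function(importance) {
  if (inherits(importance, "mortality_model"))
    importance <- importance$selection
  if (inherits(importance, "l1_selection"))
    importance <- abs(importance$coef)
  if (is.null(names(importance)))
    stop("importance must be named by feature", call. = FALSE)
  tab <- matrix(0, length(VITALS), length(TECHNIQUES),
                dimnames = list(VITALS, TECHNIQUES))
  for (i in seq_along(importance)) {
    p <- parse_feature_name(names(importance)[i])
    tab[p$vital, p$technique] <- tab[p$vital, p$technique] + abs(importance[i])
  }
  structure(tab, class = c("importance_table", "matrix", "array"))
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> importance mass by vital x technique\n")
  print(unclass(round(x, 4)))
  invisible(x)
}
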