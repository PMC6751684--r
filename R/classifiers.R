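#' The classifier roster
#'
#' Eight classifier families of two typologies are used to build the
#' ensemble: tree ensembles (gradient boosting, random forest, bagged
#' trees), whose feature importance is the split-use frequency, and linear
#' models (logistic regression, passive-aggressive, SGD with hinge loss,
#' linear-kernel SVC, ridge), whose importance is coefficient magnitude.
#' Tree ensembles default to 300 predictors; the support-vector classifier
#' uses a linear kernel; everything else runs on library defaults.
#'
#' @return Character vector of the supported family names.
#' @export
classifier_families <- function() {
  c("gradient_boosting", "random_forest", "logistic_regression",
    "passive_aggressive", "sgd_linear", "svc_linear", "ridge",
    "bagging_trees")
}

tree_families <- function() c("gradient_boosting", "random_forest", "bagging_trees")

#' Fit one classifier instance
#'
#' Fits a single classifier of the given family on a (standardized)
#' training matrix. The returned object carries its typology, the fitted
#' model, and — for linear families — the classes x features coefficient
#' matrix, so importance extraction and prediction are uniform across
#' families.
#'
#' @param family One of [classifier_families()].
#' @param X Numeric matrix, samples x features (standardized).
#' @param y Class labels, one per row of `X`.
#' @param params Named list of hyperparameter overrides. Recognised:
#'   `n_estimators` (tree ensembles, default 300), `max_depth` and `eta`
#'   (gradient boosting), `cost` (SVC and passive-aggressive C),
#'   `lambda` (ridge / logistic regularization), `alpha`, `eta0` and
#'   `epochs` (online linear models).
#' @param seed Integer seed controlling any randomness in the fit.
#' @return Object of class `mirsign_classifier`.
#' @export
fit_classifier <- function(family, X, y, params = list(), seed = 0L) {
  family <- match.arg(family, classifier_families())
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("need at least 2 classes")
  fitter <- switch(family,
    gradient_boosting = fit_gradient_boosting,
    random_forest = function(...) fit_ranger(..., bagging = FALSE),
    bagging_trees = function(...) fit_ranger(..., bagging = TRUE),
    logistic_regression = fit_logistic,
    ridge = fit_ridge,
    svc_linear = fit_svc_ovr,
    passive_aggressive = function(...) fit_online_linear(..., loss = "pa"),
    sgd_linear = function(...) fit_online_linear(..., loss = "sgd"))
  obj <- fitter(X = X, y = y, lev = lev, params = params, seed = seed)
  obj$family <- family
  obj$levels <- lev
  obj$feature_names <- colnames(X)
  class(obj) <- "mirsign_classifier"
  obj
}

#' Per-feature importance of a fitted classifier
#'
#' Dispatches by typology: split counting for tree ensembles
#' ([importance_from_tree_ensemble()]), summed absolute coefficients for
#' linear models ([importance_from_linear_coefficients()]).
#'
#' @param object A `mirsign_classifier`.
#' @param feature_names Feature names; defaults to those seen at fit time.
#' @return An `importance_vector`.
#' @export
classifier_importance <- function(object, feature_names = object$feature_names) {
  switch(object$typology,
    tree_ensemble = importance_from_tree_ensemble(
      extract_tree_splits(object$model, feature_names), feature_names),
    linear = importance_from_linear_coefficients(
      unname(object$coefficients), feature_names),
    precomputed = importance_vector(object$importance[feature_names],
                                    feature_names, "precomputed"),
    stop("unknown typology: ", object$typology))
}

#' @export
predict.mirsign_classifier <- function(object, newdata, ...) {
  object$predict_fun(newdata)
}

## -- tree ensembles ---------------------------------------------------------

fit_gradient_boosting <- function(X, y, lev, params, seed) {
  n_estimators <- params$n_estimators %||% 300L
  max_depth <- params$max_depth %||% 3L
  eta <- params$eta %||% 0.1
  codes <- match(y, lev) - 1L
  dtrain <- xgboost::xgb.DMatrix(X, label = codes, nthread = 1)
  xgb_params <- list(max_depth = max_depth, eta = eta, nthread = 1,
                     tree_method = "hist",
                     seed = as.integer(seed %% 2147483647))
  if (length(lev) > 2L) {
    xgb_params$objective <- "multi:softmax"
    xgb_params$num_class <- length(lev)
  } else {
    xgb_params$objective <- "binary:logistic"
  }
  model <- xgboost::xgb.train(params = xgb_params, data = dtrain,
                              nrounds = n_estimators, verbose = 0)
  pred_fun <- function(newdata) {
    p <- predict(model, xgboost::xgb.DMatrix(newdata, nthread = 1))
    if (length(lev) > 2L) lev[p + 1L] else lev[(p > 0.5) + 1L]
  }
  list(typology = "tree_ensemble", model = model, predict_fun = pred_fun)
}

fit_ranger <- function(X, y, lev, params, seed, bagging) {
  n_estimators <- params$n_estimators %||% 300L
  mtry <- if (bagging) ncol(X) else floor(sqrt(ncol(X)))
  df <- data.frame(..y = factor(y, levels = lev), X, check.names = FALSE)
  model <- ranger::ranger(dependent.variable.name = "..y", data = df,
                          num.trees = n_estimators, mtry = mtry,
                          seed = as.integer(seed %% 2147483647),
                          num.threads = 1, verbose = FALSE)
  pred_fun <- function(newdata) {
    nd <- data.frame(newdata, check.names = FALSE)
    as.character(predict(model, data = nd, num.threads = 1)$predictions)
  }
  list(typology = "tree_ensemble", model = model, predict_fun = pred_fun)
}

## -- linear models ----------------------------------------------------------

fit_logistic <- function(X, y, lev, params, seed) {
  lambda <- params$lambda %||% 1e-3
  fam <- if (length(lev) > 2L) "multinomial" else "binomial"
  # fit along a decreasing path down to the target lambda: glmnet's warm
  # starts make the small-lambda solution far more reliable than a one-off
  path <- exp(seq(log(1), log(lambda), length.out = 20L))
  model <- glmnet::glmnet(X, factor(y, levels = lev), family = fam,
                          alpha = 0, lambda = path, standardize = FALSE)
  cf <- stats::coef(model, s = lambda)
  B <- if (is.list(cf)) t(sapply(cf, function(b) as.numeric(b)[-1L]))
       else rbind(as.numeric(cf)[-1L])
  colnames(B) <- colnames(X)
  pred_fun <- function(newdata) {
    p <- predict(model, newx = newdata, type = "class", s = lambda)
    as.character(p[, 1L])
  }
  list(typology = "linear", model = model, coefficients = B,
       predict_fun = pred_fun)
}

fit_ridge <- function(X, y, lev, params, seed) {
  lambda <- params$lambda %||% 1
  # one-vs-rest ridge regression on +/-1 targets, closed form
  Y <- sapply(lev, function(cl) ifelse(y == cl, 1, -1))
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + lambda
  B <- solve(XtX, crossprod(X, Y))             # features x classes
  b0 <- colMeans(Y) - colMeans(X) %*% B
  coefs <- t(B)
  colnames(coefs) <- colnames(X)
  pred_fun <- function(newdata) {
    scores <- sweep(newdata %*% B, 2L, as.numeric(b0), "+")
    lev[max.col(scores, ties.method = "first")]
  }
  list(typology = "linear", coefficients = coefs, predict_fun = pred_fun)
}

fit_svc_ovr <- function(X, y, lev, params, seed) {
  cost <- params$cost %||% 1
  fits <- lapply(lev, function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(X, yb, kernel = "linear", cost = cost, scale = FALSE)
    w <- as.numeric(crossprod(m$coefs, m$SV))  # 1 x features
    rho <- m$rho
    # e1071's decision-value sign follows the class order seen in training;
    # orient so the positive class scores higher
    dec <- X %*% w - rho
    if (mean(dec[y == cl]) < mean(dec[y != cl])) { w <- -w; rho <- -rho }
    list(w = w, rho = rho)
  })
  W <- do.call(rbind, lapply(fits, `[[`, "w"))  # classes x features
  rho <- vapply(fits, `[[`, numeric(1), "rho")
  colnames(W) <- colnames(X)
  pred_fun <- function(newdata) {
    scores <- sweep(newdata %*% t(W), 2L, rho)  # decision value per class
    lev[max.col(scores, ties.method = "first")]
  }
  list(typology = "linear", coefficients = W, predict_fun = pred_fun)
}

# Online one-vs-rest linear classifiers trained by epochs of single-sample
# updates: passive-aggressive (PA-I) or SGD on the hinge loss with L2 decay.
fit_online_linear <- function(X, y, lev, params, seed, loss) {
  epochs <- params$epochs %||% 5L
  C <- params$cost %||% 1
  alpha <- params$alpha %||% 1e-4
  eta0 <- params$eta0 %||% 0.01
  n <- nrow(X); p <- ncol(X)
  rng <- local_rng(seed)
  W <- matrix(0, length(lev), p)
  b <- numeric(length(lev))
  Yb <- sapply(lev, function(cl) ifelse(y == cl, 1, -1))  # n x classes
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    for (i in rng$sample_int(n)) {
      t_step <- t_step + 1L
      x <- X[i, ]
      margins <- as.numeric(W %*% x + b) * Yb[i, ]
      for (c in which(margins < 1)) {
        yc <- Yb[i, c]
        if (loss == "pa") {
          tau <- min(C, (1 - margins[c]) / (sum(x * x) + 1))
          W[c, ] <- W[c, ] + tau * yc * x
          b[c] <- b[c] + tau * yc
        } else {
          eta <- eta0 / (1 + alpha * eta0 * t_step)
          W[c, ] <- (1 - eta * alpha) * W[c, ] + eta * yc * x
          b[c] <- b[c] + eta * yc
        }
      }
      if (loss == "sgd") {
        ok <- which(margins >= 1)
        if (length(ok)) {
          eta <- eta0 / (1 + alpha * eta0 * t_step)
          W[ok, ] <- (1 - eta * alpha) * W[ok, ]
        }
      }
    }
  }
  colnames(W) <- colnames(X)
  pred_fun <- function(newdata) {
    scores <- sweep(newdata %*% t(W), 2L, -b)
    lev[max.col(scores, ties.method = "first")]
  }
  list(typology = "linear", coefficients = W, predict_fun = pred_fun)
}
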