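# Penalized functional multi-response linear regression: jointly predicts
# selection parameters (selection coefficient s, initial beneficial-allele
# frequency f, onset or split time T) from wavelet coefficient vectors.

#' Fit the functional multi-response predictor
#'
#' Models each (transformed) selection parameter as an affine function of
#' the wavelet coefficient vector,
#' \eqn{\sigma_\ell = \alpha_\ell + \xi^T \zeta_\ell + \epsilon_\ell}, with
#' the summed squared-error loss over responses and the same elastic-net
#' penalty as the classifier. The fit is joint across responses (glmnet
#' `mgaussian`: one lambda, grouped penalty). Responses listed in
#' `log_cols` are log10-transformed first (the selection coefficient and
#' initial frequency always should be; they must be positive); every
#' transformed response is then standardized to training mean 0, SD 1.
#' `(gamma, j0, lambda)` are chosen by seeded stratification-free k-fold CV
#' minimizing the mean held-out squared error summed over responses, with
#' the same tie-breaks as the classifier, then refitted on all data.
#'
#' @param features List of unstandardized [feature_curves()].
#' @param responses Data frame of numeric responses (e.g. columns `s`, `f`,
#'   `T`), one row per observation.
#' @param log_cols Response columns to log10-transform before fitting;
#'   defaults to the intersection of `names(responses)` with
#'   `c("s", "f", "T", "T_sel", "T_split")`.
#' @inheritParams fit_classifier
#' @return An object of class `"sweepwave_predictor"` with elements
#'   `responses`, `alpha`, `Z`, `gamma`, `lambda`, `j0`, `wavelet`,
#'   `standardization`, `response_scaling`, `cv_report`, plus stored
#'   training residuals on the standardized log scale.
#' @seealso [predict.sweepwave_predictor()], [evaluate_predictions()]
#' @export
fit_predictor <- function(features, responses,
                          gamma_grid = seq(0, 1, by = 0.1),
                          level_grid = NULL, folds = 10L, seed = 1L,
                          family = c("daubechies_least_asymmetric", "haar"),
                          vanishing_moments = 8L, include_2d = NULL,
                          nlambda = 50L, log_cols = NULL, ...) {
  family <- match.arg(family)
  fcs <- as_fc_list(features)
  responses <- as.data.frame(responses)
  if (nrow(responses) != length(fcs)) {
    stop("responses and features lengths differ", call. = FALSE)
  }
  if (nrow(responses) < folds) {
    stop("need at least ", folds, " observations for ", folds, "-fold CV",
         call. = FALSE)
  }
  if (!all(vapply(responses, is.numeric, logical(1))) ||
      anyNA(responses) || any(!is.finite(as.matrix(responses)))) {
    stop("responses must be finite numerics", call. = FALSE)
  }
  if (is.null(log_cols)) {
    log_cols <- intersect(names(responses), c("s", "f", "T", "T_sel",
                                              "T_split"))
  }
  if (any(vapply(responses[log_cols], function(v) any(v <= 0), logical(1)))) {
    stop("log-transformed responses must be positive", call. = FALSE)
  }
  Ylog <- as.matrix(responses)
  for (cl in log_cols) Ylog[, cl] <- log10(Ylog[, cl])
  mu <- colMeans(Ylog)
  sdv <- apply(Ylog, 2, stats::sd)
  all_constant <- all(sdv == 0)
  sdv[sdv == 0] <- 1
  Y <- sweep(sweep(Ylog, 2, mu), 2, sdv, `/`)

  p <- ncol(fcs[[1]]$curves)
  if (length(gamma_grid) == 0) stop("empty gamma grid", call. = FALSE)
  if (is.null(level_grid)) level_grid <- candidate_levels(p)
  if (length(level_grid) == 0) stop("empty level grid", call. = FALSE)
  if (is.null(include_2d)) {
    include_2d <- all(vapply(fcs, function(f) !is.null(f$twod), logical(1)))
  }
  fold <- with_seed(seed,
                    sample(rep(seq_len(folds), length.out = length(fcs))))

  if (all_constant) {
    # zero-variance targets: the penalized fit is an intercept-only model
    spec <- wavelet_spec(family, vanishing_moments, j0 = level_grid[1],
                         p = p)
    sp_full <- suppressWarnings(fit_standardization(fcs))
    X_full <- build_xi_matrix(fcs, sp_full, spec, include_2d)
    Z <- matrix(0, ncol(X_full), ncol(Y),
                dimnames = list(colnames(X_full), colnames(Y)))
    alpha <- stats::setNames(numeric(ncol(Y)), colnames(Y))
    return(structure(
      list(responses = colnames(Y), alpha = alpha, Z = Z,
           gamma = gamma_grid[1], lambda = Inf, j0 = level_grid[1],
           wavelet = spec, standardization = sp_full,
           response_scaling = list(log_cols = log_cols, log_base = 10,
                                   mean = mu, sd = sdv),
           include_2d = include_2d, p = p, folds = folds, seed = seed,
           cv_report = data.frame(gamma = gamma_grid[1],
                                  j0 = level_grid[1], lambda = Inf,
                                  cv_mse = 0),
           cv_mse = 0, train_norm_max = max(sqrt(rowSums(X_full^2))),
           residuals_std = Y, call = match.call()),
      class = "sweepwave_predictor"))
  }

  # glmnet's grouped multi-response family needs >= 2 responses; a single
  # response is the same objective under the plain gaussian family
  mg_fit <- function(x, y, alpha, ...) {
    if (ncol(y) == 1) {
      glmnet::glmnet(x, y[, 1], family = "gaussian", alpha = alpha,
                     standardize = FALSE, ...)
    } else {
      glmnet::glmnet(x, y, family = "mgaussian", alpha = alpha,
                     standardize = FALSE, standardize.response = FALSE, ...)
    }
  }
  mg_predict <- function(fit, newx, s, q) {
    pr <- predict(fit, newx = newx, s = s)
    if (q == 1) pr <- array(pr, dim = c(nrow(pr), 1, ncol(pr)))
    pr
  }
  mg_coef <- function(fit, s, q, names_q) {
    cf <- stats::coef(fit, s = s)
    if (q == 1) cf <- stats::setNames(list(cf), names_q)
    cf
  }

  report <- NULL
  for (j0 in level_grid) {
    spec <- wavelet_spec(family, vanishing_moments, j0 = j0, p = p)
    sp_full <- suppressWarnings(fit_standardization(fcs))
    X_full <- build_xi_matrix(fcs, sp_full, spec, include_2d)
    fold_X <- lapply(seq_len(folds), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      sp <- suppressWarnings(fit_standardization(fcs[tr]))
      list(train = build_xi_matrix(fcs[tr], sp, spec, include_2d),
           test = build_xi_matrix(fcs[te], sp, spec, include_2d),
           tr = tr, te = te)
    })
    for (gamma in gamma_grid) {
      path <- mg_fit(X_full, Y, alpha = gamma, nlambda = nlambda,
                     ...)$lambda
      sse <- matrix(0, folds, length(path))
      for (f in seq_len(folds)) {
        fd <- fold_X[[f]]
        fit <- mg_fit(fd$train, Y[fd$tr, , drop = FALSE], alpha = gamma,
                      lambda = path, ...)
        pred <- mg_predict(fit, fd$test, path, ncol(Y))  # n_te x q x n_s
        truth <- Y[fd$te, , drop = FALSE]
        sse[f, ] <- apply(pred, 3, function(ph) sum((ph - truth)^2))
      }
      mse <- colSums(sse) / length(fcs)
      best <- which.min(mse)  # first index on ties -> larger lambda
      report <- rbind(report, data.frame(
        gamma = gamma, j0 = j0, lambda = path[best], score = -mse[best]))
    }
  }
  sel <- select_best(report)
  spec <- wavelet_spec(family, vanishing_moments, j0 = sel$j0, p = p)
  sp_full <- suppressWarnings(fit_standardization(fcs))
  X_full <- build_xi_matrix(fcs, sp_full, spec, include_2d)
  # explicit lambda sequence: see the matching comment in fit_classifier
  lam <- mg_fit(X_full, Y, alpha = sel$gamma, nlambda = nlambda, ...)$lambda
  path <- mg_fit(X_full, Y, alpha = sel$gamma, lambda = lam, ...)
  cf <- mg_coef(path, s = sel$lambda, q = ncol(Y), names_q = colnames(Y))
  Z <- do.call(cbind, lapply(cf, function(b) as.numeric(b)[-1]))
  alpha <- vapply(cf, function(b) as.numeric(b)[1], numeric(1))
  colnames(Z) <- colnames(Y)
  names(alpha) <- colnames(Y)
  rownames(Z) <- colnames(X_full)
  fitted_std <- sweep(X_full %*% Z, 2, alpha, `+`)
  report$cv_mse <- -report$score
  report$score <- NULL
  # norm envelope used to warn about extrapolation at prediction time
  xi_norms <- sqrt(rowSums(X_full^2))
  structure(
    list(responses = colnames(Y), alpha = alpha, Z = Z,
         gamma = sel$gamma, lambda = sel$lambda, j0 = sel$j0,
         wavelet = spec, standardization = sp_full,
         response_scaling = list(log_cols = log_cols, log_base = 10,
                                 mean = mu, sd = sdv),
         include_2d = include_2d, p = p, folds = folds, seed = seed,
         cv_report = report, cv_mse = -sel$score,
         train_norm_max = max(xi_norms),
         residuals_std = Y - fitted_std,
         call = match.call()),
    class = "sweepwave_predictor"
  )
}

#' Transform responses to / from the fitting scale
#'
#' `transform_responses()` maps natural-scale responses to the standardized
#' log scale a fitted predictor works on; `back_transform_responses()` is
#' its exact inverse.
#'
#' @param y Data frame or matrix of responses (columns matching the model).
#' @param scaling The `response_scaling` element of a fitted predictor.
#' @return Matrix on the transformed (or natural) scale.
#' @export
transform_responses <- function(y, scaling) {
  y <- as.matrix(y)
  for (cl in intersect(colnames(y), scaling$log_cols)) {
    y[, cl] <- log(y[, cl], base = scaling$log_base)
  }
  sweep(sweep(y, 2, scaling$mean[colnames(y)]), 2,
        scaling$sd[colnames(y)], `/`)
}

#' @rdname transform_responses
#' @export
back_transform_responses <- function(y, scaling) {
  y <- as.matrix(y)
  y <- sweep(sweep(y, 2, scaling$sd[colnames(y)], `*`), 2,
             scaling$mean[colnames(y)], `+`)
  for (cl in intersect(colnames(y), scaling$log_cols)) {
    y[, cl] <- scaling$log_base^y[, cl]
  }
  y
}

#' Predict selection parameters
#'
#' Affine prediction on the standardized log scale, then unstandardized and
#' back-transformed per the model's response scaling. Inputs whose
#' coefficient-vector norm exceeds the training envelope trigger a warning
#' (accuracy degrades outside the training range); they are not clipped.
#'
#' @param object A fitted [fit_predictor()].
#' @param newdata A [feature_curves()] or list of them (unstandardized).
#' @param scale `"natural"` (default), `"log"` (log-transformed, not
#'   standardized), or `"standardized"`.
#' @param ... Unused.
#' @return Data frame of predictions, one column per response.
#' @export
predict.sweepwave_predictor <- function(object, newdata,
                                        scale = c("natural", "log",
                                                  "standardized"), ...) {
  scale <- match.arg(scale)
  fcs <- as_fc_list(newdata)
  X <- build_xi_matrix(fcs, object$standardization, object$wavelet,
                       object$include_2d)
  if (ncol(X) != nrow(object$Z)) {
    stop("feature dimension ", ncol(X), " does not match the model (",
         nrow(object$Z), ")", call. = FALSE)
  }
  if (max(sqrt(rowSums(X^2))) > 1.5 * object$train_norm_max) {
    warning("input lies outside the training envelope; predictions may be ",
            "unreliable", call. = FALSE)
  }
  std <- sweep(X %*% object$Z, 2, object$alpha, `+`)
  colnames(std) <- object$responses
  out <- switch(scale,
    standardized = std,
    log = {
      sc <- object$response_scaling
      sweep(sweep(std, 2, sc$sd, `*`), 2, sc$mean, `+`)
    },
    natural = back_transform_responses(std, object$response_scaling))
  as.data.frame(out)
}

#' RMSE and MAE of parameter predictions
#'
#' Root mean squared error and mean absolute error per response, on
#' whatever common scale `pred` and `truth` are supplied (use
#' [transform_responses()] to move between scales). MAE never exceeds RMSE.
#'
#' @param pred,truth Data frames or matrices of equal dimension.
#' @return Data frame with columns `response`, `rmse`, `mae`.
#' @examples
#' evaluate_predictions(data.frame(x = c(0, 0)), data.frame(x = c(3, 4)))
#' @export
evaluate_predictions <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("pred and truth dimensions differ", call. = FALSE)
  }
  err <- pred - truth
  rmse <- sqrt(colMeans(err^2))
  mae <- colMeans(abs(err))
  stopifnot(all(mae <= rmse + 1e-12))
  data.frame(response = colnames(pred), rmse = unname(rmse),
             mae = unname(mae), row.names = NULL)
}

#' @export
print.sweepwave_predictor <- function(x, ...) {
  cat("Functional multi-response predictor (elastic net, wavelet domain)\n")
  cat("  responses:", paste(x$responses, collapse = ", "),
      sprintf("(log10: %s)",
              paste(x$response_scaling$log_cols, collapse = ", ")), "\n")
  cat(sprintf("  basis: %s, j0 = %d, p = %d%s\n", x$wavelet$family, x$j0,
              x$p, if (x$include_2d) " (+ 2-D r2 blocks)" else ""))
  cat(sprintf("  selected gamma = %g, lambda = %.4g (CV MSE %.4f)\n",
              x$gamma, x$lambda, x$cv_mse))
  invisible(x)
}

#' @export
summary.sweepwave_predictor <- function(object, ...) {
  print(object)
  cat("\nTraining residual SD (standardized log scale):\n")
  print(apply(object$residuals_std, 2, stats::sd))
  invisible(object)
}

#' @export
coef.sweepwave_predictor <- function(object, ...) {
  list(alpha = object$alpha, Z = object$Z)
}

#' @export
residuals.sweepwave_predictor <- function(object, ...) {
  object$residuals_std
}

#' @rdname plot.sweepwave_classifier
#' @export
plot.sweepwave_predictor <- function(x, ...) {
  plot.sweepwave_classifier(x, ...)
}
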