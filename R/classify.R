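# Penalized functional multinomial regression: elastic-net multinomial fit
# in the wavelet domain, with nested cross-validation over the elastic-net
# mixing parameter gamma, the truncation level j0, and the penalty weight
# lambda.

#' Fit the functional multinomial classifier
#'
#' Models the class probability of a genomic region as a softmax over linear
#' scores \eqn{\alpha_k + \xi^T \zeta_k}, where \eqn{\xi} is the
#' concatenation of the wavelet coefficient segments of the standardized
#' summary-statistic curves. The penalty mixes lasso and ridge:
#' \eqn{\sum_k \gamma \|\zeta_k\|_1 + (1-\gamma) \|\zeta_k\|_2^2}, weighted
#' by \eqn{\lambda}.
#'
#' For every `(gamma, j0)` pair the model runs seeded, class-stratified
#' k-fold cross-validation: standardization is estimated on the training
#' folds only, both folds are transformed to the wavelet domain, an
#' elastic-net multinomial path is fitted (glmnet), and held-out
#' classification accuracy is recorded along the `lambda` path. The
#' combination with the highest mean CV accuracy wins (ties prefer smaller
#' `j0`, then larger `gamma`, then larger `lambda`) and is refitted on the
#' full training set.
#'
#' @param features List of unstandardized [feature_curves()].
#' @param labels Class labels (factor or character), one per observation;
#'   the neutral class should be labelled `"neutral"` for thresholded calls.
#' @param gamma_grid Elastic-net mixing values in `[0, 1]`
#'   (default `seq(0, 1, 0.1)`).
#' @param level_grid Truncation levels to search (default
#'   [candidate_levels()] for the curve length).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment (the only source of
#'   randomness; the fit is reproducible given the seed).
#' @param family,vanishing_moments Wavelet basis options, see
#'   [wavelet_spec()].
#' @param include_2d Use the r-squared moment blocks as additional
#'   covariates; defaults to `TRUE` when every observation carries them.
#' @param nlambda Length of the automatic `lambda` path.
#' @param ... Further arguments passed to [glmnet::glmnet()] (e.g. `thresh`).
#' @return An object of class `"sweepwave_classifier"` with elements
#'   `classes`, `alpha` (intercepts), `Z` (wavelet-domain coefficient
#'   matrix, one column per class), `gamma`, `lambda`, `j0`, `wavelet`,
#'   `standardization`, `cv_report`, and `class_proportions`.
#' @seealso [predict.sweepwave_classifier()], [call_class()],
#'   [coefficient_functions()], [reliability_curve()]
#' @export
fit_classifier <- function(features, labels,
                           gamma_grid = seq(0, 1, by = 0.1),
                           level_grid = NULL, folds = 10L, seed = 1L,
                           family = c("daubechies_least_asymmetric", "haar"),
                           vanishing_moments = 8L, include_2d = NULL,
                           nlambda = 50L, ...) {
  family <- match.arg(family)
  fcs <- as_fc_list(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  if (length(labels) != length(fcs)) {
    stop("labels and features lengths differ", call. = FALSE)
  }
  if (length(gamma_grid) == 0 || length(unique(table(labels))) > 1) {
    if (length(gamma_grid) == 0) stop("empty gamma grid", call. = FALSE)
    warning("unbalanced classes; balanced training data is recommended",
            call. = FALSE)
  }
  p <- ncol(fcs[[1]]$curves)
  if (is.null(level_grid)) level_grid <- candidate_levels(p)
  if (length(level_grid) == 0) stop("empty level grid", call. = FALSE)
  if (is.null(include_2d)) {
    include_2d <- all(vapply(fcs, function(f) !is.null(f$twod), logical(1)))
  }
  fold <- stratified_folds(labels, folds, seed)

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
      path <- glmnet::glmnet(X_full, labels, family = "multinomial",
                             alpha = gamma, nlambda = nlambda,
                             standardize = FALSE, ...)$lambda
      correct <- matrix(0, folds, length(path))
      for (f in seq_len(folds)) {
        fd <- fold_X[[f]]
        fit <- glmnet::glmnet(fd$train, labels[fd$tr],
                              family = "multinomial", alpha = gamma,
                              lambda = path, standardize = FALSE, ...)
        pred <- predict(fit, newx = fd$test, s = path, type = "class")
        correct[f, ] <- colSums(pred == as.character(labels[fd$te]))
      }
      acc <- colSums(correct) / length(labels)
      best <- which.max(acc)  # first index on ties -> larger lambda
      report <- rbind(report, data.frame(
        gamma = gamma, j0 = j0, lambda = path[best], score = acc[best]))
    }
  }
  sel <- select_best(report)
  spec <- wavelet_spec(family, vanishing_moments, j0 = sel$j0, p = p)
  sp_full <- suppressWarnings(fit_standardization(fcs))
  X_full <- build_xi_matrix(fcs, sp_full, spec, include_2d)
  # refit with the lambda sequence given explicitly: glmnet's automatic
  # path stores the null model at its head, while explicit sequences are
  # solved exactly (as the CV fold fits were)
  lam <- glmnet::glmnet(X_full, labels, family = "multinomial",
                        alpha = sel$gamma, nlambda = nlambda,
                        standardize = FALSE, ...)$lambda
  path <- glmnet::glmnet(X_full, labels, family = "multinomial",
                         alpha = sel$gamma, lambda = lam,
                         standardize = FALSE, ...)
  cf <- stats::coef(path, s = sel$lambda)
  Z <- do.call(cbind, lapply(cf, function(b) as.numeric(b)[-1]))
  alpha <- vapply(cf, function(b) as.numeric(b)[1], numeric(1))
  colnames(Z) <- names(cf)
  rownames(Z) <- colnames(X_full)
  names(report)[names(report) == "score"] <- "cv_accuracy"
  structure(
    list(classes = levels(labels), alpha = alpha, Z = Z,
         gamma = sel$gamma, lambda = sel$lambda, j0 = sel$j0,
         wavelet = spec, standardization = sp_full,
         include_2d = include_2d, p = p, folds = folds, seed = seed,
         cv_report = report, cv_accuracy = sel$score,
         class_proportions = as.numeric(table(labels)) / length(labels),
         call = match.call()),
    class = "sweepwave_classifier"
  )
}

classifier_eta <- function(object, features) {
  fcs <- as_fc_list(features)
  X <- build_xi_matrix(fcs, object$standardization, object$wavelet,
                       object$include_2d)
  if (ncol(X) != nrow(object$Z)) {
    stop("feature dimension ", ncol(X), " does not match the model (",
         nrow(object$Z), ")", call. = FALSE)
  }
  eta <- X %*% object$Z
  sweep(eta, 2, object$alpha, `+`)
}

softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

#' Predict class probabilities or thresholded calls
#'
#' @param object A fitted [fit_classifier()] model.
#' @param newdata A [feature_curves()] or a list of them (unstandardized;
#'   the model applies its own frozen standardization).
#' @param type `"prob"` for softmax class probabilities (rows sum to 1),
#'   `"class"` for thresholded calls via [call_class()], `"link"` for the
#'   linear scores.
#' @param threshold Sweep-probability threshold used when `type = "class"`.
#' @param ... Unused.
#' @return A numeric matrix (`"prob"`/`"link"`) or character vector
#'   (`"class"`).
#' @export
predict.sweepwave_classifier <- function(object, newdata,
                                         type = c("prob", "class", "link"),
                                         threshold = 0.7, ...) {
  type <- match.arg(type)
  eta <- classifier_eta(object, newdata)
  colnames(eta) <- object$classes
  if (type == "link") return(eta)
  pr <- softmax_rows(eta)
  if (type == "prob") return(pr)
  apply(pr, 1, call_class, sweep_threshold = threshold)
}

#' Threshold a probability vector into a class call
#'
#' Returns the most probable class, except that a non-neutral winner whose
#' probability does not exceed `sweep_threshold` is demoted to neutral;
#' exact ties are broken toward neutral.
#'
#' @param probs Named probability vector over classes (must include
#'   `neutral_label` for demotion to apply).
#' @param sweep_threshold Demotion threshold (default 0.7: a non-neutral
#'   probability less than or equal to 0.7 is called neutral).
#' @param neutral_label Name of the neutral class.
#' @return The called class label.
#' @examples
#' call_class(c(neutral = 0.31, sweep = 0.69))  # "neutral"
#' call_class(c(neutral = 0.25, sweep = 0.75))  # "sweep"
#' @export
call_class <- function(probs, sweep_threshold = 0.7,
                       neutral_label = "neutral") {
  if (abs(sum(probs) - 1) > 1e-6 || any(probs < 0)) {
    stop("probs must be a probability vector", call. = FALSE)
  }
  top <- max(probs)
  winners <- names(probs)[probs == top]
  if (neutral_label %in% winners) return(neutral_label)
  best <- winners[1]
  if (neutral_label %in% names(probs) && probs[best] <= sweep_threshold) {
    return(neutral_label)
  }
  best
}

#' Reconstructed coefficient functions of a fitted model
#'
#' Inverts the wavelet representation of each class's (or response's)
#' fitted coefficient segment, giving the functional-regression weight
#' curve \eqn{\hat\beta(t)} over window position for every summary
#' statistic.
#'
#' @param model A fitted [fit_classifier()] or [fit_predictor()] object.
#' @return A named list (one element per class/response) of `9 x p` matrices
#'   of reconstructed coefficient functions, with class
#'   `"coefficient_functions"`.
#' @export
coefficient_functions <- function(model) {
  if (is.null(model$Z)) stop("model is not fitted", call. = FALSE)
  p <- model$p
  m <- length(STAT_NAMES)
  out <- lapply(seq_len(ncol(model$Z)), function(k) {
    beta <- matrix(NA_real_, m, p, dimnames = list(STAT_NAMES, NULL))
    for (s in seq_len(m)) {
      seg <- model$Z[(s - 1) * p + seq_len(p), k]
      beta[s, ] <- reconstruct_beta(seg, model$wavelet)
    }
    beta
  })
  names(out) <- if (!is.null(colnames(model$Z))) {
    colnames(model$Z)
  } else if (!is.null(model$classes)) {
    model$classes
  } else {
    model$responses
  }
  structure(out, class = "coefficient_functions")
}

#' Calibration (reliability) curve of a classifier
#'
#' Slides overlapping probability bins of width `window_width` (step `step`)
#' across `[0, 1]`; in each bin reports the mean predicted probability of
#' the positive class and the observed fraction of that class among the
#' test observations falling in the bin.
#'
#' @param model A fitted [fit_classifier()].
#' @param features Test-set feature curves (list).
#' @param labels True labels.
#' @param positive_class Class whose probability is calibrated
#'   (default `"sweep"`).
#' @param window_width Bin width (default 0.05).
#' @param step Bin step (default 0.001).
#' @return Data frame with columns `bin_lo`, `bin_hi`, `mean_pred`,
#'   `obs_frac`, `n` (empty bins are dropped).
#' @export
reliability_curve <- function(model, features, labels,
                              positive_class = "sweep",
                              window_width = 0.05, step = 0.001) {
  fcs <- as_fc_list(features)
  if (length(fcs) == 0) stop("empty test set", call. = FALSE)
  pr <- predict(model, fcs, type = "prob")[, positive_class]
  y <- as.character(labels) == positive_class
  lo <- seq(0, 1 - window_width, by = step)
  rows <- lapply(lo, function(l) {
    hi <- l + window_width
    inb <- pr >= l & (pr <= hi)
    if (!any(inb)) return(NULL)
    data.frame(bin_lo = l, bin_hi = hi, mean_pred = mean(pr[inb]),
               obs_frac = mean(y[inb]), n = sum(inb))
  })
  do.call(rbind, rows)
}

#' @export
print.sweepwave_classifier <- function(x, ...) {
  cat("Functional multinomial classifier (elastic net, wavelet domain)\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  basis: %s, j0 = %d, p = %d%s\n", x$wavelet$family, x$j0,
              x$p, if (x$include_2d) " (+ 2-D r2 blocks)" else ""))
  cat(sprintf("  selected gamma = %g, lambda = %.4g (CV accuracy %.3f)\n",
              x$gamma, x$lambda, x$cv_accuracy))
  cat(sprintf("  %d of %d coefficients nonzero\n", sum(x$Z != 0),
              length(x$Z)))
  invisible(x)
}

#' @export
summary.sweepwave_classifier <- function(object, ...) {
  print(object)
  cat("\nCross-validation report (best lambda per gamma/level):\n")
  print(object$cv_report, row.names = FALSE)
  invisible(object)
}

#' @export
coef.sweepwave_classifier <- function(object, ...) {
  list(alpha = object$alpha, Z = object$Z)
}

#' Plot reconstructed coefficient functions
#'
#' One panel per class (or response): the reconstructed weight curves of all
#' nine summary statistics over window position.
#'
#' @param x A fitted classifier or predictor.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sweepwave_classifier <- function(x, ...) {
  cfs <- coefficient_functions(x)
  old <- graphics::par(mfrow = c(1, length(cfs)))
  on.exit(graphics::par(old))
  for (nm in names(cfs)) {
    graphics::matplot(t(cfs[[nm]]), type = "l", lty = 1,
                      xlab = "window", ylab = expression(hat(beta)(t)),
                      main = nm, ...)
  }
  invisible(x)
}
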