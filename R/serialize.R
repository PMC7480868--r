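# JSON serialization of fitted models (schema version 1). Matrices are
# stored dense row-major with explicit dimensions so models are portable
# across sessions and languages.

mat_to_json <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m), rownames = rownames(m),
       colnames = colnames(m), data = as.vector(t(m)))
}

mat_from_json <- function(j) {
  m <- matrix(unlist(j$data), j$nrow, j$ncol, byrow = TRUE)
  if (!is.null(j$rownames)) rownames(m) <- unlist(j$rownames)
  if (!is.null(j$colnames)) colnames(m) <- unlist(j$colnames)
  m
}

#' Serialize a fitted model to JSON
#'
#' Stores intercepts, the wavelet-domain coefficient matrix, the chosen
#' `(gamma, lambda, j0)`, the wavelet basis, the frozen standardization
#' parameters, and (for predictors) the response scaling, under a versioned
#' schema. [read_model()] restores an object whose predictions are
#' identical to the original's.
#'
#' @param model A fitted [fit_classifier()] or [fit_predictor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  type <- if (inherits(model, "sweepwave_classifier")) {
    "classifier"
  } else if (inherits(model, "sweepwave_predictor")) {
    "predictor"
  } else {
    stop("not a sweepwave model", call. = FALSE)
  }
  sp <- model$standardization
  obj <- list(
    schema = "sweepwave-model", schema_version = 1L, type = type,
    alpha = as.list(stats::setNames(as.numeric(model$alpha),
                                    names(model$alpha))),
    Z = mat_to_json(model$Z),
    gamma = model$gamma, lambda = model$lambda, j0 = model$j0,
    wavelet = unclass(model$wavelet),
    include_2d = model$include_2d, p = model$p,
    standardization = list(
      means = mat_to_json(sp$means), sds = mat_to_json(sp$sds),
      twod_means = if (!is.null(sp$twod_means)) {
        lapply(sp$twod_means, mat_to_json)
      },
      twod_sds = if (!is.null(sp$twod_sds)) {
        lapply(sp$twod_sds, mat_to_json)
      }
    )
  )
  if (type == "classifier") {
    obj$classes <- model$classes
    obj$class_proportions <- model$class_proportions
  } else {
    obj$responses <- model$responses
    sc <- model$response_scaling
    obj$response_scaling <- list(
      log_cols = sc$log_cols, log_base = sc$log_base,
      mean = as.list(stats::setNames(as.numeric(sc$mean), names(sc$mean))),
      sd = as.list(stats::setNames(as.numeric(sc$sd), names(sc$sd))))
    obj$train_norm_max <- model$train_norm_max
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `"sweepwave_classifier"` or `"sweepwave_predictor"` object.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path)
  if (!identical(j$schema, "sweepwave-model")) {
    stop("not a sweepwave model file: ", path, call. = FALSE)
  }
  sp <- structure(list(
    means = mat_from_json(j$standardization$means),
    sds = mat_from_json(j$standardization$sds),
    twod_means = if (!is.null(j$standardization$twod_means)) {
      lapply(j$standardization$twod_means, mat_from_json)
    },
    twod_sds = if (!is.null(j$standardization$twod_sds)) {
      lapply(j$standardization$twod_sds, mat_from_json)
    }), class = "standardization_params")
  w <- j$wavelet
  spec <- wavelet_spec(w$family, w$vanishing_moments, j0 = w$j0, p = w$p)
  base <- list(
    alpha = unlist(j$alpha), Z = mat_from_json(j$Z),
    gamma = j$gamma, lambda = j$lambda, j0 = j$j0, wavelet = spec,
    standardization = sp, include_2d = isTRUE(j$include_2d), p = j$p)
  if (j$type == "classifier") {
    base$classes <- unlist(j$classes)
    base$class_proportions <- unlist(j$class_proportions)
    structure(base, class = "sweepwave_classifier")
  } else {
    base$responses <- unlist(j$responses)
    base$response_scaling <- list(
      log_cols = unlist(j$response_scaling$log_cols),
      log_base = j$response_scaling$log_base,
      mean = unlist(j$response_scaling$mean),
      sd = unlist(j$response_scaling$sd))
    base$train_norm_max <- j$train_norm_max
    structure(base, class = "sweepwave_predictor")
  }
}
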