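# Shared machinery for the two functional-regression models: assembling the
# wavelet-domain design matrix from feature curves, and the cross-validation
# bookkeeping both fitters use.

as_fc_list <- function(features) {
  if (inherits(features, "feature_curves")) return(list(features))
  if (!is.list(features) ||
      !all(vapply(features, inherits, logical(1), "feature_curves"))) {
    stop("features must be a feature_curves object or a list of them",
         call. = FALSE)
  }
  features
}

# n x (m*p [+ 4*(p/2)^2]) wavelet-domain design matrix: per statistic, the
# standardized curve's DWT segment; 2-D blocks go through the separable
# transform and are appended row-major.
build_xi_matrix <- function(fcs, sp, spec, include_2d = FALSE) {
  p <- spec$p
  W <- dwt_matrix(spec)
  spec2 <- if (include_2d) {
    wavelet_spec(spec$family, spec$vanishing_moments,
                 j0 = min(spec$j0, as.integer(round(log2(p / 2))) - 2L),
                 p = p / 2L)
  } else {
    NULL
  }
  W2 <- if (include_2d) dwt_matrix(spec2) else NULL
  rows <- lapply(fcs, function(fc) {
    if (ncol(fc$curves) != p) {
      stop("feature curves have ", ncol(fc$curves),
           " windows but the basis expects p = ", p, call. = FALSE)
    }
    z <- standardize_curves(fc, sp)
    xi <- as.vector(t(z$curves %*% t(W)))  # segments concatenated by statistic
    if (include_2d) {
      if (is.null(z$twod)) {
        stop("model uses 2-D statistics but this observation has none",
             call. = FALSE)
      }
      xi <- c(xi, unlist(lapply(TWOD_NAMES, function(nm) {
        as.vector(t(W2 %*% z$twod[[nm]] %*% t(W2)))
      }), use.names = FALSE))
    }
    xi
  })
  X <- do.call(rbind, rows)
  seg <- as.vector(t(outer(STAT_NAMES, seq_len(p) - 1L, paste, sep = ".")))
  if (include_2d) {
    seg <- c(seg, unlist(lapply(TWOD_NAMES, function(nm) {
      paste(nm, seq_len((p / 2)^2) - 1L, sep = ".")
    })))
  }
  colnames(X) <- seg
  X
}

# seeded, stratified fold assignment; every class must have >= folds members
stratified_folds <- function(labels, folds, seed) {
  tab <- table(labels)
  if (any(tab < folds)) {
    stop("every class needs at least ", folds,
         " observations for stratified ", folds, "-fold CV", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# tie-break rule shared by both fitters: best score first, then smaller j0
# (smoother coefficient functions), then larger gamma (sparser), then larger
# lambda (stronger penalty)
select_best <- function(report, maximize = TRUE) {
  score <- if (maximize) report$score else -report$score
  ord <- order(-score, report$j0, -report$gamma, -report$lambda)
  report[ord[1], , drop = FALSE]
}
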