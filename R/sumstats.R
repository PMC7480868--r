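# Per-window summary statistics (pi-hat, haplotype spectrum, H-statistics,
# pairwise r^2 and its cross-window moments), feature-curve assembly, and
# training-set standardization.

STAT_NAMES <- c("pi", "H1", "H12", "H2_H1",
                paste0("hapfreq", 1:5))
TWOD_NAMES <- c("r2_mean", "r2_var", "r2_skew", "r2_kurt")

#' Mean pairwise sequence difference in a window
#'
#' The average Hamming distance over all `choose(n, 2)` haplotype pairs in a
#' window, computed exactly via per-site allele counts.
#'
#' @param window_alleles `n x w` 0/1 matrix (haplotypes in rows).
#' @return Nonnegative scalar.
#' @examples
#' pi_hat(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))  # 8/6
#' @export
pi_hat <- function(window_alleles) {
  n <- nrow(window_alleles)
  if (is.null(n) || n < 2) {
    stop("pi_hat needs at least 2 haplotypes", call. = FALSE)
  }
  cs <- colSums(window_alleles)
  sum(cs * (n - cs)) / choose(n, 2)
}

#' Haplotype frequency spectrum of a window
#'
#' Frequencies of the distinct full-window haplotypes, sorted descending;
#' sums to 1.
#'
#' @param window_alleles `n x w` 0/1 matrix.
#' @return Descending numeric vector of haplotype frequencies.
#' @export
haplotype_spectrum <- function(window_alleles) {
  if (is.null(nrow(window_alleles)) || nrow(window_alleles) < 1) {
    stop("haplotype_spectrum needs at least 1 haplotype", call. = FALSE)
  }
  keys <- apply(window_alleles, 1, paste, collapse = "")
  as.numeric(sort(table(keys), decreasing = TRUE)) / length(keys)
}

#' Haplotype homozygosity statistics H1, H12, H2/H1
#'
#' From a descending haplotype frequency spectrum `p1 >= p2 >= ...`:
#' `H1 = sum(p_i^2)`, `H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2`,
#' `H2 = H1 - p1^2`. `H12` pools the two most common haplotypes and `H2/H1`
#' separates soft from hard sweeps. A single-haplotype spectrum yields
#' `(1, 1, 0)`.
#'
#' @param spectrum Descending frequency vector summing to 1.
#' @return Named numeric vector `c(H1, H12, H2_over_H1)`.
#' @examples
#' h_statistics(c(0.4, 0.3, 0.2, 0.1))
#' @export
h_statistics <- function(spectrum) {
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) == 0 || any(spectrum < 0)) {
    stop("spectrum must be a nonnegative frequency vector", call. = FALSE)
  }
  if (is.unsorted(rev(spectrum))) {
    stop("spectrum must be sorted in descending order", call. = FALSE)
  }
  if (abs(sum(spectrum) - 1) > 1e-8) {
    stop("spectrum must sum to 1", call. = FALSE)
  }
  H1 <- sum(spectrum^2)
  H12 <- if (length(spectrum) >= 2) {
    (spectrum[1] + spectrum[2])^2 + sum(spectrum[-(1:2)]^2)
  } else {
    H1
  }
  H2 <- H1 - spectrum[1]^2
  c(H1 = H1, H12 = H12, H2_over_H1 = if (H1 > 0) H2 / H1 else 0)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the 0/1 allelic states at two sites,
#' equal to \eqn{D^2 / (p_A(1-p_A) p_B(1-p_B))}. Both sites must be
#' polymorphic in the sample.
#'
#' @param site_a,site_b 0/1 vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
r2_pair <- function(site_a, site_b) {
  va <- stats::var(site_a); vb <- stats::var(site_b)
  if (va == 0 || vb == 0) {
    stop("r2 is undefined for a monomorphic site", call. = FALSE)
  }
  stats::cor(site_a, site_b)^2
}

# population moments; exact-zero variance collapses skew/kurt to 0
dist_moments <- function(v) {
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 <= 1e-20) {
    return(c(mean = m, var = 0, skew = 0, kurt = 0))
  }
  c(mean = m, var = m2, skew = mean(d^3) / m2^1.5, kurt = mean(d^4) / m2^2)
}

#' Moments of pairwise r-squared between two windows
#'
#' Mean, variance, skewness, and kurtosis of r-squared over all cross-window
#' SNP pairs (`w_a * w_b` pairs for distinct windows; the `choose(w, 2)`
#' distinct within-window pairs when a window is paired with itself).
#' Population (biased) moments; kurtosis is non-excess (`m4 / m2^2`); a
#' zero-variance pair set returns `(mean, 0, 0, 0)`.
#'
#' @param window_a,window_b `n x w` 0/1 matrices over the same haplotypes.
#'   Pass the same matrix twice (or omit `window_b`) for the self-pair case.
#' @return Named numeric vector `c(mean, var, skew, kurt)`.
#' @export
r2_moments <- function(window_a, window_b = NULL) {
  self <- is.null(window_b) || identical(window_a, window_b)
  if (self) window_b <- window_a
  if (ncol(window_a) < 1 || ncol(window_b) < 1 ||
      (self && ncol(window_a) < 2)) {
    stop("empty r2 pair set", call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(window_a, window_b))^2
  if (anyNA(R)) stop("r2 is undefined for a monomorphic site", call. = FALSE)
  vals <- if (self) R[upper.tri(R)] else as.vector(R)
  dist_moments(vals)
}

#' Construct a feature-curve set
#'
#' One observation's summary-statistic curves: a `9 x p` matrix (rows, in
#' fixed order: pi, H1, H12, H2/H1, hapfreq1..hapfreq5) plus, optionally,
#' the four symmetric `p/2 x p/2` blocks of cross-window r-squared moments.
#'
#' @param curves `9 x p` numeric matrix.
#' @param twod Optional named list of the 4 symmetric moment matrices
#'   (`r2_mean`, `r2_var`, `r2_skew`, `r2_kurt`).
#' @param obs_id Observation identifier.
#' @param standardized Whether the curves are already standardized.
#' @return An object of class `"feature_curves"`.
#' @export
feature_curves <- function(curves, twod = NULL, obs_id = NA_character_,
                           standardized = FALSE) {
  curves <- as.matrix(curves)
  if (nrow(curves) != length(STAT_NAMES)) {
    stop("curves must have ", length(STAT_NAMES), " rows", call. = FALSE)
  }
  rownames(curves) <- STAT_NAMES
  if (!is.null(twod)) {
    if (!identical(sort(names(twod)), sort(TWOD_NAMES))) {
      stop("twod must be a named list of the 4 r2-moment blocks",
           call. = FALSE)
    }
    twod <- twod[TWOD_NAMES]
    sides <- vapply(twod, function(m) nrow(m), integer(1))
    if (any(sides != ncol(curves) / 2)) {
      stop("2-D blocks must be (p/2 x p/2)", call. = FALSE)
    }
  }
  structure(list(obs_id = obs_id, curves = curves, twod = twod,
                 standardized = isTRUE(standardized)),
            class = "feature_curves")
}

#' @export
print.feature_curves <- function(x, ...) {
  cat(sprintf("Feature curves [%s]: %d statistics x %d windows%s%s\n",
              x$obs_id, nrow(x$curves), ncol(x$curves),
              if (!is.null(x$twod)) " + 4 r2-moment blocks" else "",
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Compute feature curves for one layout placement
#'
#' Evaluates the nine one-dimensional statistics in each of the `p`
#' overlapping windows anchored at `anchor_offset` on the filtered SNP axis,
#' and (optionally) the four cross-window r-squared moment blocks over the
#' `p/2` alternating non-overlapping windows — `p/2 * (p/2 + 1) / 2` unique
#' window-pair evaluations (2,080 at `p = 128`), mirrored by symmetry.
#' Haplotype-frequency rows are padded with 0 when a window holds fewer than
#' 5 distinct haplotypes.
#'
#' @param h A filtered [haplotype_matrix()].
#' @param layout A [build_layout()].
#' @param anchor_offset 0-based offset of the placement (default 0); the
#'   placement must fit: `anchor_offset + layout$span <= ncol(h)`.
#' @param include_2d Whether to compute the r-squared moment blocks.
#' @return A [feature_curves()] object.
#' @export
featurize <- function(h, layout, anchor_offset = 0L, include_2d = FALSE) {
  S <- ncol(h$alleles)
  if (anchor_offset < 0 || anchor_offset + layout$span > S) {
    stop("anchor does not fit: offset ", anchor_offset, " + span ",
         layout$span, " exceeds ", S, " SNPs", call. = FALSE)
  }
  n <- nrow(h$alleles)
  p <- layout$p
  curves <- matrix(NA_real_, length(STAT_NAMES), p,
                   dimnames = list(STAT_NAMES, NULL))
  win_cols <- function(i) {  # 0-based window id -> 1-based column indices
    anchor_offset + seq.int(layout$windows[i + 1L, "first"],
                            layout$windows[i + 1L, "last"]) + 1L
  }
  for (i in seq_len(p) - 1L) {
    wa <- h$alleles[, win_cols(i), drop = FALSE]
    if (any(colSums(wa) %in% c(0L, n))) {
      stop("monomorphic site inside a window; filter sites first",
           call. = FALSE)
    }
    spec <- haplotype_spectrum(wa)
    hs <- h_statistics(spec)
    top5 <- c(spec, numeric(5))[1:5]
    curves[, i + 1L] <- c(pi_hat(wa), hs[["H1"]], hs[["H12"]],
                          hs[["H2_over_H1"]], top5)
  }
  twod <- NULL
  if (include_2d) {
    ids <- layout$nonoverlapping_ids
    q <- length(ids)
    twod <- stats::setNames(
      replicate(4, matrix(NA_real_, q, q), simplify = FALSE), TWOD_NAMES)
    for (a in seq_len(q)) {
      for (b in a:q) {
        mom <- if (a == b) {
          r2_moments(h$alleles[, win_cols(ids[a]), drop = FALSE])
        } else {
          r2_moments(h$alleles[, win_cols(ids[a]), drop = FALSE],
                     h$alleles[, win_cols(ids[b]), drop = FALSE])
        }
        for (k in 1:4) {
          twod[[k]][a, b] <- mom[k]
          twod[[k]][b, a] <- mom[k]
        }
      }
    }
  }
  feature_curves(curves, twod = twod,
                 obs_id = paste0(h$chrom, ":", anchor_offset))
}

#' Estimate standardization parameters from a training set
#'
#' Per-statistic, per-window means and population standard deviations over
#' the training observations (and per-cell parameters for the r-squared
#' moment blocks when present in every observation). Cells with zero
#' training variance get SD 1, with a warning.
#'
#' @param training Non-empty list of unstandardized [feature_curves()].
#' @return An object of class `"standardization_params"`.
#' @export
fit_standardization <- function(training) {
  if (length(training) == 0) stop("empty training set", call. = FALSE)
  arr <- vapply(training, function(fc) fc$curves,
                training[[1]]$curves)  # m x p x n
  means <- apply(arr, c(1, 2), mean)
  sds <- sqrt(apply(arr, c(1, 2), function(v) mean((v - mean(v))^2)))
  nzero <- sum(sds == 0)
  if (nzero > 0) {
    warning(nzero, " feature cell(s) with zero training variance; SD set to 1",
            call. = FALSE)
    sds[sds == 0] <- 1
  }
  out <- list(means = means, sds = sds, twod_means = NULL, twod_sds = NULL)
  if (all(vapply(training, function(fc) !is.null(fc$twod), logical(1)))) {
    out$twod_means <- lapply(TWOD_NAMES, function(nm) {
      Reduce(`+`, lapply(training, function(fc) fc$twod[[nm]])) /
        length(training)
    })
    names(out$twod_means) <- TWOD_NAMES
    out$twod_sds <- lapply(TWOD_NAMES, function(nm) {
      mu <- out$twod_means[[nm]]
      s <- sqrt(Reduce(`+`, lapply(training, function(fc) {
        (fc$twod[[nm]] - mu)^2
      })) / length(training))
      s[s == 0] <- 1
      s
    })
    names(out$twod_sds) <- TWOD_NAMES
  }
  structure(out, class = "standardization_params")
}

#' Standardize feature curves
#'
#' Applies frozen training means/SDs cell-wise ([fit_standardization()]).
#' Standardizing an already-standardized observation is an error.
#'
#' @param fc A [feature_curves()] with `standardized = FALSE`.
#' @param sp A [fit_standardization()] result.
#' @return The standardized [feature_curves()].
#' @export
standardize_curves <- function(fc, sp) {
  if (fc$standardized) {
    stop("feature curves are already standardized", call. = FALSE)
  }
  curves <- (fc$curves - sp$means) / sp$sds
  twod <- fc$twod
  if (!is.null(twod) && !is.null(sp$twod_means)) {
    twod <- stats::setNames(lapply(TWOD_NAMES, function(nm) {
      (twod[[nm]] - sp$twod_means[[nm]]) / sp$twod_sds[[nm]]
    }), TWOD_NAMES)
  }
  feature_curves(curves, twod = twod, obs_id = fc$obs_id, standardized = TRUE)
}

#' Write/read feature tables as TSV
#'
#' One row per observation; one column per (statistic, window) cell named
#' `stat:window` (1-based window index), preceded by `obs_id`. When 2-D
#' blocks are present, their upper triangles (including the diagonal) are
#' appended row-major as `stat:i:j` columns and mirrored on read.
#'
#' @param fcs List of [feature_curves()].
#' @param path Output path.
#' @return `path` invisibly (`write_features_tsv`); a list of
#'   [feature_curves()] (`read_features_tsv`).
#' @export
write_features_tsv <- function(fcs, path) {
  p <- ncol(fcs[[1]]$curves)
  has2d <- !is.null(fcs[[1]]$twod)
  header <- c("obs_id",
              as.vector(t(outer(STAT_NAMES, seq_len(p), paste, sep = ":"))))
  if (has2d) {
    q <- p / 2
    ut <- which(upper.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
    ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
    header <- c(header, unlist(lapply(TWOD_NAMES, function(nm) {
      paste(nm, ut[, 1], ut[, 2], sep = ":")
    })))
  }
  rows <- vapply(fcs, function(fc) {
    v <- as.vector(t(fc$curves))
    if (has2d) {
      q <- p / 2
      ut <- which(upper.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
      ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
      v <- c(v, unlist(lapply(TWOD_NAMES, function(nm) {
        fc$twod[[nm]][ut]
      })))
    }
    paste(c(fc$obs_id, format(v, digits = 17, trim = TRUE,
                              scientific = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  cn <- colnames(tab)
  curve_cols <- grep(paste0("^(", paste(STAT_NAMES, collapse = "|"),
                            "):[0-9]+$"), cn)
  p <- length(curve_cols) / length(STAT_NAMES)
  twod_cols <- grep(paste0("^(", paste(TWOD_NAMES, collapse = "|"),
                           "):[0-9]+:[0-9]+$"), cn)
  lapply(seq_len(nrow(tab)), function(i) {
    curves <- matrix(as.numeric(tab[i, curve_cols]), length(STAT_NAMES), p,
                     byrow = TRUE)
    twod <- NULL
    if (length(twod_cols) > 0) {
      q <- p / 2
      ut <- which(upper.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
      ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
      nper <- nrow(ut)
      vals <- as.numeric(tab[i, twod_cols])
      twod <- stats::setNames(lapply(seq_along(TWOD_NAMES), function(k) {
        m <- matrix(0, q, q)
        m[ut] <- vals[(k - 1) * nper + seq_len(nper)]
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
        m
      }), TWOD_NAMES)
    }
    feature_curves(curves, twod = twod, obs_id = as.character(tab$obs_id[i]))
  })
}
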