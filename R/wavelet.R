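# Orthonormal periodized discrete wavelet transform (Haar and Daubechies
# least-asymmetric families), implemented as explicit orthonormal p x p
# matrices. p is small here (<= 128), so the matrix form is both fast enough
# and makes orthonormality (Parseval, exact inversion) structural.

# Daubechies least-asymmetric ("symlet") scaling filters, indexed by the
# number of vanishing moments. Standard published constants.
.symlet_filters <- list(
  "4" = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
          0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
          -0.012603967262037833, 0.0322231006040427),
  "8" = c(-0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
          0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
          0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
          -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
          0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
          0.0018899503327594609)
)

#' Specify a wavelet basis
#'
#' Defines the orthonormal wavelet basis used to represent summary-statistic
#' curves: the filter family, the number of vanishing moments, and the
#' truncation (coarsest detail) level `j0`. Boundary handling is periodic,
#' the only mode that keeps the length-`p` to length-`p` map exactly
#' orthonormal.
#'
#' @param family `"haar"` or `"daubechies_least_asymmetric"`.
#' @param vanishing_moments Number of vanishing moments; fixed at 1 for Haar,
#'   4 or 8 for the least-asymmetric family (default 8).
#' @param j0 Coarsest resolution level retained as father coefficients, in
#'   `0:(J-2)` where `J = log2(p)`. Smaller `j0` gives smoother reconstructed
#'   coefficient functions.
#' @param p Curve length, a power of two (default 128).
#' @return An object of class `"wavelet_spec"`.
#' @examples
#' wavelet_spec("haar", j0 = 0, p = 8)
#' @export
wavelet_spec <- function(family = c("daubechies_least_asymmetric", "haar"),
                         vanishing_moments = 8L, j0 = 0L, p = 128L) {
  family <- match.arg(family)
  if (!is_pow2(p)) {
    stop("curve length p must be a power of two, got ", p, call. = FALSE)
  }
  J <- as.integer(round(log2(p)))
  if (j0 < 0 || j0 > J - 2) {
    stop("truncation level j0 must lie in 0..", J - 2, " for p = ", p,
         call. = FALSE)
  }
  if (family == "haar") {
    vanishing_moments <- 1L
  } else if (!as.character(vanishing_moments) %in% names(.symlet_filters)) {
    stop("unsupported vanishing_moments for the least-asymmetric family: ",
         vanishing_moments, call. = FALSE)
  }
  structure(
    list(family = family, vanishing_moments = as.integer(vanishing_moments),
         boundary = "periodic", p = as.integer(p), J = J, j0 = as.integer(j0)),
    class = "wavelet_spec"
  )
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("Wavelet basis:", x$family,
      sprintf("(%d vanishing moment%s)", x$vanishing_moments,
              if (x$vanishing_moments > 1) "s" else ""), "\n")
  cat("  p =", x$p, " J =", x$J, " truncation level j0 =", x$j0,
      " boundary = periodic\n")
  invisible(x)
}

#' Candidate truncation levels
#'
#' The grid of coarsest detail levels searched during cross-validation:
#' `0:(log2(p) - 2)`, six levels (`0:5`) at the default `p = 128`.
#'
#' @param p Curve length, a power of two.
#' @return Integer vector of candidate `j0` values.
#' @examples
#' candidate_levels(128)
#' @export
candidate_levels <- function(p = 128L) {
  if (!is_pow2(p)) stop("p must be a power of two", call. = FALSE)
  0:(as.integer(round(log2(p))) - 2L)
}

is_pow2 <- function(p) {
  p <- as.integer(p)
  length(p) == 1L && !is.na(p) && p >= 2L && bitwAnd(p, p - 1L) == 0L
}

scaling_filter <- function(spec) {
  if (spec$family == "haar") {
    c(1, 1) / sqrt(2)
  } else {
    .symlet_filters[[as.character(spec$vanishing_moments)]]
  }
}

# One analysis stage on a block of size n: rows 1..n/2 are the scaling
# (father) outputs, rows n/2+1..n the detail (mother) outputs. The filter is
# periodized, so the stage matrix is orthonormal for every dyadic n >= 2.
dwt_stage_matrix <- function(n, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror filter
  S <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (l in seq_along(h)) {
      col <- ((2L * (k - 1L) + (l - 1L)) %% n) + 1L
      S[k, col] <- S[k, col] + h[l]
      S[n / 2 + k, col] <- S[n / 2 + k, col] + g[l]
    }
  }
  S
}

# Full orthonormal analysis matrix W: coefficient vector = W %*% curve.
# Row order: 2^j0 fathers at level j0, then mothers level j0, j0+1, ..., J-1,
# within each level by location k ascending.
dwt_matrix <- function(spec) {
  p <- spec$p
  h <- scaling_filter(spec)
  W <- diag(p)
  n <- p
  while (n > 2^spec$j0) {
    S <- dwt_stage_matrix(n, h)
    W[seq_len(n), ] <- S %*% W[seq_len(n), , drop = FALSE]
    n <- n / 2L
  }
  W
}

#' Discrete wavelet analysis of a curve
#'
#' Transforms a length-`p` curve into its orthonormal wavelet coefficient
#' segment: `2^j0` father (scaling) coefficients followed by mother (detail)
#' coefficients for levels `j0, ..., J-1` (location-ascending within each
#' level). Whatever the truncation level, the segment has length `p`
#' exactly, and the transform is an isometry: the Euclidean norm of the
#' segment equals the norm of the curve.
#'
#' @param curve Numeric vector of length `spec$p`.
#' @param spec A [wavelet_spec()].
#' @return Numeric vector of length `p` of analysis coefficients.
#' @examples
#' s <- wavelet_spec("haar", j0 = 0, p = 8)
#' dwt(c(1, 1, 1, 1, 0, 0, 0, 0), s)
#' @export
dwt <- function(curve, spec) {
  if (length(curve) != spec$p) {
    stop("curve length ", length(curve), " does not match spec p = ", spec$p,
         call. = FALSE)
  }
  drop(dwt_matrix(spec) %*% as.numeric(curve))
}

#' Inverse discrete wavelet transform
#'
#' Exact inverse of [dwt()]: synthesizes a length-`p` curve from a
#' coefficient segment. `idwt(dwt(x, s), s)` reproduces `x` to numerical
#' precision for both filter families.
#'
#' @param segment Numeric coefficient vector of length `spec$p`.
#' @param spec A [wavelet_spec()].
#' @return Numeric vector of length `p`.
#' @export
idwt <- function(segment, spec) {
  if (length(segment) != spec$p) {
    stop("segment length ", length(segment), " does not match spec p = ",
         spec$p, call. = FALSE)
  }
  drop(crossprod(dwt_matrix(spec), as.numeric(segment)))
}

#' Separable 2-D wavelet analysis of a square block
#'
#' Applies the orthonormal 1-D transform to rows then columns of a square
#' matrix whose side is a power of two (used for the window-pair r-squared
#' moment blocks), truncated at the same `j0`. The Frobenius norm is
#' preserved.
#'
#' @param block Square numeric matrix; side must be a power of two.
#' @param spec A [wavelet_spec()] whose `p` equals the block side.
#' @param flatten If `TRUE` (default) return the coefficient matrix flattened
#'   row-major; otherwise return the matrix.
#' @return Numeric vector of length `p^2` (or a `p x p` matrix).
#' @export
dwt2 <- function(block, spec, flatten = TRUE) {
  if (!is.matrix(block) || nrow(block) != ncol(block)) {
    stop("block must be a square matrix", call. = FALSE)
  }
  if (nrow(block) != spec$p) {
    stop("block side ", nrow(block), " does not match spec p = ", spec$p,
         call. = FALSE)
  }
  W <- dwt_matrix(spec)
  cf <- W %*% block %*% t(W)
  if (flatten) as.vector(t(cf)) else cf
}

#' Inverse separable 2-D wavelet transform
#'
#' @param segment Row-major flattened coefficient vector of length `p^2`, or
#'   a `p x p` coefficient matrix.
#' @param spec A [wavelet_spec()].
#' @return The synthesized `p x p` matrix.
#' @export
idwt2 <- function(segment, spec) {
  p <- spec$p
  cf <- if (is.matrix(segment)) segment else matrix(segment, p, p, byrow = TRUE)
  if (nrow(cf) != p || ncol(cf) != p) {
    stop("coefficient block does not match spec p = ", p, call. = FALSE)
  }
  W <- dwt_matrix(spec)
  t(W) %*% cf %*% W
}

#' Reconstruct a coefficient function from wavelet-domain coefficients
#'
#' Synthesizes the functional-regression weight curve \eqn{\hat\beta(t)} at
#' the `p` window positions from a fitted wavelet-domain coefficient segment
#' \eqn{\zeta}. This is the same synthesis operator as [idwt()]; it exists
#' for inspecting and plotting fitted models.
#'
#' @param zeta Numeric coefficient segment of length `spec$p`.
#' @param spec A [wavelet_spec()].
#' @return Numeric vector of length `p`.
#' @export
reconstruct_beta <- function(zeta, spec) idwt(zeta, spec)
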