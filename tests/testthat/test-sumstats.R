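# Per-window summary statistics against brute-force oracles, and the
# standardization contract.

test_that("pi_hat equals the mean pairwise Hamming distance", {
  expect_equal(pi_hat(matrix(0L, 5, 10)), 0)
  two <- rbind(c(1, 0, 1, 0, 0, 0, 0, 0, 0, 0),
               c(0, 0, 1, 1, 0, 0, 0, 0, 1, 0))
  expect_equal(pi_hat(two), 3)  # single pair differing at 3 of 10 sites
  four <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(pi_hat(four), 8 / 6)  # enumeration of all 6 pairs
  expect_error(pi_hat(matrix(0L, 1, 4)), "at least 2")
})

test_that("haplotype spectrum matches string-count enumeration", {
  all_distinct <- diag(4)
  expect_equal(haplotype_spectrum(all_distinct), rep(0.25, 4))
  counts <- rbind(matrix(rep(c(0, 0), 4), 4, 2, byrow = TRUE),
                  matrix(rep(c(0, 1), 3), 3, 2, byrow = TRUE),
                  matrix(rep(c(1, 0), 2), 2, 2, byrow = TRUE),
                  matrix(c(1, 1), 1, 2))
  expect_equal(haplotype_spectrum(counts), c(0.4, 0.3, 0.2, 0.1))
  set.seed(5)
  w <- matrix(rbinom(200, 1, 0.5), 20, 10)
  expect_equal(haplotype_spectrum(w), oracle_spectrum(w))
})

test_that("H-statistics follow the pooled-homozygosity formulas", {
  expect_equal(unname(h_statistics(1.0)), c(1, 1, 0))
  expect_equal(unname(h_statistics(c(0.4, 0.3, 0.2, 0.1))),
               c(0.30, 0.54, 0.14 / 0.30))
  expect_equal(unname(h_statistics(c(0.5, 0.5))), c(0.5, 1.0, 0.5))
  expect_error(h_statistics(c(0.3, 0.7)), "descending")
  expect_error(h_statistics(c(0.5, 0.4)), "sum to 1")
})

test_that("H12 >= H1 >= H2 and all lie in [0, 1] for random spectra", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(1:8, 1)
    spec <- sort(as.vector(stats::rmultinom(1, 30, runif(k))) / 30,
                 decreasing = TRUE)
    spec <- spec[spec > 0]
    h <- h_statistics(spec)
    H2 <- h[["H1"]] - spec[1]^2
    expect_true(h[["H12"]] >= h[["H1"]])
    expect_true(h[["H1"]] >= H2)
    expect_true(all(c(h[["H1"]], h[["H12"]]) <= 1 + 1e-12))
    expect_true(h[["H2_over_H1"]] >= 0 && h[["H2_over_H1"]] < 1)
  }
})

test_that("r2 matches the D^2 haplotype-count definition", {
  a <- c(1, 1, 1, 0, 0, 0, 0, 1)
  expect_equal(r2_pair(a, a), 1)
  # AB, Ab, aB, ab counts 3, 1, 1, 3 over n = 8
  sa <- c(rep(1, 3), rep(1, 1), rep(0, 1), rep(0, 3))
  sb <- c(rep(1, 3), rep(0, 1), rep(1, 1), rep(0, 3))
  expect_equal(r2_pair(sa, sb), 0.25)
  expect_equal(r2_pair(sa, sb), oracle_r2(sa, sb))
  # independent composition: D = 0
  ia <- c(1, 1, 0, 0); ib <- c(1, 0, 1, 0)
  expect_equal(r2_pair(ia, ib), 0)
  expect_error(r2_pair(rep(1, 8), sb), "monomorphic")
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(13)
  for (i in 1:50) {
    a <- rbinom(20, 1, 0.5); b <- rbinom(20, 1, 0.5)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(r2_pair(a, b), r2_pair(b, a))
    expect_equal(r2_pair(1 - a, b), r2_pair(a, b))
    expect_equal(r2_pair(a, 1 - b), r2_pair(a, b))
  }
})

test_that("r2 moments match a double-loop oracle and the degenerate rule", {
  h <- random_hapmat(20, 20, seed = 21)
  wa <- h$alleles[, 1:10]; wb <- h$alleles[, 11:20]
  expect_equal(unname(r2_moments(wa, wb)), oracle_r2_moments(wa, wb),
               tolerance = 1e-12)
  expect_equal(unname(r2_moments(wa)), oracle_r2_moments(wa),
               tolerance = 1e-12)
  # all pairwise r2 equal -> (c, 0, 0, 0): perfectly correlated sites
  base <- c(rep(0, 5), rep(1, 5))
  wa_eq <- cbind(base, base, base)
  expect_equal(unname(r2_moments(wa_eq)), c(1, 0, 0, 0))
})

test_that("featurize fills 9 x p curves and padded haplotype frequencies", {
  h <- random_hapmat(25, 660, seed = 31)
  l <- build_layout()
  fc <- featurize(h, l, 0)
  expect_equal(dim(fc$curves), c(9, 128))
  expect_false(anyNA(fc$curves))
  # windowed values agree with direct per-window computation
  w5 <- h$alleles[, (l$windows[5, 1] + 1):(l$windows[5, 2] + 1)]
  expect_equal(unname(fc$curves["pi", 5]), oracle_pi(w5))
  sp5 <- as.numeric(oracle_spectrum(w5))
  expect_equal(unname(fc$curves["hapfreq1", 5]), sp5[1])
  expect_equal(fc$curves[paste0("hapfreq", 1:5), 5], c(sp5, numeric(5))[1:5],
               ignore_attr = TRUE)
  expect_error(featurize(h, l, 100), "anchor does not fit")
})

test_that("two-dimensional blocks are symmetric with 2,080 unique pairs at p = 128", {
  l <- build_layout()
  q <- length(l$nonoverlapping_ids)
  expect_equal(q * (q + 1) / 2, 2080)
  h <- random_hapmat(20, 645, seed = 33)
  fc <- featurize(h, l, 0, include_2d = TRUE)
  for (nm in names(fc$twod)) {
    expect_equal(fc$twod[[nm]], t(fc$twod[[nm]]))
    expect_equal(dim(fc$twod[[nm]]), c(64, 64))
  }
  expect_true(all(fc$twod$r2_mean >= 0 & fc$twod$r2_mean <= 1))
  expect_true(all(fc$twod$r2_var >= 0))
  # spot-check one off-diagonal entry against the oracle
  ids <- l$nonoverlapping_ids
  wa <- h$alleles[, (l$windows[ids[3] + 1, 1] + 1):(l$windows[ids[3] + 1, 2] + 1)]
  wb <- h$alleles[, (l$windows[ids[10] + 1, 1] + 1):(l$windows[ids[10] + 1, 2] + 1)]
  mom <- oracle_r2_moments(wa, wb)
  expect_equal(fc$twod$r2_mean[3, 10], mom[1])
  expect_equal(fc$twod$r2_kurt[3, 10], mom[4])
})

test_that("a centered diversity trough yields centrally extreme curves", {
  h <- generate_haplotypes(fixture_spec(n_haplotypes = 60, n_snps = 900,
                                        pattern = "trough", seed = 5))
  hf <- filter_minor_allele_count(h)
  l <- build_layout()
  off <- (ncol(hf$alleles) - l$span) %/% 2
  fc <- featurize(hf, l, off)
  expect_true(abs(which.min(fc$curves["pi", ]) - 64.5) <= 3.5)
  expect_true(abs(which.max(fc$curves["H12", ]) - 64.5) <= 3.5)
})

test_that("standardization uses frozen training moments", {
  p <- 16
  mk <- function(val) feature_curves(matrix(val, 9, p))
  # identical observations: zero-variance guard
  expect_warning(sp0 <- fit_standardization(list(mk(2), mk(2))),
                 "zero training variance")
  expect_true(all(sp0$sds == 1))
  z <- standardize_curves(mk(2), sp0)
  expect_true(all(z$curves == 0))
  # values {1, 3} -> z-scores -1, +1 (population SD)
  sp <- fit_standardization(list(mk(1), mk(3)))
  expect_equal(standardize_curves(mk(1), sp)$curves,
               matrix(-1, 9, p, dimnames = list(rownames(sp$means), NULL)))
  expect_equal(unname(standardize_curves(mk(3), sp)$curves[1, 1]), 1)
  expect_error(standardize_curves(standardize_curves(mk(1), sp), sp),
               "already standardized")
})

test_that("train-then-apply standardization centers the training set", {
  set.seed(17)
  train <- lapply(1:12, function(i) feature_curves(matrix(rnorm(9 * 8), 9, 8)))
  sp <- fit_standardization(train)
  zs <- lapply(train, standardize_curves, sp = sp)
  arr <- simplify2array(lapply(zs, function(z) z$curves))
  expect_lt(max(abs(apply(arr, c(1, 2), mean))), 1e-12)
  expect_lt(max(abs(apply(arr, c(1, 2), function(v) mean((v - mean(v))^2)) - 1)),
            1e-12)
})

test_that("feature tables round-trip through TSV", {
  h <- random_hapmat(15, 50, seed = 41)
  l <- build_layout(p = 4, window_snps = 10, overlap_snps = 5)
  fcs <- list(featurize(h, l, 0, include_2d = TRUE),
              featurize(h, l, 5, include_2d = TRUE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(fcs, f)
  back <- read_features_tsv(f)
  expect_equal(back[[1]]$curves, fcs[[1]]$curves, tolerance = 1e-12)
  expect_equal(back[[2]]$twod$r2_kurt, fcs[[2]]$twod$r2_kurt,
               tolerance = 1e-12)
})
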