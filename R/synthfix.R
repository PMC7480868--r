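# Seeded synthetic-data generators. These are deliberately NOT
# population-genetic simulations (no coalescent, no recombination model):
# they construct haplotype matrices and feature curves whose spatial
# diversity patterns mimic the qualitative signatures of sweeps (a central
# diversity trough with elevated haplotype homozygosity) and adaptive
# introgression (a trough flanked by a diversity crest), so the statistical
# machinery can be tested end to end without external data.

#' Specify a synthetic fixture
#'
#' @param n_haplotypes Number of haplotypes (>= 4).
#' @param n_snps Number of segregating sites.
#' @param pattern Spatial diversity pattern: `"flat"` (constant), `"trough"`
#'   (sweep-like central loss of diversity), or `"trough_plus_crest"`
#'   (adaptive-introgression-like trough with flanking excess diversity).
#' @param trough_depth Fraction of haplotypes pulled onto the common
#'   lineage at the trough center, in `[0, 1]`.
#' @param trough_width Trough standard deviation as a fraction of the
#'   region.
#' @param crest_height Intensity of the flanking diversity excess in
#'   `[0, 1]`.
#' @param noise_sd Per-cell allele flip probability.
#' @param n_groups Number of background haplotype lineages.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_haplotypes = 100L, n_snps = 800L,
                         pattern = c("flat", "trough", "trough_plus_crest"),
                         trough_depth = 0.9, trough_width = 0.15,
                         crest_height = 0.5, noise_sd = 0.0,
                         n_groups = 6L, seed = 1L) {
  pattern <- match.arg(pattern)
  if (n_haplotypes < 4) stop("need n_haplotypes >= 4", call. = FALSE)
  if (trough_depth < 0 || trough_depth > 1) {
    stop("trough_depth must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_snps = as.integer(n_snps), pattern = pattern,
                 trough_depth = trough_depth, trough_width = trough_width,
                 crest_height = crest_height, noise_sd = noise_sd,
                 n_groups = as.integer(n_groups), seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic haplotype matrix
#'
#' Haplotypes are copies of a small set of founder lineages; under the
#' trough patterns a spatially varying fraction of haplotypes is pulled
#' onto a single common lineage (peaking at `trough_depth` in the center),
#' which raises windowed haplotype homozygosity (H1/H12) and depresses
#' pairwise diversity exactly where a sweep would. The crest pattern adds a
#' diverged donor lineage in two flanking bands. A pure function of the
#' spec (seeded); the caller's RNG state is untouched.
#'
#' @param spec A [fixture_spec()].
#' @return A [haplotype_matrix()] (columns may become monomorphic inside a
#'   deep trough; apply [filter_minor_allele_count()] before featurizing).
#' @export
generate_haplotypes <- function(spec) {
  n <- spec$n_haplotypes; S <- spec$n_snps; G <- spec$n_groups
  with_seed(spec$seed, {
    group <- rep(seq_len(G), length.out = n)
    alleles <- if (spec$pattern == "flat" && spec$noise_sd == 0) {
      # two constant lineages: every window sees the identical spectrum
      matrix(rep(group %% 2L, S), n, S)
    } else {
      founders <- matrix(stats::rbinom(G * S, 1L, 0.5), G, S)
      A <- founders[group, , drop = FALSE]
      t_ax <- (seq_len(S) - 0.5) / S
      if (spec$pattern %in% c("trough", "trough_plus_crest")) {
        q <- spec$trough_depth *
          exp(-((t_ax - 0.5) / spec$trough_width)^2 / 2)
        for (s in seq_len(S)) {
          k <- round(q[s] * n)
          if (k > 0) A[seq_len(k), s] <- founders[1L, s]
        }
      }
      if (spec$pattern == "trough_plus_crest") {
        # diverged donor lineage in two bands flanking the trough
        band <- spec$crest_height *
          (exp(-((t_ax - 0.5 - 2.2 * spec$trough_width) /
                   spec$trough_width)^2 / 2) +
           exp(-((t_ax - 0.5 + 2.2 * spec$trough_width) /
                   spec$trough_width)^2 / 2))
        donors <- which(group == G)
        for (s in seq_len(S)) {
          if (stats::runif(1) < band[s]) {
            A[donors, s] <- 1L - founders[1L, s]
          }
        }
      }
      if (spec$noise_sd > 0) {
        flip <- matrix(stats::rbinom(n * S, 1L, min(spec$noise_sd, 1)),
                       n, S)
        A <- abs(A - flip)
      }
      A
    }
    positions <- cumsum(sample(5:30, S, replace = TRUE))
    haplotype_matrix(alleles, positions, chrom = "chrSim")
  })
}

# smooth bump over window positions used by the curve-space templates
window_bump <- function(p, width = 0.12) {
  t_ax <- (seq_len(p) - 0.5) / p
  exp(-((t_ax - 0.5) / width)^2 / 2)
}

# class template: baseline levels of the nine statistics with
# pattern-dependent spatial deformation
curve_template <- function(p, pattern, trough_depth = 0.7,
                           crest_height = 0.5, width = 0.12) {
  base <- c(pi = 2.5, H1 = 0.15, H12 = 0.2, H2_H1 = 0.6,
            hapfreq1 = 0.25, hapfreq2 = 0.15, hapfreq3 = 0.1,
            hapfreq4 = 0.08, hapfreq5 = 0.06)
  curves <- matrix(base, length(base), p, dimnames = list(STAT_NAMES, NULL))
  if (pattern %in% c("trough", "trough_plus_crest")) {
    b <- window_bump(p, width)
    curves["pi", ] <- base["pi"] * (1 - trough_depth * b)
    curves["H1", ] <- base["H1"] + trough_depth * b * (0.75 - base["H1"])
    curves["H12", ] <- base["H12"] + trough_depth * b * (0.85 - base["H12"])
    curves["H2_H1", ] <- base["H2_H1"] * (1 - 0.8 * trough_depth * b)
    curves["hapfreq1", ] <- base["hapfreq1"] +
      trough_depth * b * (0.85 - base["hapfreq1"])
  }
  if (pattern == "trough_plus_crest") {
    t_ax <- (seq_len(p) - 0.5) / p
    band <- exp(-((t_ax - 0.5 - 2.2 * width) / width)^2 / 2) +
      exp(-((t_ax - 0.5 + 2.2 * width) / width)^2 / 2)
    curves["pi", ] <- curves["pi", ] + crest_height * 2 * band
    curves["H2_H1", ] <- pmin(curves["H2_H1", ] + 0.3 * crest_height * band,
                              0.95)
  }
  curves
}

#' Generate labeled feature-curve fixtures
#'
#' Draws observations directly in curve space: each class has a template
#' (built from the fixture patterns) and observations are template plus iid
#' Gaussian noise. When `response_map` is enabled, three latent parameters
#' `u1, u2, u3 ~ U(0, 1)` deform the template linearly (trough depth in pi,
#' H12 bump height, top-haplotype-frequency bump) and the responses are a
#' known affine function of them on the log10 scale
#' (`s = 10^(-4 + 2 u1)`, `f = 10^(-3 + 2 u2)`, `T = 10^(2 + 1.5 u3)`),
#' which makes predictor parameter-recovery testable by construction.
#'
#' @param class_specs Named character vector or list mapping class labels to
#'   patterns (e.g. `c(neutral = "flat", sweep = "trough")`).
#' @param n_per_class Observations per class (>= 1).
#' @param response_map `NULL` (classification fixture), `TRUE` for the
#'   built-in affine map above, or a `function(latents)` returning a data
#'   frame of responses.
#' @param p Number of windows (default 128).
#' @param noise_sd Iid Gaussian noise SD added to every curve cell.
#' @param seed Integer seed.
#' @return A list with elements `features` (list of [feature_curves()]),
#'   `labels` (factor), `responses` (data frame or `NULL`), and `latents`.
#' @export
generate_feature_fixtures <- function(class_specs, n_per_class,
                                      response_map = NULL, p = 128L,
                                      noise_sd = 0.05, seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  class_specs <- unlist(class_specs)
  if (anyDuplicated(class_specs)) {
    stop("class specs must be distinct patterns", call. = FALSE)
  }
  m <- length(STAT_NAMES)
  with_seed(seed, {
    features <- list(); labels <- character(0)
    latents <- NULL; responses <- NULL
    for (cl in names(class_specs)) {
      template <- curve_template(p, class_specs[[cl]])
      for (i in seq_len(n_per_class)) {
        curves <- template
        if (!is.null(response_map)) {
          u <- stats::runif(3)
          b <- window_bump(p)
          curves["pi", ] <- curves["pi", ] - 1.5 * u[1] * b
          curves["H12", ] <- curves["H12", ] + 0.5 * u[2] * b
          curves["hapfreq1", ] <- curves["hapfreq1", ] + 0.3 * u[3] * b
          latents <- rbind(latents, u)
        }
        curves <- curves + matrix(stats::rnorm(m * p, sd = noise_sd), m, p)
        features <- c(features, list(feature_curves(
          curves, obs_id = paste0(cl, "_", i))))
        labels <- c(labels, cl)
      }
    }
    if (!is.null(response_map)) {
      latents <- as.data.frame(latents)
      names(latents) <- c("u1", "u2", "u3")
      rownames(latents) <- NULL
      responses <- if (is.function(response_map)) {
        response_map(latents)
      } else {
        data.frame(s = 10^(-4 + 2 * latents$u1),
                   f = 10^(-3 + 2 * latents$u2),
                   T = 10^(2 + 1.5 * latents$u3))
      }
    }
    list(features = features, labels = factor(labels),
         responses = responses, latents = latents)
  })
}

#' Missing-data block mask
#'
#' Emulates mappability/alignability filtering: removes `n_blocks`
#' contiguous, non-overlapping blocks of SNP indices, each holding
#' `round(frac_per_block * S)` SNPs (defaults: ten blocks of 3% each, 30%
#' of the data in total). Blocks are placed uniformly at random by seeded
#' rejection sampling; if disjoint placement fails after `max_tries`
#' attempts a packing error is raised.
#'
#' @param S Total number of SNPs.
#' @param n_blocks Number of blocks (default 10).
#' @param frac_per_block Fraction of SNPs per block (default 0.03);
#'   `n_blocks * frac_per_block` must not exceed 1.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempt budget.
#' @return Sorted integer vector of removed (1-based) SNP indices, with the
#'   block starts in attribute `"blocks"`.
#' @export
missing_data_mask <- function(S, n_blocks = 10L, frac_per_block = 0.03,
                              seed = 1L, max_tries = 10000L) {
  S <- as.integer(S)
  if (n_blocks * frac_per_block > 1) {
    stop("n_blocks * frac_per_block must be <= 1", call. = FALSE)
  }
  bs <- as.integer(round(frac_per_block * S))
  if (bs == 0L || n_blocks == 0L) {
    return(structure(integer(0), blocks = integer(0), block_size = bs))
  }
  if (n_blocks * bs > S) {
    stop("blocks cannot be packed disjointly into ", S, " SNPs",
         call. = FALSE)
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      starts <- sample.int(S - bs + 1L, n_blocks, replace = TRUE)
      ord <- sort(starts)
      if (all(diff(ord) >= bs)) {
        idx <- sort(unlist(lapply(ord, function(st) st:(st + bs - 1L))))
        return(structure(idx, blocks = ord, block_size = bs))
      }
    }
    stop("could not place ", n_blocks, " disjoint blocks of ", bs,
         " SNPs in ", S, " after ", max_tries, " attempts", call. = FALSE)
  })
}
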