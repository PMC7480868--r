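# Brute-force oracles and small fixture builders shared across tests. The
# oracles enumerate definitions directly (double loops, string counting)
# and stay independent of the implementation paths they check.

random_hapmat <- function(n, S, seed, chrom = "chrT") {
  set.seed(seed)
  # rejection per column keeps every site polymorphic
  cols <- replicate(S, {
    repeat {
      v <- rbinom(n, 1, runif(1, 0.1, 0.9))
      if (sum(v) > 0 && sum(v) < n) return(v)
    }
  })
  haplotype_matrix(cols, positions = sort(sample.int(S * 50, S)),
                   chrom = chrom)
}

oracle_pi <- function(mat) {
  n <- nrow(mat); tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(mat[i, ] != mat[j, ])
  }
  tot / choose(n, 2)
}

oracle_spectrum <- function(mat) {
  keys <- apply(mat, 1, paste, collapse = "")
  as.numeric(sort(table(keys), decreasing = TRUE)) / nrow(mat)
}

oracle_r2 <- function(a, b) {
  n <- length(a)
  pA <- mean(a); pB <- mean(b)
  D <- mean(a == 1 & b == 1) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

oracle_r2_moments <- function(wa, wb = NULL) {
  self <- is.null(wb)
  if (self) wb <- wa
  vals <- c()
  for (i in seq_len(ncol(wa))) {
    js <- if (self) seq_len(ncol(wb)) else seq_len(ncol(wb))
    for (j in js) {
      if (self && j <= i) next
      vals <- c(vals, oracle_r2(wa[, i], wb[, j]))
    }
  }
  m <- mean(vals); d <- vals - m; m2 <- mean(d^2)
  if (m2 <= 1e-20) return(c(m, 0, 0, 0))
  c(m, m2, mean(d^3) / m2^1.5, mean(d^4) / m2^2)
}

oracle_mac_keep <- function(mat, min_count) {
  keep <- logical(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    cnt1 <- sum(mat[, s]); cnt0 <- nrow(mat) - cnt1
    keep[s] <- min(cnt0, cnt1) >= min_count
  }
  keep
}

# explicit orthonormal Haar matrix for p = 8, j0 = 0 (fathers then mothers
# coarse-to-fine), built from the basis definition rather than the filter
# bank
haar8_matrix <- function() {
  rbind(
    rep(1, 8) / sqrt(8),
    c(1, 1, 1, 1, -1, -1, -1, -1) / sqrt(8),
    c(1, 1, -1, -1, 0, 0, 0, 0) / 2,
    c(0, 0, 0, 0, 1, 1, -1, -1) / 2,
    c(1, -1, 0, 0, 0, 0, 0, 0) / sqrt(2),
    c(0, 0, 1, -1, 0, 0, 0, 0) / sqrt(2),
    c(0, 0, 0, 0, 1, -1, 0, 0) / sqrt(2),
    c(0, 0, 0, 0, 0, 0, 1, -1) / sqrt(2)
  )
}

write_test_vcf <- function(path, n_samples = 3, unphased_rows = integer(0)) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("S", seq_len(n_samples))),
                 collapse = "\t"))
  set.seed(42)
  rows <- vapply(1:10, function(i) {
    gts <- replicate(n_samples, {
      repeat {
        g <- paste(rbinom(2, 1, 0.5), collapse = "|")
        if (TRUE) return(g)
      }
    })
    # guarantee polymorphism
    gts[1] <- "0|1"
    if (i %in% unphased_rows) gts[2] <- sub("\\|", "/", "0/1")
    paste(c("chr9", i * 100, ".", "A", "T", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

total_variation <- function(v) sum(abs(diff(v)))

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
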