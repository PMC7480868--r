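# Genome-scan driver: anchor placement, record contracts, gene
# summarization. The classifier is trained on featurized synthetic regions
# so the scan exercises the full haplotype -> curves -> wavelet -> softmax
# path.

train_scan_models <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    l <- build_layout()
    feats <- list(); labs <- character(0)
    for (i in 1:14) {
      for (pat in c("flat", "trough")) {
        h <- generate_haplotypes(fixture_spec(
          n_haplotypes = 50, n_snps = 1000, pattern = pat,
          noise_sd = 0.02, seed = 1000 + 10 * i + (pat == "trough")))
        hf <- filter_minor_allele_count(h)
        off <- (ncol(hf$alleles) - l$span) %/% 2
        feats <- c(feats, list(featurize(hf, l, off)))
        labs <- c(labs, if (pat == "flat") "neutral" else "sweep")
      }
    }
    m <- fit_classifier(feats, labs, gamma_grid = 1, level_grid = 1,
                        folds = 4, seed = 5, nlambda = 20)
    cache <<- list(classifier = m, layout = l)
    cache
  }
})

test_that("a span-sized region yields exactly one sorted record", {
  tm <- train_scan_models()
  h <- generate_haplotypes(fixture_spec(n_haplotypes = 50, n_snps = 800,
                                        pattern = "trough", noise_sd = 0.02,
                                        seed = 77))
  hf <- filter_minor_allele_count(h)
  hf <- sweepwave:::subset_sites(hf, 1:645)
  sc <- run_scan(hf, tm$classifier, layout = tm$layout)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$pos, hf$positions[323])  # 0-based 322
  expect_equal(sc$span_start, hf$positions[1])
  expect_equal(sc$span_end, hf$positions[645])
  expect_equal(sc$prob_neutral + sc$prob_sweep, 1, tolerance = 1e-12)
})

test_that("a centered sweep-like trough is scored above neutrality", {
  tm <- train_scan_models()
  h <- generate_haplotypes(fixture_spec(n_haplotypes = 50, n_snps = 1000,
                                        pattern = "trough", noise_sd = 0.02,
                                        seed = 201))
  hf <- filter_minor_allele_count(h)
  sc <- run_scan(hf, tm$classifier, layout = tm$layout)
  expect_gt(max(sc$prob_sweep), max(sc$prob_neutral[
    which.max(sc$prob_sweep)]))
  # neutral region scores neutral throughout
  hn <- generate_haplotypes(fixture_spec(n_haplotypes = 50, n_snps = 1000,
                                         pattern = "flat", noise_sd = 0.02,
                                         seed = 202))
  hnf <- filter_minor_allele_count(hn)
  scn <- run_scan(hnf, tm$classifier, layout = tm$layout)
  expect_gt(mean(scn$prob_neutral), 0.5)
})

test_that("regions shorter than the span produce zero records with a notice", {
  tm <- train_scan_models()
  h <- generate_haplotypes(fixture_spec(n_haplotypes = 50, n_snps = 800,
                                        pattern = "flat", noise_sd = 0.02,
                                        seed = 301))
  hf <- filter_minor_allele_count(h)
  hf <- sweepwave:::subset_sites(hf, 1:600)
  expect_message(sc <- run_scan(hf, tm$classifier, layout = tm$layout),
                 "no SNPs can be classified")
  expect_equal(nrow(sc), 0)
})

test_that("consecutive records sit five filtered SNPs apart and runs are deterministic", {
  tm <- train_scan_models()
  h <- generate_haplotypes(fixture_spec(n_haplotypes = 50, n_snps = 830,
                                        pattern = "trough", noise_sd = 0.02,
                                        seed = 401))
  hf <- filter_minor_allele_count(h)
  sc <- run_scan(hf, tm$classifier, layout = tm$layout)
  idx <- match(sc$pos, hf$positions)
  expect_true(all(diff(idx) == 5))
  sc2 <- run_scan(hf, tm$classifier, layout = tm$layout)
  expect_identical(sc, sc2)
})

test_that("predictor output is masked to non-neutral calls", {
  tm <- train_scan_models()
  fx <- generate_feature_fixtures(c(any = "trough"), n_per_class = 20,
                                  response_map = TRUE, seed = 55)
  pm <- fit_predictor(fx$features, fx$responses, gamma_grid = 1,
                      level_grid = 1, folds = 4, seed = 5, nlambda = 10)
  h <- generate_haplotypes(fixture_spec(n_haplotypes = 50, n_snps = 700,
                                        pattern = "flat", noise_sd = 0.02,
                                        seed = 501))
  hf <- filter_minor_allele_count(h)
  # the predictor was trained on curve-space fixtures, so applying it to
  # haplotype-derived curves warns about leaving the training envelope
  expect_warning(
    sc <- run_scan(hf, tm$classifier, predictor = pm, layout = tm$layout,
                   threshold = 0.99),  # force neutral calls
    "training envelope")
  expect_true(all(is.na(sc$s)))
  expect_warning(
    sc_all <- run_scan(hf, tm$classifier, predictor = pm,
                       layout = tm$layout, threshold = 0.99,
                       emit_all = TRUE),
    "training envelope")
  expect_false(anyNA(sc_all$s))
})

test_that("gene summaries pick the strongest record with position tie-breaks", {
  rec <- data.frame(chrom = "c", pos = c(100, 200, 300),
                    span_start = 1, span_end = 400,
                    prob_neutral = c(0.4, 0.1, 0.4),
                    prob_sweep = c(0.6, 0.9, 0.6),
                    call = c("neutral", "sweep", "neutral"))
  class(rec) <- c("sweepwave_scan", "data.frame")
  best <- summarize_gene(rec, list("c", 0, 1000))
  expect_equal(best$pos, 200)
  tie <- summarize_gene(rec[c(1, 3), ], list("c", 0, 1000))
  expect_equal(tie$pos, 100)  # equal probabilities -> smallest position
  single <- summarize_gene(rec, list("c", 250, 1000))
  expect_equal(single$pos, 300)
  expect_error(summarize_gene(rec, list("c", 5000, 6000)), "no scan record")
})

test_that("scan records export as BED-like TSV", {
  rec <- data.frame(chrom = "c", pos = c(100, 200),
                    span_start = 1, span_end = 400,
                    prob_neutral = c(0.4, 0.2), prob_sweep = c(0.6, 0.8),
                    call = c("neutral", "sweep"), s = c(NA, 0.01))
  class(rec) <- c("sweepwave_scan", "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(rec, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$start, c(99, 199))
  expect_equal(back$end, c(100, 200))
  expect_equal(back$call, c("neutral", "sweep"))
})
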