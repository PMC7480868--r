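# Genome-scan driver: slide the window layout one step at a time across a
# filtered chromosome, classify each central SNP, and attach parameter
# predictions to non-neutral calls.

#' Scan a chromosome for selection signals
#'
#' Places the window layout at every scan anchor (the classified SNP shifts
#' by one window step, 5 SNPs at the defaults, per iteration), computes
#' feature curves, classifies the central SNP, and — when a predictor is
#' supplied — predicts selection parameters. Parameters are computed for
#' every anchor but reported only on non-neutral calls unless
#' `emit_all = TRUE`. Regions shorter than the span yield zero records and
#' a notice that no SNP can be classified.
#'
#' @param h A filtered [haplotype_matrix()] (minor-allele-count filter and
#'   any region mask already applied).
#' @param classifier A fitted [fit_classifier()].
#' @param predictor Optional fitted [fit_predictor()].
#' @param layout A [build_layout()] compatible with the models
#'   (default: the standard layout at the classifier's `p`).
#' @param threshold Sweep-probability threshold for [call_class()].
#' @param emit_all Report parameter predictions on neutral calls too.
#' @return A data frame of class `"sweepwave_scan"`, sorted by position:
#'   `chrom`, `pos` (bp of the classified SNP), `span_start`, `span_end`
#'   (bp footprint), one `prob_<class>` column per class, `call`, and the
#'   predictor's response columns (NA where masked).
#' @export
run_scan <- function(h, classifier, predictor = NULL, layout = NULL,
                     threshold = 0.7, emit_all = FALSE) {
  if (is.null(layout)) layout <- build_layout(p = classifier$p)
  if (layout$p != classifier$p) {
    stop("layout p = ", layout$p, " does not match the classifier (",
         classifier$p, ")", call. = FALSE)
  }
  if (!is.null(predictor) && predictor$p != classifier$p) {
    stop("predictor and classifier disagree on p", call. = FALSE)
  }
  anchors <- scan_anchors(ncol(h$alleles), layout)
  if (nrow(anchors) == 0) {
    out <- data.frame(chrom = character(), pos = numeric(),
                      span_start = numeric(), span_end = numeric())
    class(out) <- c("sweepwave_scan", "data.frame")
    return(out)
  }
  fcs <- lapply(anchors$offset, function(off) {
    featurize(h, layout, anchor_offset = off,
              include_2d = classifier$include_2d)
  })
  probs <- predict(classifier, fcs, type = "prob")
  calls <- apply(probs, 1, call_class, sweep_threshold = threshold)
  out <- data.frame(
    chrom = h$chrom,
    pos = h$positions[anchors$classified_index + 1L],
    span_start = h$positions[anchors$offset + 1L],
    span_end = h$positions[anchors$offset + layout$span],
    stringsAsFactors = FALSE
  )
  pcols <- as.data.frame(probs)
  names(pcols) <- paste0("prob_", classifier$classes)
  out <- cbind(out, pcols)
  out$call <- calls
  if (!is.null(predictor)) {
    params <- predict(predictor, fcs, scale = "natural")
    if (!emit_all) {
      params[calls == "neutral", ] <- NA_real_
    }
    out <- cbind(out, params)
  }
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sweepwave_scan", "data.frame")
  out
}

#' @export
print.sweepwave_scan <- function(x, ...) {
  cat(sprintf("Selection scan: %d classified SNP(s)", nrow(x)))
  if (nrow(x) > 0) {
    tab <- table(x$call)
    cat(" [", paste(names(tab), tab, sep = ": ", collapse = ", "), "]")
  }
  cat("\n")
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Best-supported record within a gene
#'
#' Among scan records whose classified position falls inside the interval
#' (BED semantics, 0-based half-open), returns the one with the highest
#' non-neutral class probability; ties go to the smallest position.
#'
#' @param records A [run_scan()] result.
#' @param gene_interval List or vector `(chrom, start, end)`.
#' @return A single-row data frame.
#' @export
summarize_gene <- function(records, gene_interval) {
  if (nrow(records) == 0) stop("no scan records", call. = FALSE)
  chrom <- as.character(gene_interval[[1]])
  start <- as.numeric(gene_interval[[2]])
  end <- as.numeric(gene_interval[[3]])
  inb <- records$chrom == chrom & (records$pos - 1) >= start &
    (records$pos - 1) < end
  if (!any(inb)) {
    stop("no scan record inside ", chrom, ":", start, "-", end,
         call. = FALSE)
  }
  r <- records[inb, , drop = FALSE]
  pc <- grep("^prob_", names(r), value = TRUE)
  pc <- setdiff(pc, "prob_neutral")
  best_prob <- do.call(pmax, c(as.list(r[pc]), list(na.rm = TRUE)))
  r <- r[order(-best_prob, r$pos), , drop = FALSE]
  r[1, , drop = FALSE]
}

#' Write scan records as a BED-like TSV
#'
#' Columns: chrom, 0-based start (pos - 1), pos, call, per-class
#' probabilities, and any predicted parameters.
#'
#' @param records A [run_scan()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(records, path) {
  out <- data.frame(chrom = records$chrom, start = records$pos - 1,
                    end = records$pos, call = records$call,
                    records[grep("^prob_", names(records))],
                    check.names = FALSE)
  extra <- setdiff(names(records),
                   c("chrom", "pos", "span_start", "span_end", "call",
                     grep("^prob_", names(records), value = TRUE)))
  if (length(extra)) out <- cbind(out, records[extra])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
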