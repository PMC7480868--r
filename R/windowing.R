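# SNP-window layout arithmetic: the p overlapping 10-SNP windows, the
# alternating non-overlapping windows used for two-dimensional statistics,
# the classified central SNP, and the one-window scan step.

#' Build the SNP-window layout
#'
#' Delimits `p` windows of `window_snps` SNPs, each overlapping its neighbor
#' by `overlap_snps`, on the filtered SNP axis. Window `i` (0-based) starts
#' at `i * (window_snps - overlap_snps)`; the total span is
#' `window_snps + (p - 1) * (window_snps - overlap_snps)` SNPs (645 at the
#' defaults). The classified SNP is the middle SNP of the overlap between
#' windows `p/2` and `p/2 + 1` (1-based numbering); an even-length overlap
#' takes the lower median. The alternating windows `0, 2, 4, ...` (`p/2` of
#' them, pairwise disjoint) are used for two-dimensional statistics.
#'
#' @param p Number of windows; must be a power of two (wavelet requirement).
#' @param window_snps SNPs per window (default 10).
#' @param overlap_snps Overlap with each neighbor (default 5);
#'   `0 <= overlap_snps < window_snps`.
#' @return An object of class `"window_layout"` with fields `p`,
#'   `window_snps`, `overlap_snps`, `step`, `span`, `windows` (p x 2 matrix
#'   of 0-based inclusive first/last SNP indices), `central_snp_index`
#'   (0-based), and `nonoverlapping_ids` (0-based window ids).
#' @examples
#' build_layout()$span  # 645
#' @export
build_layout <- function(p = 128L, window_snps = 10L, overlap_snps = 5L) {
  if (!is_pow2(p)) {
    stop("p must be a power of two (discrete wavelet transform requirement), ",
         "got ", p, call. = FALSE)
  }
  p <- as.integer(p); window_snps <- as.integer(window_snps)
  overlap_snps <- as.integer(overlap_snps)
  if (overlap_snps < 0 || overlap_snps >= window_snps) {
    stop("need 0 <= overlap_snps < window_snps", call. = FALSE)
  }
  step <- window_snps - overlap_snps
  starts <- (seq_len(p) - 1L) * step
  windows <- cbind(first = starts, last = starts + window_snps - 1L)
  span <- window_snps + (p - 1L) * step
  # overlap of windows p/2 and p/2 + 1 (1-based) = 0-based ids p/2-1, p/2
  a <- p / 2L - 1L; b <- p / 2L
  ov <- seq.int(windows[b + 1L, "first"], windows[a + 1L, "last"])
  ov <- ov[ov >= windows[b + 1L, "first"]]
  central <- if (overlap_snps > 0) {
    ov[ceiling(length(ov) / 2)]  # lower median for even-length overlaps
  } else {
    windows[b + 1L, "first"]
  }
  structure(
    list(p = p, window_snps = window_snps, overlap_snps = overlap_snps,
         step = step, span = span, windows = windows,
         central_snp_index = as.integer(central),
         nonoverlapping_ids = seq.int(0L, p - 2L, by = 2L)),
    class = "window_layout"
  )
}

#' @export
print.window_layout <- function(x, ...) {
  cat(sprintf(
    "Window layout: %d windows of %d SNPs (overlap %d), span %d SNPs\n",
    x$p, x$window_snps, x$overlap_snps, x$span))
  cat(sprintf(
    "  classified SNP: 0-based index %d (middle of the overlap of windows %d and %d)\n",
    x$central_snp_index, x$p / 2L, x$p / 2L + 1L))
  cat(sprintf("  %d alternating non-overlapping windows for 2-D statistics\n",
              length(x$nonoverlapping_ids)))
  invisible(x)
}

#' Enumerate scan anchors along a chromosome
#'
#' Places the layout at offsets `0, step, 2*step, ...` while the full span
#' still fits in the `S` filtered SNPs, so the classified SNP shifts by one
#' window step (5 SNPs at the defaults) per iteration. Regions shorter than
#' the span yield no anchors and a notice that they cannot be classified.
#'
#' @param S Total number of (filtered) SNPs available.
#' @param layout A [build_layout()].
#' @return A data frame with columns `offset` (0-based first SNP of the
#'   placement) and `classified_index` (0-based index of the classified SNP).
#' @examples
#' nrow(scan_anchors(655, build_layout()))  # 3 anchors at offsets 0, 5, 10
#' @export
scan_anchors <- function(S, layout) {
  S <- as.integer(S)
  if (S < layout$span) {
    message("region too short (", S, " SNPs < span ", layout$span,
            "): no SNPs can be classified")
    return(data.frame(offset = integer(), classified_index = integer()))
  }
  offs <- seq.int(0L, S - layout$span, by = layout$step)
  data.frame(offset = offs,
             classified_index = offs + layout$central_snp_index)
}
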