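# Haplotype input/output: phased 0/1 matrices from VCF or ms-style text,
# minor-allele-count filtering, and retained-region (BED) masks.

#' Construct a haplotype matrix
#'
#' A phased, biallelic haplotype sample: an `n x S` matrix of 0/1 alleles
#' (haplotypes in rows, segregating sites in columns) with strictly
#' increasing 1-based bp positions.
#'
#' @param alleles Integer/numeric matrix of 0s and 1s, haplotypes in rows.
#' @param positions Strictly increasing bp coordinates, one per column.
#' @param chrom Chromosome label.
#' @param sample_ids Optional haplotype labels (length `nrow(alleles)`).
#' @return An object of class `"haplotype_matrix"` with fields `alleles`,
#'   `positions`, `chrom`, `sample_ids`.
#' @examples
#' haplotype_matrix(matrix(c(0, 1, 1, 0), 2, 2), positions = c(10, 20))
#' @export
haplotype_matrix <- function(alleles, positions, chrom = "chr1",
                             sample_ids = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L))) {
    stop("alleles must be 0/1 (phased, biallelic)", call. = FALSE)
  }
  positions <- as.numeric(positions)
  if (length(positions) != ncol(alleles)) {
    stop("positions length must equal the number of sites", call. = FALSE)
  }
  if (ncol(alleles) > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (!is.null(sample_ids) && length(sample_ids) != nrow(alleles)) {
    stop("sample_ids length must equal the number of haplotypes",
         call. = FALSE)
  }
  structure(list(alleles = alleles, positions = positions,
                 chrom = as.character(chrom), sample_ids = sample_ids),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("Haplotype matrix: %d haplotypes x %d sites on %s (%s..%s bp)\n",
              nrow(x$alleles), ncol(x$alleles), x$chrom,
              format(min(x$positions)), format(max(x$positions))))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Read phased haplotypes from VCF or ms-style text
#'
#' For VCF input, only phased biallelic SNP records with fully called
#' genotypes are kept; multi-allelic, unphased, or partially missing records
#' are skipped (with a message giving the count), never coerced. For the ms
#' dialect the file must contain a `segsites:` line, a `positions:` line, and
#' one 0/1 string per haplotype. Fractional ms positions are converted to bp
#' by `round(fraction * locus_length)`; ties created by rounding are bumped
#' by +1 bp to preserve strict monotonicity.
#'
#' @param path Path to the input file.
#' @param format `"vcf"` or `"ms"`.
#' @param locus_length Locus length in bp, required when ms positions are
#'   fractions in `[0, 1]`.
#' @param chrom Chromosome label to assign to ms input (VCF input takes it
#'   from the records).
#' @return A [haplotype_matrix()]. Monomorphic columns are dropped.
#' @export
read_haplotypes <- function(path, format = c("vcf", "ms"),
                            locus_length = NULL, chrom = "chr1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  h <- if (format == "ms") {
    read_ms_haplotypes(path, locus_length = locus_length, chrom = chrom)
  } else {
    read_vcf_haplotypes(path)
  }
  poly <- colSums(h$alleles) > 0L & colSums(h$alleles) < nrow(h$alleles)
  if (!any(poly)) {
    stop("no polymorphic sites in ", path, call. = FALSE)
  }
  if (!all(poly)) {
    message(sum(!poly), " monomorphic site(s) dropped")
    h <- subset_sites(h, which(poly))
  }
  h
}

read_ms_haplotypes <- function(path, locus_length = NULL, chrom = "chr1") {
  lines <- readLines(path, warn = FALSE)
  seg_i <- grep("^segsites:", lines)
  if (length(seg_i) == 0) {
    stop("ms format error at line 1: no 'segsites:' line found",
         call. = FALSE)
  }
  seg_i <- seg_i[1]
  S <- suppressWarnings(as.integer(sub("^segsites:\\s*", "", lines[seg_i])))
  if (is.na(S) || S < 1) {
    stop("ms format error at line ", seg_i, ": unparseable segsites count",
         call. = FALSE)
  }
  pos_i <- grep("^positions:", lines)
  if (length(pos_i) == 0 || pos_i[1] < seg_i) {
    stop("ms format error: no 'positions:' line after segsites",
         call. = FALSE)
  }
  pos_i <- pos_i[1]
  pos <- suppressWarnings(as.numeric(
    strsplit(trimws(sub("^positions:\\s*", "", lines[pos_i])), "\\s+")[[1]]))
  if (length(pos) != S || anyNA(pos)) {
    stop("ms format error at line ", pos_i, ": expected ", S,
         " numeric positions", call. = FALSE)
  }
  hap_lines <- lines[-seq_len(pos_i)]
  hap_lines <- hap_lines[nzchar(trimws(hap_lines))]
  if (length(hap_lines) == 0) {
    stop("ms format error: no haplotype rows after positions line",
         call. = FALSE)
  }
  bad <- which(!grepl("^[01]+$", trimws(hap_lines)) |
                 nchar(trimws(hap_lines)) != S)
  if (length(bad) > 0) {
    stop("ms format error at line ", pos_i + bad[1],
         ": haplotype row is not a 0/1 string of length ", S, call. = FALSE)
  }
  alleles <- do.call(rbind, lapply(strsplit(trimws(hap_lines), ""),
                                   as.integer))
  if (all(pos <= 1)) {
    if (is.null(locus_length)) {
      stop("ms positions are fractions; supply locus_length to convert to bp",
           call. = FALSE)
    }
    pos <- round(pos * locus_length)
  } else {
    pos <- round(pos)
  }
  # +1 bumping of rounding ties keeps positions strictly increasing
  for (i in seq_along(pos)[-1]) {
    if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
  }
  haplotype_matrix(alleles, pos, chrom = chrom)
}

read_vcf_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) {
    stop("VCF has no genotype columns", call. = FALSE)
  }
  gt <- gt[, -1, drop = FALSE]  # drop FORMAT
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- sub(":.*$", "", gt)
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  phased <- apply(gt, 1, function(r) {
    all(grepl("^[01]\\|[01]$", r))
  })
  keep <- biallelic & phased
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " VCF record(s) skipped (multi-allelic, unphased, or ",
            "missing genotypes)")
  }
  if (!any(keep)) stop("no usable phased biallelic VCF records", call. = FALSE)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # columns of `gt` are diploid samples; split into two haplotypes each
  hap_of <- function(row) as.integer(unlist(strsplit(row, "\\|")))
  alleles <- t(apply(gt, 1, hap_of))  # sites x (2 * samples)
  alleles <- t(alleles)               # haplotypes x sites
  ids <- as.vector(rbind(paste0(colnames(gt), "_1"),
                         paste0(colnames(gt), "_2")))
  pos <- as.numeric(fix[, "POS"])
  ord <- order(pos)
  h <- haplotype_matrix(alleles[, ord, drop = FALSE], pos[ord],
                        chrom = fix[ord[1], "CHROM"], sample_ids = ids)
  h
}

#' Write haplotypes as ms-style text
#'
#' Serializes a [haplotype_matrix()] in the ms dialect with integer bp
#' positions, so `read_haplotypes(..., format = "ms")` round-trips alleles
#' and positions exactly.
#'
#' @param h A [haplotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(h, path) {
  lines <- c(
    "//",
    paste0("segsites: ", ncol(h$alleles)),
    paste0("positions: ", paste(format(h$positions, scientific = FALSE,
                                       trim = TRUE), collapse = " ")),
    apply(h$alleles, 1, paste, collapse = "")
  )
  writeLines(lines, path)
  invisible(path)
}

subset_sites <- function(h, idx) {
  haplotype_matrix(h$alleles[, idx, drop = FALSE], h$positions[idx],
                   chrom = h$chrom, sample_ids = h$sample_ids)
}

#' Remove sites with low minor-allele count
#'
#' Retains exactly the columns whose minor allele (the rarer of the two) is
#' carried by at least `min_count` haplotypes; the default 3 removes sites
#' with minor allele count less than three. Idempotent; all retained sites
#' are polymorphic.
#'
#' @param h A [haplotype_matrix()].
#' @param min_count Minimum minor-allele count to retain a site (>= 1).
#' @return The filtered [haplotype_matrix()] (possibly with zero sites).
#' @export
filter_minor_allele_count <- function(h, min_count = 3L) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  cs <- colSums(h$alleles)
  mac <- pmin(cs, nrow(h$alleles) - cs)
  subset_sites(h, which(mac >= min_count))
}

#' Construct a retained-region mask
#'
#' Intervals to RETAIN, in BED convention: 0-based, half-open
#' `[start, end)`. Overlapping or book-ended intervals on the same
#' chromosome are merged during normalization.
#'
#' @param chrom Chromosome labels (recycled).
#' @param start,end Interval bounds, `start < end`, 0-based half-open.
#' @return An object of class `"region_mask"`: a data frame with columns
#'   `chrom`, `start`, `end`.
#' @examples
#' region_mask("chr1", c(0, 500), c(100, 900))
#' @export
region_mask <- function(chrom = character(), start = numeric(),
                        end = numeric()) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) {
    stop("mask intervals must satisfy start < end", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    merged <- d[1, , drop = FALSE]
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        j <- nrow(merged)
        if (d$start[i] <= merged$end[j]) {
          merged$end[j] <- max(merged$end[j], d$end[i])
        } else {
          merged <- rbind(merged, d[i, ])
        }
      }
    }
    merged
  }))
  if (is.null(out)) out <- df
  rownames(out) <- NULL
  structure(out, class = c("region_mask", "data.frame"))
}

#' Read a retained-region mask from a BED file
#'
#' Reads the first three BED columns (chrom, start, end; 0-based half-open)
#' as intervals to retain, e.g. a precomputed mappability mask.
#'
#' @param path Path to a BED file.
#' @return A [region_mask()].
#' @export
read_region_mask <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end")[1:3])
  region_mask(bed$chrom, bed$start, bed$end)
}

#' Apply a retained-region mask to a haplotype matrix
#'
#' Keeps the sites whose 1-based position falls inside a retained interval
#' (BED semantics: position `p` is inside `[start, end)` iff
#' `start <= p - 1 < end`). Coordinates are never shifted; downstream
#' windows are SNP-delimited.
#'
#' @param h A [haplotype_matrix()].
#' @param mask A [region_mask()]. An empty mask retains nothing; a non-empty
#'   mask with no intervals on `h$chrom` is an error.
#' @return The masked [haplotype_matrix()].
#' @export
apply_region_mask <- function(h, mask) {
  m <- mask[mask$chrom == h$chrom, , drop = FALSE]
  if (nrow(mask) > 0 && nrow(m) == 0) {
    stop("mask has no intervals on chromosome ", h$chrom, call. = FALSE)
  }
  keep <- rep(FALSE, ncol(h$alleles))
  pos0 <- h$positions - 1
  for (i in seq_len(nrow(m))) {
    keep <- keep | (pos0 >= m$start[i] & pos0 < m$end[i])
  }
  subset_sites(h, which(keep))
}
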