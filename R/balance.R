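# Virtual opposite-allele read set: a diagnostic that isolates
# mapping-induced bias by constructing a read set that is perfectly
# balanced at every SNP by design, remapping it, and recording where the
# balance breaks.

#' Build the doubled opposite-allele read set
#'
#' Selects mapped reads with MAPQ >= `min_mapq` that carry the reference
#' or alternative allele (base quality >= `min_baseq`) at one or more
#' panel SNPs, and emits each such read together with one copy in which
#' the allele at every overlapping panel SNP is swapped to its
#' counterpart (ref <-> alt; third-allele bases are left as they are).
#' The joint set therefore has exactly equal ref and alt representation
#' at every SNP before remapping. Reads whose only SNP bases are third
#' alleles are excluded and counted.
#'
#' @param alignments mapped `read_alignments`.
#' @param panel a [snp_panel].
#' @param min_mapq original mapping quality required (default 30).
#' @param min_baseq base quality required at the SNP (default 30).
#' @return A data frame of class `balanced_reads`: columns read_id, seq
#'   (reference-forward), qual, chrom, start, strand (the original
#'   locus), is_swapped; attribute `n_excluded_other`.
#' @export
build_balanced_readset <- function(alignments, panel, min_mapq = 30L,
                                   min_baseq = 30L) {
  stopifnot(inherits(alignments, "read_alignments"),
            inherits(panel, "snp_panel"))
  aln <- alignments[alignments$mapq >= min_mapq, , drop = FALSE]
  h <- aln_snp_overlap(aln, panel)
  carrier <- (h$is_ref | h$is_alt) & h$baseq >= min_baseq
  sel <- sort(unique(h$aidx[carrier]))
  touched <- sort(unique(h$aidx))
  n_excluded <- length(setdiff(touched, sel))
  aln <- aln[sel, , drop = FALSE]
  hs <- h[h$aidx %in% sel & (h$is_ref | h$is_alt), , drop = FALSE]
  swapped <- aln$sequence
  for (k in seq_len(nrow(hs))) {
    j <- match(hs$aidx[k], sel)
    new <- if (hs$is_ref[k]) panel$alt[hs$pidx[k]] else panel$ref[hs$pidx[k]]
    substr(swapped[j], hs$qoff[k], hs$qoff[k]) <- new
  }
  out <- data.frame(
    read_id = c(aln$read_id, paste0(aln$read_id, "_swap", recycle0 = TRUE)),
    seq = c(aln$sequence, swapped),
    qual = c(aln$qual, aln$qual),
    chrom = c(aln$chrom, aln$chrom),
    start = c(aln$start, aln$start),
    strand = c(aln$strand, aln$strand),
    is_swapped = rep(c(FALSE, TRUE), each = nrow(aln)),
    stringsAsFactors = FALSE)
  class(out) <- c("balanced_reads", "data.frame")
  attr(out, "n_excluded_other") <- n_excluded
  out
}

#' Remap the doubled read set and measure per-SNP balance
#'
#' Every read of the doubled set (originals and swapped copies alike) is
#' remapped in its original orientation. Per SNP, the alternative-allele
#' fraction is computed over remapped reads covering it with MAPQ >=
#' `min_remap_mapq`, by default restricted to reads landing back on their
#' original (chrom, start, strand); reads that map back elsewhere are
#' counted separately. Counts are kept as exact integers so that perfect
#' balance (fraction exactly 1/2) is detectable without floating-point
#' comparisons.
#'
#' @param doubled a `balanced_reads` set from [build_balanced_readset].
#' @param reference the [ref_genome] of the first mapping round.
#' @param params [mapper_params].
#' @param panel the [snp_panel].
#' @param min_remap_mapq MAPQ required after remapping (default 30).
#' @param require_original_locus if `TRUE` (default), only reads
#'   returning to their first-round locus contribute.
#' @return Data frame with chrom, pos, n_ref, n_alt (integer counts);
#'   attribute `n_offsite` counts reads mapped back to a different locus
#'   with sufficient quality.
#' @export
remap_and_classify <- function(doubled, reference, params = mapper_params(),
                               panel, min_remap_mapq = 30L,
                               require_original_locus = TRUE) {
  stopifnot(inherits(doubled, "balanced_reads"))
  seqs <- doubled$seq
  minus <- doubled$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  res <- map_reads(data.frame(read_id = doubled$read_id, seq = seqs,
                              qual = doubled$qual, stringsAsFactors = FALSE),
                   reference, params)
  idx <- match(doubled$read_id, res$read_id)
  back <- !is.na(idx) & res$mapq[idx] >= min_remap_mapq
  orig <- back & res$chrom[idx] == doubled$chrom &
    res$start[idx] == doubled$start & res$strand[idx] == doubled$strand
  orig[is.na(orig)] <- FALSE
  n_offsite <- sum(back & !orig, na.rm = TRUE)
  keep <- if (require_original_locus) orig else back
  kept <- res[idx[keep], , drop = FALSE]
  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  kept <- new_read_alignments(kept)
  h <- read_snp_hits(kept, panel)
  is_ref <- h$base == panel$ref[h$pidx]
  is_alt <- h$base == panel$alt[h$pidx]
  n <- nrow(panel)
  cnt <- function(w) {
    v <- integer(n)
    t0 <- table(factor(h$pidx[w], levels = seq_len(n)))
    v[] <- as.integer(t0)
    v
  }
  out <- data.frame(chrom = panel$chrom, pos = panel$pos,
                    n_ref = cnt(is_ref), n_alt = cnt(is_alt),
                    stringsAsFactors = FALSE)
  attr(out, "n_offsite") <- n_offsite
  out
}

BALANCE_BINS <- c("0", "(0,0.4)", "[0.4,0.5)", "0.5", "(0.5,0.6]",
                  "(0.6,1)", "1")

#' Histogram of per-SNP allelic balance
#'
#' Assigns each SNP with at least one ref/alt read to exactly one of the
#' bins {0}, (0, 0.4), \[0.4, 0.5), {0.5}, (0.5, 0.6\], (0.6, 1), {1},
#' using exact integer arithmetic on (alt count, total count) so that the
#' singleton bins are hit exactly. SNPs with no ref/alt reads are
#' excluded and counted separately.
#'
#' @param fractions data frame with columns n_ref and n_alt (integer
#'   counts per SNP), e.g. from [remap_and_classify].
#' @param filtered_flag whether the panel was mappability-filtered
#'   (recorded, not acted on).
#' @return An object of class `balance_histogram`: bin counts, `n_snps`,
#'   `n_uncovered`, `filtered_flag`.
#' @export
balance_histogram <- function(fractions, filtered_flag = TRUE) {
  a <- as.integer(fractions$n_alt)
  t <- as.integer(fractions$n_ref) + a
  cov <- t > 0L
  a <- a[cov]; t <- t[cov]
  bin <- character(length(a))
  bin[a == 0L] <- "0"
  bin[a == t] <- "1"
  bin[a > 0L & 5L * a < 2L * t] <- "(0,0.4)"
  bin[5L * a >= 2L * t & 2L * a < t] <- "[0.4,0.5)"
  bin[2L * a == t] <- "0.5"
  bin[2L * a > t & 5L * a <= 3L * t & a < t] <- "(0.5,0.6]"
  bin[5L * a > 3L * t & a < t] <- "(0.6,1)"
  counts <- table(factor(bin, levels = BALANCE_BINS))
  structure(list(counts = counts, n_snps = length(a),
                 n_uncovered = sum(!cov), filtered_flag = filtered_flag),
            class = "balance_histogram")
}

#' @export
print.balance_histogram <- function(x, ...) {
  cat(sprintf("Allelic balance over %d SNPs (%s panel; %d uncovered excluded)\n",
              x$n_snps,
              if (x$filtered_flag) "mappability-filtered" else "unfiltered",
              x$n_uncovered))
  df <- data.frame(bin = names(x$counts),
                   n = as.integer(x$counts),
                   pct = sprintf("%.2f%%", 100 * as.integer(x$counts) /
                                   max(1L, x$n_snps)))
  print(df, row.names = FALSE)
  invisible(x)
}
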