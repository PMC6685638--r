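# Pileup construction at panel SNPs and allelic-balance metrics.

# For every (alignment, panel SNP) overlap, return the read base observed at
# the SNP. Offsets follow the CIGAR for gapped reads; a deletion spanning the
# SNP yields base NA. No quality filtering happens here.
read_snp_hits <- function(alignments, panel) {
  hits <- list()
  for (ch in intersect(unique(alignments$chrom), unique(panel$chrom))) {
    ai <- which(alignments$chrom == ch)
    pi <- which(panel$chrom == ch)
    q <- IRanges::IRanges(start = alignments$start[ai] + 1L,
                          width = alignments$ref_len[ai])
    s <- IRanges::IRanges(start = panel$pos[pi], width = 1L)
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    hits[[ch]] <- data.frame(aidx = ai[S4Vectors::queryHits(ov)],
                             pidx = pi[S4Vectors::subjectHits(ov)])
  }
  if (!length(hits))
    return(data.frame(aidx = integer(), pidx = integer(),
                      qoff = integer(), base = character(),
                      baseq = integer(), stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  roff <- panel$pos[h$pidx] - alignments$start[h$aidx]  # 1-based ref offset
  qoff <- roff
  gapped <- alignments$has_indel[h$aidx]
  if (any(gapped)) {
    qoff[gapped] <- mapply(cigar_query_offset,
                           alignments$cigar[h$aidx[gapped]], roff[gapped])
  }
  ok <- !is.na(qoff)
  h <- h[ok, , drop = FALSE]; qoff <- qoff[ok]
  h$qoff <- qoff
  h$base <- substring(alignments$sequence[h$aidx], qoff, qoff)
  h$baseq <- qual_at(alignments$qual[h$aidx], qoff)
  rownames(h) <- NULL
  h
}

# query (read) offset corresponding to 1-based reference offset `roff`;
# NA if the reference base is deleted in the read
cigar_query_offset <- function(cigar, roff) {
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  q <- 0L; r <- 0L
  for (k in seq_along(op)) {
    if (op[k] == "M") {
      if (roff <= r + n[k]) return(q + (roff - r))
      q <- q + n[k]; r <- r + n[k]
    } else if (op[k] == "I") {
      q <- q + n[k]
    } else {
      if (roff <= r + n[k]) return(NA_integer_)
      r <- r + n[k]
    }
  }
  NA_integer_
}

#' Pileup of panel SNPs
#'
#' Collects, for every panel SNP, the read bases observed there among
#' alignments passing the mapping-quality threshold, keeping bases with
#' quality at or above `min_baseq`. Base qualities are used exactly as
#' stored -- the package contains no base-quality rescaling model, since
#' rescaling typically consults the reference allele and can amplify the
#' very bias being measured. Reads with a deletion spanning the SNP
#' contribute nothing.
#'
#' @param alignments a mapped, deduplicated, length-filtered
#'   `read_alignments` data frame, coordinate-sorted.
#' @param panel a [snp_panel].
#' @param min_mapq,min_baseq inclusive thresholds (analysis default 30).
#' @param read_group optional: restrict to one library.
#' @return An object of class `pileup`: a list with `obs` (one row per
#'   retained observation: site index, read id, allele class, base/map
#'   quality, fragment length, read group) and the panel.
#' @export
pileup <- function(alignments, panel, min_mapq = 30L, min_baseq = 30L,
                   read_group = NULL) {
  stopifnot(inherits(alignments, "read_alignments"),
            inherits(panel, "snp_panel"))
  if (is.unsorted(order(alignments$chrom, alignments$start)))
    stopf("alignments must be coordinate-sorted")
  keep <- alignments$mapq >= min_mapq
  if (!is.null(read_group))
    keep <- keep & !is.na(alignments$read_group) &
      alignments$read_group == read_group
  aln <- alignments[keep, , drop = FALSE]
  h <- read_snp_hits(aln, panel)
  h <- h[h$baseq >= min_baseq, , drop = FALSE]
  allele <- ifelse(h$base == panel$ref[h$pidx], "ref",
                   ifelse(h$base == panel$alt[h$pidx], "alt", "other"))
  obs <- data.frame(site = h$pidx,
                    chrom = panel$chrom[h$pidx], pos = panel$pos[h$pidx],
                    read_id = aln$read_id[h$aidx],
                    allele = allele, baseq = h$baseq,
                    mapq = aln$mapq[h$aidx],
                    fragment_length = aln$length[h$aidx],
                    read_group = aln$read_group[h$aidx],
                    stringsAsFactors = FALSE)
  structure(list(obs = obs, panel = panel,
                 min_mapq = min_mapq, min_baseq = min_baseq),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("Pileup: %d observations at %d of %d panel SNPs (MQ>=%d, BQ>=%d)\n",
              nrow(x$obs), length(unique(x$obs$site)), nrow(x$panel),
              x$min_mapq, x$min_baseq))
  invisible(x)
}

#' Per-site allele counts
#'
#' One row per panel SNP with the number of reference, alternative and
#' other bases observed, the alternative-allele fraction (computed over
#' ref+alt only; third-allele noise is excluded from both numerator and
#' denominator) and the heterozygous-site call.
#'
#' @param x a [pileup].
#' @param min_depth,band heterozygosity rule passed to
#'   [classify_heterozygous].
#' @return Data frame with columns chrom, pos, ref, alt, n_ref, n_alt,
#'   n_other, alt_fraction, is_het.
#' @export
site_counts <- function(x, min_depth = 10L, band = c(0.25, 0.75)) {
  stopifnot(inherits(x, "pileup"))
  p <- x$panel
  n <- nrow(p)
  tab <- function(cls) {
    v <- integer(n)
    t0 <- table(factor(x$obs$site[x$obs$allele == cls], levels = seq_len(n)))
    v[] <- as.integer(t0)
    v
  }
  out <- data.frame(chrom = p$chrom, pos = p$pos, ref = p$ref, alt = p$alt,
                    n_ref = tab("ref"), n_alt = tab("alt"),
                    n_other = tab("other"), stringsAsFactors = FALSE)
  out$alt_fraction <- alt_fraction(out$n_ref, out$n_alt)
  out$is_het <- classify_heterozygous(out$n_ref, out$n_alt, min_depth, band)
  out
}

#' Heterozygous-site rule
#'
#' A site counts as heterozygous when it is covered by at least
#' `min_depth` reads carrying one of the two panel alleles, of which
#' between 25 and 75 percent (inclusive band) represent the alternative
#' allele.
#'
#' @param n_ref,n_alt per-site counts of reference / alternative reads.
#' @param min_depth minimum ref+alt depth.
#' @param band inclusive alternative-allele fraction band.
#' @return Logical vector.
#' @export
classify_heterozygous <- function(n_ref, n_alt, min_depth = 10L,
                                  band = c(0.25, 0.75)) {
  tot <- n_ref + n_alt
  tot >= min_depth & n_alt >= band[1] * tot & n_alt <= band[2] * tot
}

#' Alternative-allele fraction
#'
#' alt / (ref + alt); observations matching neither panel allele are
#' excluded. `NA` where no panel-allele reads were seen.
#'
#' @param n_ref,n_alt per-site counts.
#' @export
alt_fraction <- function(n_ref, n_alt) {
  tot <- n_ref + n_alt
  ifelse(tot > 0, n_alt / tot, NA_real_)
}

#' Mean allelic balance at heterozygous sites
#'
#' The headline bias metric: the mean per-site alternative-allele fraction
#' over sites classified heterozygous, with the standard error of the mean
#' (sample sd / sqrt(n)). An unbiased pipeline is expected to sit at 0.5.
#'
#' @param x a [pileup], or a numeric vector of per-site fractions.
#' @param min_depth,band heterozygosity rule.
#' @return A list of class `bias_summary` with `mean_alt_fraction`, `se`,
#'   `n_sites`.
#' @export
bias_summary <- function(x, min_depth = 10L, band = c(0.25, 0.75)) {
  fr <- if (inherits(x, "pileup")) {
    sc <- site_counts(x, min_depth, band)
    sc$alt_fraction[sc$is_het]
  } else as.numeric(x)
  fr <- fr[!is.na(fr)]
  if (length(fr) < 2L)
    stopf("bias_summary needs at least 2 heterozygous sites (got %d)",
          length(fr))
  structure(list(mean_alt_fraction = mean(fr),
                 se = sd(fr) / sqrt(length(fr)),
                 n_sites = length(fr)),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("Mean alt fraction %.4f +/- %.4f (2 se), %d het sites\n",
              x$mean_alt_fraction, 2 * x$se, x$n_sites))
  invisible(x)
}

#' Allelic balance stratified by fragment length
#'
#' Observations at each site are partitioned into fragment-length bins
#' and per-bin alternative-allele fractions are recomputed from the
#' bin-restricted reads; the minimum-depth heterozygosity rule is
#' re-applied within each bin, so only sites still classifiable at that
#' length contribute. Bins are `[e1, e2), [e2, e3), ...` with the last
#' bin closed on the right.
#'
#' @param x a [pileup].
#' @param bin_edges numeric vector of bin edges (length >= 2).
#' @param min_depth,band heterozygosity rule applied per bin.
#' @return Data frame with bin_low, bin_high, mean_alt_fraction, se,
#'   n_sites (empty bins have n_sites 0 and NA summaries).
#' @export
stratify_by_fragment_length <- function(x, bin_edges, min_depth = 10L,
                                        band = c(0.25, 0.75)) {
  stopifnot(inherits(x, "pileup"), length(bin_edges) >= 2)
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_low = bin_edges[-length(bin_edges)],
                    bin_high = bin_edges[-1],
                    mean_alt_fraction = NA_real_, se = NA_real_,
                    n_sites = 0L)
  for (b in seq_len(nb)) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1]
    inbin <- x$obs$fragment_length >= lo &
      (x$obs$fragment_length < hi | (b == nb & x$obs$fragment_length == hi))
    sub <- x
    sub$obs <- x$obs[inbin, , drop = FALSE]
    sc <- site_counts(sub, min_depth, band)
    fr <- sc$alt_fraction[sc$is_het]
    out$n_sites[b] <- length(fr)
    if (length(fr) >= 2L) {
      out$mean_alt_fraction[b] <- mean(fr)
      out$se[b] <- sd(fr) / sqrt(length(fr))
    }
  }
  out
}

#' Fraction of covered sites classified heterozygous
#'
#' (# heterozygous sites) / (# sites with ref+alt depth >= `min_depth`),
#' with a binomial standard error -- a relative, coverage-conditioned
#' proxy for the individual's heterozygosity. Reference bias (e.g. from
#' short fragments) depresses it.
#'
#' @param x a [pileup].
#' @param min_depth,band heterozygosity rule.
#' @return List with `proportion`, `se`, `n_eligible`, `n_het`.
#' @export
heterozygosity_proxy <- function(x, min_depth = 10L, band = c(0.25, 0.75)) {
  sc <- site_counts(x, min_depth, band)
  eligible <- (sc$n_ref + sc$n_alt) >= min_depth
  n <- sum(eligible)
  if (n == 0L) stopf("no sites with depth >= %d", min_depth)
  p <- sum(sc$is_het[eligible]) / n
  list(proportion = p, se = sqrt(p * (1 - p) / n),
       n_eligible = n, n_het = sum(sc$is_het[eligible]))
}

#' Modal fragment length
#'
#' Most frequent fragment length among the alignments; ties go to the
#' smaller length.
#'
#' @param alignments a `read_alignments` data frame or a numeric vector
#'   of lengths.
#' @export
fragment_length_mode <- function(alignments) {
  len <- if (inherits(alignments, "read_alignments")) alignments$length
         else as.numeric(alignments)
  if (!length(len)) stopf("no alignments")
  tt <- table(len)
  lens <- as.numeric(names(tt))
  lens[which(tt == max(tt))[1]]  # names(tt) sorted ascending: tie -> smaller
}

#' Cross-sample correlation of per-site allelic balance
#'
#' Pearson correlation of per-site alternative-allele fractions over the
#' sites classified heterozygous in both samples, with a two-sided p-value
#' from the t transform (n - 2 degrees of freedom). Significant positive
#' correlations indicate that the strength of reference (or alternative)
#' bias is a property of the locus rather than the sample.
#'
#' @param x,y two [pileup] objects built on the same panel.
#' @param min_depth,band heterozygosity rule.
#' @return List with `r`, `p_value`, `n_sites`.
#' @export
bias_correlation <- function(x, y, min_depth = 10L, band = c(0.25, 0.75)) {
  stopifnot(inherits(x, "pileup"), inherits(y, "pileup"))
  if (!identical(x$panel[c("chrom", "pos")], y$panel[c("chrom", "pos")]))
    stopf("pileups must be built on the same panel")
  sx <- site_counts(x, min_depth, band)
  sy <- site_counts(y, min_depth, band)
  shared <- which(sx$is_het & sy$is_het)
  n <- length(shared)
  if (n < 3L) stopf("need >= 3 sites heterozygous in both samples (got %d)", n)
  r <- cor(sx$alt_fraction[shared], sy$alt_fraction[shared])
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p_value = p, n_sites = n)
}

#' Per-site TSV report
#' @param x a [pileup].
#' @param path output file.
#' @param min_depth,band heterozygosity rule.
#' @export
write_site_report <- function(x, path, min_depth = 10L, band = c(0.25, 0.75)) {
  sc <- site_counts(x, min_depth, band)
  write.table(sc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
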