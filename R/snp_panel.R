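#' SNP panel of known biallelic sites
#'
#' All bias measurements in this package are restricted to a panel of known
#' biallelic SNPs (in practice transversions, to stay clear of post-mortem
#' deamination artifacts). A panel is a data frame with columns `chrom`,
#' `pos` (1-based), `ref`, `alt`, and optional `id`, `maf` (minor-allele
#' frequency) and `ancestry` (local ancestry of the reference assembly),
#' sorted by (chrom, pos) with no duplicate positions. Alleles are always
#' expressed on the reference forward strand.
#'
#' @param chrom character vector of sequence names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt reference / alternative alleles, single bases in A,C,G,T.
#' @param id optional site labels.
#' @param maf optional minor-allele frequencies in \[0, 0.5\].
#' @param ancestry optional labels in African, European, EastAsian, Uncertain.
#' @return An object of class `snp_panel` (a data frame).
#' @examples
#' snp_panel(c("chr1", "chr1"), c(100L, 200L), c("A", "G"), c("T", "C"))
#' @export
snp_panel <- function(chrom, pos, ref, alt, id = NA_character_,
                      maf = NA_real_, ancestry = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   id = as.character(id), maf = as.numeric(maf),
                   ancestry = as.character(ancestry),
                   stringsAsFactors = FALSE)
  if (any(!df$ref %in% DNA_BASES) || any(!df$alt %in% DNA_BASES))
    stopf("panel alleles must be canonical bases (A, C, G, T)")
  if (any(df$ref == df$alt))
    stopf("ref and alt alleles must differ")
  if (any(df$pos < 1L))
    stopf("positions must be >= 1")
  bad <- !is.na(df$ancestry) & !df$ancestry %in% ANCESTRY_LABELS
  if (any(bad))
    stopf("unknown ancestry label(s): %s",
          paste(unique(df$ancestry[bad]), collapse = ", "))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(df[c("chrom", "pos")]))
    stopf("duplicate (chrom, pos) in panel")
  rownames(df) <- NULL
  class(df) <- c("snp_panel", "data.frame")
  df
}

ANCESTRY_LABELS <- c("African", "European", "EastAsian", "Uncertain")

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d sites on %d sequence(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a SNP panel from disk
#'
#' Supported dialects: 6-column EIGENSTRAT `.snp` (id, chrom, genetic
#' position, physical position, ref, alt), VCF restricted to biallelic SNV
#' records (multi-allelic records are an error), and a tab-separated
#' `alleles_tsv` dialect with columns chrom, pos, ref, alt and optionally
#' maf; lines starting with `#` are comments. Output is sorted and
#' duplicate positions are an error.
#'
#' @param path file path.
#' @param format one of `"eigenstrat_snp"`, `"vcf"`, `"alleles_tsv"`.
#' @return A [snp_panel].
#' @export
read_panel <- function(path, format = c("eigenstrat_snp", "vcf", "alleles_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  switch(format,
    eigenstrat_snp = parse_eigenstrat_snp(lines, path),
    vcf = parse_vcf_panel(lines, path),
    alleles_tsv = parse_alleles_tsv(lines, path))
}

parse_eigenstrat_snp <- function(lines, path) {
  keep <- nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stopf("%s: line %d: expected 6 whitespace-separated fields, got %d",
          path, lineno[which(nf != 6L)[1]], nf[nf != 6L][1])
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(pos))
    stopf("%s: line %d: non-integer position", path, lineno[which(is.na(pos))[1]])
  snp_panel(chrom = m[, 2], pos = pos, ref = m[, 5], alt = m[, 6], id = m[, 1])
}

parse_vcf_panel <- function(lines, path) {
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  nf <- lengths(fields)
  if (any(nf < 8L))
    stopf("%s: line %d: expected >= 8 tab-separated VCF fields",
          path, lineno[which(nf < 8L)[1]])
  m <- t(vapply(fields, function(f) f[1:5], character(5)))
  multi <- grepl(",", m[, 5], fixed = TRUE)
  if (any(multi))
    stopf("%s: line %d: multi-allelic record (ALT = %s); only biallelic SNVs are supported",
          path, lineno[which(multi)[1]], m[multi, 5][1])
  snv <- m[, 4] %in% DNA_BASES & m[, 5] %in% DNA_BASES
  if (any(!snv))
    stopf("%s: line %d: not a biallelic SNV (REF = %s, ALT = %s)",
          path, lineno[which(!snv)[1]], m[!snv, 4][1], m[!snv, 5][1])
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    stopf("%s: line %d: non-integer POS", path, lineno[which(is.na(pos))[1]])
  id <- ifelse(m[, 3] == ".", NA_character_, m[, 3])
  snp_panel(chrom = m[, 1], pos = pos, ref = m[, 4], alt = m[, 5], id = id)
}

parse_alleles_tsv <- function(lines, path) {
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stopf("%s: line %d: expected >= 4 tab-separated fields (chrom, pos, ref, alt)",
          path, lineno[which(nf < 4L)[1]])
  chrom <- vapply(fields, `[`, character(1), 1)
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  if (anyNA(pos))
    stopf("%s: line %d: non-integer position", path, lineno[which(is.na(pos))[1]])
  maf <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 5) f[5] else NA_character_, character(1))))
  snp_panel(chrom = chrom, pos = pos,
            ref = vapply(fields, `[`, character(1), 3),
            alt = vapply(fields, `[`, character(1), 4), maf = maf)
}

#' Write a panel in the alleles_tsv dialect
#' @param panel a [snp_panel].
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  out <- panel[c("chrom", "pos", "ref", "alt", "maf")]
  writeLines(c("#chrom\tpos\tref\talt\tmaf",
               sprintf("%s\t%d\t%s\t%s\t%s", out$chrom, out$pos, out$ref,
                       out$alt, ifelse(is.na(out$maf), "", format(out$maf)))),
             path)
  invisible(path)
}

#' Keep only transversion SNPs
#'
#' Removes transition sites (A/G and C/T pairs), which post-mortem
#' deamination can mimic; all downstream bias metrics assume a
#' transversions-only panel.
#'
#' @param panel a [snp_panel].
#' @return The filtered panel.
#' @export
filter_transversions <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  keep <- is_transversion(panel$ref, panel$alt)
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep SNPs at or above a minor-allele frequency
#' @param panel a [snp_panel] with `maf` set for every record.
#' @param min_maf inclusive threshold (the reference panels used 0.05).
#' @export
filter_by_frequency <- function(panel, min_maf) {
  stopifnot(inherits(panel, "snp_panel"))
  if (anyNA(panel$maf))
    stopf("filter_by_frequency: every record must have maf set")
  out <- panel[panel$maf >= min_maf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a panel to a mappability mask
#'
#' Intervals are 0-based half-open (BED convention); a SNP at 1-based
#' position p is kept iff start <= p-1 < end for some interval on its
#' chromosome. Intervals on chromosomes absent from the panel are ignored
#' with a warning.
#'
#' @param panel a [snp_panel].
#' @param mask data frame with columns chrom, start, end (e.g. from
#'   [read_bed] or [compute_mappability]).
#' @export
apply_mappability_mask <- function(panel, mask) {
  stopifnot(inherits(panel, "snp_panel"))
  mask <- as.data.frame(mask)
  unknown <- setdiff(unique(mask$chrom), unique(panel$chrom))
  if (length(unknown))
    warning(sprintf("mask interval(s) on unknown chromosome(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  keep <- logical(nrow(panel))
  for (ch in unique(panel$chrom)) {
    pi <- which(panel$chrom == ch)
    mi <- mask[mask$chrom == ch, , drop = FALSE]
    if (!nrow(mi)) next
    q <- IRanges::IRanges(start = panel$pos[pi], width = 1L)
    s <- IRanges::IRanges(start = mi$start + 1L, end = mi$end)
    keep[pi] <- IRanges::overlapsAny(q, s)
  }
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate SNPs with the local ancestry of the reference assembly
#'
#' Each SNP inside a labelled segment gets that segment's label; SNPs
#' outside all segments are labelled `"Uncertain"`. Overlapping segments
#' with conflicting labels are an error.
#'
#' @param panel a [snp_panel].
#' @param segments data frame with columns chrom, start, end (0-based
#'   half-open) and label (African, European, EastAsian, Uncertain).
#' @export
annotate_ancestry <- function(panel, segments) {
  stopifnot(inherits(panel, "snp_panel"))
  segments <- as.data.frame(segments)
  if (any(!segments$label %in% ANCESTRY_LABELS))
    stopf("unknown ancestry label(s): %s",
          paste(setdiff(unique(segments$label), ANCESTRY_LABELS), collapse = ", "))
  lab <- rep("Uncertain", nrow(panel))
  for (ch in unique(panel$chrom)) {
    pi <- which(panel$chrom == ch)
    si <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(si)) next
    q <- IRanges::IRanges(start = panel$pos[pi], width = 1L)
    s <- IRanges::IRanges(start = si$start + 1L, end = si$end)
    ov <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (anyDuplicated(qh)) {
      for (d in unique(qh[duplicated(qh)])) {
        labs <- unique(si$label[sh[qh == d]])
        if (length(labs) > 1)
          stopf("conflicting ancestry labels (%s) at %s:%d",
                paste(labs, collapse = ", "), ch, panel$pos[pi][d])
      }
    }
    lab[pi[qh]] <- si$label[sh]
  }
  panel$ancestry <- lab
  panel
}

#' Read / write BED intervals
#'
#' Minimal 3+ column BED (chrom, start, end, optional name used as `label`);
#' coordinates are 0-based half-open.
#' @param path file path.
#' @return data frame with columns chrom, start, end (and label if present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stopf("%s: BED lines need >= 3 fields", path)
  out <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.integer(vapply(fields, `[`, character(1), 2)),
    end = as.integer(vapply(fields, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  if (all(lengths(fields) >= 4L))
    out$label <- vapply(fields, `[`, character(1), 4)
  out
}

#' @rdname read_bed
#' @param intervals data frame with columns chrom, start, end and
#'   optionally label.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as.data.frame(intervals)
  cols <- sprintf("%s\t%d\t%d", intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$label)) cols <- paste0(cols, "\t", intervals$label)
  writeLines(cols, path)
  invisible(path)
}
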