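#' Mapper parameters
#'
#' Settings of the internal deterministic mapper, emulating the common
#' ancient-DNA practice of running an external aligner with seeding
#' effectively disabled, a length-scaled missed-alignment fraction and a
#' capped number of gap opens. `err_rate` and `miss_frac` set the
#' per-read mismatch budget via [maxdiff]; `seed_len` is the exact k-mer
#' size used for candidate discovery (an implementation detail of the
#' internal mapper, not an alignment restriction -- `seed_disabled` records
#' that no seed-region constraint is applied).
#'
#' @param err_rate assumed per-base error rate of the budget model.
#' @param miss_frac allowed fraction of missed alignments.
#' @param max_gap_opens maximum gap opens per alignment.
#' @param seed_disabled flag kept for provenance; the internal mapper never
#'   applies a seed-region mismatch restriction.
#' @return A list of class `mapper_params`.
#' @export
mapper_params <- function(err_rate = 0.02, miss_frac = 0.01,
                          max_gap_opens = 2L, seed_disabled = TRUE) {
  if (!(err_rate > 0)) stopf("err_rate must be > 0")
  if (!(miss_frac > 0 && miss_frac < 1)) stopf("miss_frac must be in (0, 1)")
  structure(list(err_rate = err_rate, miss_frac = miss_frac,
                 max_gap_opens = as.integer(max_gap_opens),
                 seed_disabled = isTRUE(seed_disabled)),
            class = "mapper_params")
}

#' Length-scaled mismatch budget
#'
#' The maximum number of edits allowed for a read of the given length: the
#' smallest k such that P(X > k) < `miss_frac` for X ~ Poisson(length *
#' `err_rate`). This reproduces the shape of length-scaled aligner budgets
#' (short fragments tolerate fewer absolute mismatches), which is the
#' mechanism by which alternative-allele reads -- one mismatch behind --
#' are lost preferentially.
#'
#' @param length read length(s) in bases.
#' @param err_rate per-base error rate of the model.
#' @param miss_frac allowed fraction of missed alignments.
#' @return Integer vector of budgets.
#' @examples
#' maxdiff(35)  # 3 mismatches allowed for a 35-bp read
#' @export
maxdiff <- function(length, err_rate = 0.02, miss_frac = 0.01) {
  stopifnot(all(length >= 0))
  lambda <- length * err_rate
  k <- qpois(1 - miss_frac, lambda)
  # qpois gives the smallest k with P(X <= k) >= 1 - miss_frac; the budget
  # needs the strict inequality P(X > k) < miss_frac
  bump <- ppois(k, lambda, lower.tail = FALSE) >= miss_frac
  as.integer(k + bump)
}

new_read_alignments <- function(df) {
  need <- c("read_id", "sequence", "qual", "chrom", "start", "strand",
            "mapq", "edit_distance", "has_indel", "ref_len", "cigar",
            "length", "read_group", "is_duplicate")
  stopifnot(all(need %in% names(df)))
  rownames(df) <- NULL
  class(df) <- c("read_alignments", "data.frame")
  df
}

#' @export
print.read_alignments <- function(x, ...) {
  cat(sprintf("Read alignments: %d reads (%d with indels, MAPQ range %s)\n",
              nrow(x), sum(x$has_indel),
              if (nrow(x) && !is.null(x$mapq))
                paste(range(x$mapq), collapse = "-") else "-"))
  print(head(as.data.frame(x)[setdiff(names(x), c("sequence", "qual"))], 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Map reads with the internal deterministic mapper
#'
#' Searches both strands for alignments with edit distance within
#' [maxdiff] of the read length and at most `max_gap_opens` gap opens,
#' then reports the best hit. Mapping quality encodes hit uniqueness: 37
#' for a single hit within the budget, 25 for a unique best hit with
#' worse secondary hits within the budget, 0 for two or more co-optimal
#' hits. Ties are broken deterministically (lowest chromosome name, then
#' lowest start, then + strand). Sequences are stored reference-forward;
#' the original read orientation is kept in `strand`.
#'
#' @param reads data frame with columns `read_id`, `seq`, `qual`
#'   (Phred+33), and optionally `read_group`; or a character vector of
#'   sequences (ids are generated, qualities set to Phred 40).
#' @param reference a [ref_genome].
#' @param params a [mapper_params].
#' @return A `read_alignments` data frame of mapped reads (0-based
#'   `start`), with attributes `n_unmapped` and `unmapped_ids`.
#' @export
map_reads <- function(reads, reference, params = mapper_params()) {
  stopifnot(inherits(reference, "ref_genome"))
  if (length(reference) == 0 || sum(ref_lengths(reference)) == 0)
    stopf("reference is empty")
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read%d", seq_along(reads)),
                        seq = reads,
                        qual = strrep("I", nchar(reads)),
                        stringsAsFactors = FALSE)
  if (!nrow(reads)) stopf("no reads to map")
  if (any(!nzchar(reads$seq))) stopf("empty read sequence")
  if (is.null(reads$read_group)) reads$read_group <- NA_character_

  ord <- order(names(reference))
  ref_seqs <- unclass(reference)[ord]
  L <- nchar(reads$seq)
  budgets <- maxdiff(L, params$err_rate, params$miss_frac)
  res <- .cpp_map_reads(toupper(reads$seq), budgets, unname(ref_seqs),
                        params$max_gap_opens)
  mapped <- res$mapped
  qual <- reads$qual
  minus <- !is.na(res$strand) & res$strand == "-"
  # stored sequence is reference-forward; flip the quality string alongside
  qual[minus] <- vapply(strsplit(qual[minus], ""), function(q)
    paste0(rev(q), collapse = ""), character(1))
  out <- data.frame(
    read_id = reads$read_id, sequence = res$seq_fwd, qual = qual,
    chrom = names(ref_seqs)[res$chrom_idx], start = res$start,
    strand = res$strand, mapq = res$mapq,
    edit_distance = res$edit_distance, has_indel = res$has_indel,
    ref_len = res$ref_len, cigar = res$cigar, length = L,
    read_group = reads$read_group, is_duplicate = FALSE,
    stringsAsFactors = FALSE)
  out <- out[mapped, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- new_read_alignments(out)
  attr(out, "n_unmapped") <- sum(!mapped)
  attr(out, "unmapped_ids") <- reads$read_id[!mapped]
  out
}

#' @rdname map_reads
#' @param sequence single read sequence.
#' @param base_quals integer Phred scores (defaults to 40 per base).
#' @return `map_read` returns a one-row `read_alignments`, or `NULL` if
#'   the read is unmapped.
#' @export
map_read <- function(sequence, base_quals = NULL, reference,
                     params = mapper_params()) {
  qual <- if (is.null(base_quals)) strrep("I", nchar(sequence))
          else phred_to_qual(list(base_quals))
  aln <- map_reads(data.frame(read_id = "read1", seq = sequence, qual = qual,
                              stringsAsFactors = FALSE), reference, params)
  if (!nrow(aln)) NULL else aln
}

#' Uniquely mappable positions for k-bp reads
#'
#' Positions p (1-based) such that the k-mer starting at p occurs exactly
#' once in the genome, counting both strands. The standard analysis panels
#' are restricted to regions uniquely mappable with 35-bp reads; this
#' computes the equivalent mask for the internal reference.
#'
#' @param reference a [ref_genome].
#' @param k k-mer length (default 35).
#' @return Data frame of 0-based half-open intervals (chrom, start, end)
#'   of uniquely mappable k-mer start positions.
#' @export
compute_mappability <- function(reference, k = 35L) {
  stopifnot(inherits(reference, "ref_genome"), k >= 1)
  seqs <- unclass(reference)
  fwd <- list(); where <- list()
  for (nm in names(seqs)) {
    len <- nchar(seqs[[nm]])
    if (len < k) next
    p <- seq_len(len - k + 1L)
    fwd[[nm]] <- substring(seqs[[nm]], p, p + k - 1L)
    where[[nm]] <- p
  }
  if (!length(fwd)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  allk <- unlist(fwd, use.names = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(allk)))
  counts <- table(c(allk, rc))
  out <- list()
  for (nm in names(fwd)) {
    uniq <- as.integer(counts[fwd[[nm]]]) == 1L &
      !grepl("N", fwd[[nm]], fixed = TRUE)
    p <- where[[nm]][uniq]
    if (!length(p)) next
    runs <- cumsum(c(TRUE, diff(p) != 1L))
    out[[nm]] <- data.frame(
      chrom = nm,
      start = tapply(p, runs, min) - 1L,
      end = tapply(p, runs, max),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$start <- as.integer(res$start); res$end <- as.integer(res$end)
  res
}

#' Remove PCR duplicates
#'
#' Reads sharing (chrom, start, end, strand) are collapsed to the one with
#' the highest base-quality sum (ties broken by read id order); the rest
#' are dropped.
#'
#' @param alignments a `read_alignments` data frame, coordinate-sorted.
#' @return The surviving alignments.
#' @export
remove_duplicates <- function(alignments) {
  stopifnot(inherits(alignments, "read_alignments"))
  if (!nrow(alignments)) return(alignments)
  if (is.unsorted(order(alignments$chrom, alignments$start)))
    alignments <- alignments[order(alignments$chrom, alignments$start), ]
  qsum <- vapply(qual_to_phred(alignments$qual), sum, numeric(1))
  key <- paste(alignments$chrom, alignments$start,
               alignments$start + alignments$ref_len, alignments$strand)
  ord <- order(key, -qsum, alignments$read_id)
  keep <- ord[!duplicated(key[ord])]
  out <- alignments[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop fragments shorter than a minimum length
#'
#' The standard ancient-DNA pipeline removes fragments shorter than 35 bp;
#' a read of exactly `min_length` is kept.
#'
#' @param alignments a `read_alignments` data frame.
#' @param min_length minimum fragment length in bases.
#' @export
filter_short <- function(alignments, min_length = 35L) {
  stopifnot(inherits(alignments, "read_alignments"))
  out <- alignments[alignments$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- SAM / FASTQ text I/O -------------------------------------------------

#' Write / read alignments as SAM text
#'
#' A minimal single-end SAM serialisation carrying MAPQ, CIGAR, the NM
#' (edit distance) and RG (read group) tags; FLAG encodes strand (16) and
#' duplicate (1024) bits.
#'
#' @param alignments a `read_alignments` data frame.
#' @param reference the [ref_genome] the reads were mapped to (for `@SQ`
#'   header lines).
#' @param path file path.
#' @export
write_sam <- function(alignments, reference, path) {
  stopifnot(inherits(alignments, "read_alignments"),
            inherits(reference, "ref_genome"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   ref_lengths(reference)))
  flag <- ifelse(alignments$strand == "-", 16L, 0L) +
    ifelse(alignments$is_duplicate, 1024L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
                 alignments$read_id, flag, alignments$chrom,
                 alignments$start + 1L, alignments$mapq, alignments$cigar,
                 alignments$sequence, alignments$qual,
                 alignments$edit_distance)
  rg <- !is.na(alignments$read_group)
  rec[rg] <- paste0(rec[rg], "\tRG:Z:", alignments$read_group[rg])
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) stopf("%s: SAM records need >= 11 fields", path)
  flag <- as.integer(vapply(f, `[`, character(1), 2))
  tags <- lapply(f, function(x) if (length(x) > 11) x[-(1:11)] else character())
  nm <- vapply(tags, function(t) {
    h <- grep("^NM:i:", t, value = TRUE)
    if (length(h)) as.integer(sub("^NM:i:", "", h[1])) else 0L
  }, integer(1))
  rg <- vapply(tags, function(t) {
    h <- grep("^RG:Z:", t, value = TRUE)
    if (length(h)) sub("^RG:Z:", "", h[1]) else NA_character_
  }, character(1))
  cigar <- vapply(f, `[`, character(1), 6)
  seqs <- vapply(f, `[`, character(1), 10)
  new_read_alignments(data.frame(
    read_id = vapply(f, `[`, character(1), 1),
    sequence = seqs,
    qual = vapply(f, `[`, character(1), 11),
    chrom = vapply(f, `[`, character(1), 3),
    start = as.integer(vapply(f, `[`, character(1), 4)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(vapply(f, `[`, character(1), 5)),
    edit_distance = nm,
    has_indel = grepl("[ID]", cigar),
    ref_len = cigar_ref_len(cigar),
    cigar = cigar,
    length = nchar(seqs),
    read_group = rg,
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    stringsAsFactors = FALSE))
}

cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(n[op %in% c("M", "D", "=", "X", "N")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write / read FASTQ
#' @param reads data frame with columns read_id, seq, qual.
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", reads$qual),
             path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stopf("%s: truncated FASTQ", path)
  i <- seq(1L, length(lines), by = 4L)
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", lines[i])),
             seq = toupper(lines[i + 1L]),
             qual = lines[i + 3L],
             stringsAsFactors = FALSE)
}
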