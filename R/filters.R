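# Post-mapping mitigation filters based on remapping.
#
# Both filters interrogate reads that overlap panel SNPs: if a read only
# maps because it agrees with the reference allele, then a version of the
# problem in which it does not agree (allele-flipped read, or third-allele
# reference) will fail to map back to the same locus -- and symmetric
# treatment of ref- and alt-carrying reads is restored by removing it.

filter_report <- function(n_input, n_eval, n_pos, n_indel, n_mapq) {
  removed <- n_pos + n_indel + n_mapq
  structure(list(n_input_reads = n_input,
                 n_flipped_or_remapped = n_eval,
                 n_failed_position = n_pos,
                 n_failed_indel = n_indel,
                 n_failed_mapq = n_mapq,
                 n_passed = n_eval - removed,
                 fraction_removed = if (n_eval > 0) removed / n_eval else 0),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("Remapping filter: %d reads in, %d evaluated, ",
                     "%d passed (removed %.2f%%: %d position, %d indel, ",
                     "%d MAPQ)\n"),
              x$n_input_reads, x$n_flipped_or_remapped, x$n_passed,
              100 * x$fraction_removed, x$n_failed_position,
              x$n_failed_indel, x$n_failed_mapq))
  invisible(x)
}

# check that the reference carries the panel's reference allele everywhere
check_panel_vs_reference <- function(panel, reference) {
  base <- mapply(function(ch, p) ref_subseq(reference, ch, p, p),
                 panel$chrom, panel$pos)
  bad <- base != panel$ref
  if (any(bad))
    stopf("panel reference allele differs from the reference genome at: %s",
          paste(sprintf("%s:%d (panel %s, genome %s)",
                        panel$chrom[bad], panel$pos[bad],
                        panel$ref[bad], base[bad])[seq_len(min(5, sum(bad)))],
                collapse = "; "))
  invisible(TRUE)
}

# per-alignment panel overlap summary used by both filters: the indices of
# overlapping SNPs, and which of them the read supports with ref / alt
aln_snp_overlap <- function(alignments, panel) {
  h <- read_snp_hits(alignments, panel)
  h$is_ref <- h$base == panel$ref[h$pidx]
  h$is_alt <- h$base == panel$alt[h$pidx]
  h
}

#' Flip reference alleles to alternative in a read
#'
#' Returns a copy of the read sequence in which, at every overlapping
#' panel SNP where the read carries the reference allele, the base is
#' replaced by the alternative allele. Bases elsewhere (including SNPs
#' where the read carries alt or a third allele) and base qualities are
#' untouched. The sequence is handled reference-forward, as stored.
#'
#' @param read a one-row `read_alignments` data frame.
#' @param panel a [snp_panel].
#' @return The modified sequence, with attribute `n_flipped`.
#' @export
flip_ref_to_alt <- function(read, panel) {
  stopifnot(inherits(read, "read_alignments"), nrow(read) == 1L)
  h <- aln_snp_overlap(read, panel)
  if (!nrow(h)) stopf("read overlaps no panel SNP")
  seq <- read$sequence
  fl <- h[h$is_ref, , drop = FALSE]
  for (k in seq_len(nrow(fl)))
    substr(seq, fl$qoff[k], fl$qoff[k]) <- panel$alt[fl$pidx[k]]
  attr(seq, "n_flipped") <- nrow(fl)
  seq
}

# remap sequences in their original orientation and compare the landing
# locus to the original alignment
remap_compare <- function(alignments, seqs_fwd, reference, params,
                          min_remap_mapq) {
  minus <- alignments$strand == "-"
  remap_seq <- seqs_fwd
  remap_seq[minus] <- revcomp(remap_seq[minus])
  res <- map_reads(data.frame(read_id = alignments$read_id,
                              seq = remap_seq, qual = alignments$qual,
                              stringsAsFactors = FALSE),
                   reference, params)
  idx <- match(alignments$read_id, res$read_id)
  back <- !is.na(idx)
  same <- back &
    res$chrom[idx] == alignments$chrom &
    res$start[idx] == alignments$start &
    res$strand[idx] == alignments$strand
  same[is.na(same)] <- FALSE
  indel <- same & res$has_indel[idx]
  lowmq <- same & !indel & res$mapq[idx] < min_remap_mapq
  data.frame(failed_position = !same,
             failed_indel = indel,
             failed_mapq = lowmq,
             passed = same & !indel & !lowmq)
}

#' Modified-read remapping filter
#'
#' Every mapped read that carries the reference allele at one or more
#' overlapping panel SNPs is copied, the copy is flipped to carry the
#' alternative allele at all of them ([flip_ref_to_alt]), and the flipped
#' copy is remapped. The original read is kept only if the flipped copy
#' maps back to the identical (chrom, start, strand), without indels,
#' with MAPQ at least `min_remap_mapq`. Reads not overlapping any SNP,
#' or carrying only alt/other alleles, pass untouched.
#'
#' @param alignments mapped `read_alignments` against `reference`.
#' @param panel a [snp_panel].
#' @param reference the [ref_genome] used for the original mapping.
#' @param params [mapper_params] for remapping.
#' @param min_remap_mapq MAPQ the remapped copy must reach (default 30,
#'   matching the analysis-side threshold).
#' @return List with `alignments` (the passing reads, original records)
#'   and `report` (a `filter_report`).
#' @export
modified_read_filter <- function(alignments, panel, reference,
                                 params = mapper_params(),
                                 min_remap_mapq = 30L) {
  stopifnot(inherits(alignments, "read_alignments"))
  check_panel_vs_reference(panel, reference)
  h <- aln_snp_overlap(alignments, panel)
  flip_rows <- sort(unique(h$aidx[h$is_ref]))
  outcome <- rep(NA_character_, nrow(alignments))
  if (!length(flip_rows)) {
    res <- list(alignments = alignments,
                report = filter_report(nrow(alignments), 0L, 0L, 0L, 0L))
    attr(res, "per_read") <- data.frame(outcome = outcome,
                                        stringsAsFactors = FALSE)
    return(res)
  }
  seqs <- alignments$sequence[flip_rows]
  hf <- h[h$is_ref & h$aidx %in% flip_rows, , drop = FALSE]
  for (k in seq_len(nrow(hf))) {
    j <- match(hf$aidx[k], flip_rows)
    substr(seqs[j], hf$qoff[k], hf$qoff[k]) <- panel$alt[hf$pidx[k]]
  }
  cmp <- remap_compare(alignments[flip_rows, , drop = FALSE], seqs,
                       reference, params, min_remap_mapq)
  keep <- rep(TRUE, nrow(alignments))
  keep[flip_rows] <- cmp$passed
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  outcome[flip_rows] <- ifelse(cmp$passed, "pass",
                               ifelse(cmp$failed_position, "position",
                                      ifelse(cmp$failed_indel, "indel",
                                             "mapq")))
  res <- list(alignments = out,
              report = filter_report(nrow(alignments), length(flip_rows),
                                     sum(cmp$failed_position),
                                     sum(cmp$failed_indel),
                                     sum(cmp$failed_mapq)))
  attr(res, "per_read") <- data.frame(outcome = outcome,
                                      stringsAsFactors = FALSE)
  res
}

#' Build a third-allele modified reference
#'
#' Replaces the base at every panel SNP with a randomly chosen third base
#' -- neither the reference nor the known alternative allele -- so that
#' reads carrying either true allele face exactly one mismatch there.
#' The choice is uniform between the two remaining bases, driven by
#' `seed`, and recorded in a substitution table for reproducibility.
#'
#' @param reference a [ref_genome] whose base at each SNP equals the
#'   panel reference allele (checked).
#' @param panel a [snp_panel].
#' @param seed integer seed for the third-allele draw.
#' @return List with `reference` (modified [ref_genome]) and `table`
#'   (data frame chrom, pos, ref, alt, third).
#' @export
build_modified_reference <- function(reference, panel, seed) {
  check_panel_vs_reference(panel, reference)
  third <- with_seed(seed, vapply(seq_len(nrow(panel)), function(i) {
    sample(setdiff(DNA_BASES, c(panel$ref[i], panel$alt[i])), 1L)
  }, character(1)))
  modified <- ref_substitute(reference, panel$chrom, panel$pos, third)
  list(reference = modified,
       table = data.frame(chrom = panel$chrom, pos = panel$pos,
                          ref = panel$ref, alt = panel$alt, third = third,
                          stringsAsFactors = FALSE))
}

#' Write / read the third-allele substitution table
#' @param table data frame as returned by [build_modified_reference].
#' @param path file path.
#' @export
write_substitution_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_substitution_table
#' @export
read_substitution_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(pos = "integer"))
}

#' Modified-reference remapping filter
#'
#' Every read overlapping at least one panel SNP -- whatever allele it
#' carries -- is remapped against the third-allele modified reference; it
#' passes only if it lands on the identical (chrom, start, strand),
#' without indels, with MAPQ at least `min_remap_mapq`. Because ref- and
#' alt-carrying reads both face exactly one mismatch at the SNP, the
#' filter treats the two alleles symmetrically by construction. Reads
#' overlapping no SNP pass untouched.
#'
#' @param alignments mapped `read_alignments` against the original
#'   reference.
#' @param panel a [snp_panel].
#' @param modified_reference the [ref_genome] from
#'   [build_modified_reference].
#' @param substitution_table its substitution table (used to verify the
#'   modified reference matches the panel).
#' @param params [mapper_params] for remapping.
#' @param min_remap_mapq MAPQ threshold for the remap (default 30).
#' @return List with `alignments` and `report`, as in
#'   [modified_read_filter].
#' @export
modified_reference_filter <- function(alignments, panel, modified_reference,
                                      substitution_table,
                                      params = mapper_params(),
                                      min_remap_mapq = 30L) {
  stopifnot(inherits(alignments, "read_alignments"))
  st <- substitution_table
  ok <- nrow(st) == nrow(panel) &&
    identical(st$chrom, panel$chrom) && identical(st$pos, panel$pos) &&
    identical(st$ref, panel$ref) && identical(st$alt, panel$alt) &&
    all(st$third != st$ref & st$third != st$alt)
  if (!isTRUE(ok))
    stopf("substitution table does not match the panel; was the modified reference built from this panel?")
  base <- mapply(function(ch, p) ref_subseq(modified_reference, ch, p, p),
                 st$chrom, st$pos)
  if (any(base != st$third))
    stopf("modified reference does not carry the recorded third alleles")
  h <- aln_snp_overlap(alignments, panel)
  eval_rows <- sort(unique(h$aidx))
  outcome <- rep(NA_character_, nrow(alignments))
  if (!length(eval_rows)) {
    res <- list(alignments = alignments,
                report = filter_report(nrow(alignments), 0L, 0L, 0L, 0L))
    attr(res, "per_read") <- data.frame(outcome = outcome,
                                        stringsAsFactors = FALSE)
    return(res)
  }
  cmp <- remap_compare(alignments[eval_rows, , drop = FALSE],
                       alignments$sequence[eval_rows],
                       modified_reference, params, min_remap_mapq)
  keep <- rep(TRUE, nrow(alignments))
  keep[eval_rows] <- cmp$passed
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  outcome[eval_rows] <- ifelse(cmp$passed, "pass",
                               ifelse(cmp$failed_position, "position",
                                      ifelse(cmp$failed_indel, "indel",
                                             "mapq")))
  res <- list(alignments = out,
              report = filter_report(nrow(alignments), length(eval_rows),
                                     sum(cmp$failed_position),
                                     sum(cmp$failed_indel),
                                     sum(cmp$failed_mapq)))
  attr(res, "per_read") <- data.frame(outcome = outcome,
                                      stringsAsFactors = FALSE)
  res
}

#' Combined remapping filter
#'
#' Intersection of the pass sets of [modified_read_filter] and
#' [modified_reference_filter] (read identity by read id and
#' coordinates). Equivalent to applying the filters sequentially, since
#' both are per-read predicates.
#'
#' @inheritParams modified_reference_filter
#' @param reference the original [ref_genome].
#' @return List with `alignments` and `report`; the report counts each
#'   failing read once, attributed to the modified-read filter first.
#' @export
combined_filter <- function(alignments, panel, reference,
                            modified_reference, substitution_table,
                            params = mapper_params(), min_remap_mapq = 30L) {
  a <- modified_read_filter(alignments, panel, reference, params,
                            min_remap_mapq)
  b <- modified_reference_filter(alignments, panel, modified_reference,
                                 substitution_table, params, min_remap_mapq)
  key <- function(x) paste(x$read_id, x$chrom, x$start, x$strand)
  k0 <- key(alignments)
  pass_a <- k0 %in% key(a$alignments)
  pass_b <- k0 %in% key(b$alignments)
  out <- alignments[pass_a & pass_b, , drop = FALSE]
  rownames(out) <- NULL
  # per-read failure category: modified-read filter first, then reference
  fa <- attr(a, "per_read"); fb <- attr(b, "per_read")
  n_eval <- sum(!is.na(fa$outcome) | !is.na(fb$outcome))
  pick <- function(oa, ob) if (!is.na(oa) && oa != "pass") oa
    else if (!is.na(ob) && ob != "pass") ob else "pass"
  outcome <- mapply(pick, fa$outcome, fb$outcome)
  evaluated <- !is.na(fa$outcome) | !is.na(fb$outcome)
  list(alignments = out,
       report = filter_report(nrow(alignments), n_eval,
                              sum(outcome[evaluated] == "position"),
                              sum(outcome[evaluated] == "indel"),
                              sum(outcome[evaluated] == "mapq")))
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path file path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(report, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
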