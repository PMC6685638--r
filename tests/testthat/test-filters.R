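# fixtures: a clean reference, a two-SNP panel, and hand-built reads
fscene <- local({
  ref <- tiny_ref(6000L, seed = 31)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  pos <- c(2000L, 2020L, 4000L)
  refb <- vapply(pos, function(p) ref_subseq(ref, "chr1", p, p), "")
  panel <- snp_panel("chr1", pos, refb, unname(flip[refb]))
  list(ref = ref, panel = panel, pos = pos, refb = refb,
       altb = unname(flip[refb]))
})

fread <- function(id, start1, len = 50L, subs = list(), mapq = 37L) {
  s <- ref_subseq(fscene$ref, "chr1", start1, start1 + len - 1L)
  for (sub in subs) substr(s, sub[[1]] - start1 + 1L, sub[[1]] - start1 + 1L) <- sub[[2]]
  sam_rec(id, "chr1", start1, s, mapq = mapq,
          nm = length(subs))
}

test_that("flip_ref_to_alt flips every ref-carrying SNP and nothing else", {
  # read spanning SNPs 1 and 2, reference allele at both
  aln <- aln_from_records(fread("r", 1990L), fscene$ref)
  out <- flip_ref_to_alt(aln[1, ], fscene$panel)
  expect_equal(attr(out, "n_flipped"), 2L)
  expect_equal(substr(as.character(out), 11, 11), fscene$altb[1])
  expect_equal(substr(as.character(out), 31, 31), fscene$altb[2])
  # every other base untouched (position-by-position oracle)
  diffs <- which(strsplit(as.character(out), "")[[1]] !=
                   strsplit(aln$sequence[1], "")[[1]])
  expect_equal(diffs, c(11L, 31L))

  # read already carrying alt at its only SNP -> unchanged
  aln2 <- aln_from_records(
    fread("a", 3990L, subs = list(list(4000L, fscene$altb[3]))), fscene$ref)
  out2 <- flip_ref_to_alt(aln2[1, ], fscene$panel)
  expect_equal(as.character(out2), aln2$sequence[1])
  expect_equal(attr(out2, "n_flipped"), 0L)

  # read with no SNP overlap is a caller error
  aln3 <- aln_from_records(fread("n", 100L), fscene$ref)
  expect_error(flip_ref_to_alt(aln3[1, ], fscene$panel), "no panel SNP")
})

test_that("modified-read filter keeps flippable reads and drops budget-breakers", {
  b <- maxdiff(50)  # 4 mismatches for a 50-bp read
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  mk_mismatches <- function(start1, k, avoid) {
    ps <- setdiff(seq(start1 + 2L, start1 + 48L, by = 5L), avoid)[seq_len(k)]
    lapply(ps, function(p)
      list(p, unname(flip[ref_subseq(fscene$ref, "chr1", p, p)])))
  }
  recs <- c(
    fread("clean_ref", 1990L),                    # ref at both SNPs, no noise
    fread("noisy_ref", 3980L,                     # ref at SNP3 + b mismatches
          subs = mk_mismatches(3980L, b, 4000L), mapq = 37L),
    fread("no_snp", 100L),
    fread("alt_only", 3990L, subs = list(list(4000L, fscene$altb[3]))))
  aln <- aln_from_records(recs, fscene$ref)
  res <- modified_read_filter(aln, fscene$panel, fscene$ref)
  ids <- res$alignments$read_id
  expect_true(all(c("clean_ref", "no_snp", "alt_only") %in% ids))
  # flipping adds a (b+1)-th mismatch -> unmapped -> failed_position
  expect_false("noisy_ref" %in% ids)
  expect_equal(res$report$n_flipped_or_remapped, 2L)
  expect_equal(res$report$n_failed_position, 1L)
  expect_equal(res$report$n_passed, 1L)
  with(res$report, expect_equal(n_passed + n_failed_position + n_failed_indel +
                                  n_failed_mapq, n_flipped_or_remapped))
})

test_that("a flipped copy drawn to a paralog fails the position check", {
  # chr2 carries the alt-haplotype of the window around SNP1: the flipped
  # copy maps there co-optimally and loses its unique original locus
  ref2 <- ref_with_paralog(fscene$ref, 1990L, 2039L,
                           edits = list(list(2000L - 1990L + 1L,
                                             fscene$altb[1])))
  panel1 <- snp_panel("chr1", fscene$pos[1], fscene$refb[1], fscene$altb[1])
  aln <- aln_from_records(fread("r", 1990L, len = 50L), ref2)
  aln <- aln[aln$chrom == "chr1", ]
  res <- modified_read_filter(aln, panel1, ref2)
  expect_equal(nrow(res$alignments), 0L)
  expect_equal(res$report$n_failed_position, 1L)
})

test_that("modified reference carries a third allele only at SNPs, reproducibly", {
  md1 <- build_modified_reference(fscene$ref, fscene$panel, seed = 5)
  md2 <- build_modified_reference(fscene$ref, fscene$panel, seed = 5)
  expect_identical(unclass(md1$reference), unclass(md2$reference))

  tab <- md1$table
  expect_true(all(tab$third != tab$ref & tab$third != tab$alt))
  # A/T SNP -> replacement from {C,G}
  at <- tab[paste0(tab$ref, tab$alt) %in% c("AT", "TA"), ]
  if (nrow(at)) expect_true(all(at$third %in% c("C", "G")))
  # non-SNP positions byte-identical
  s0 <- strsplit(unclass(fscene$ref)[["chr1"]], "")[[1]]
  s1 <- strsplit(unclass(md1$reference)[["chr1"]], "")[[1]]
  expect_equal(which(s0 != s1), fscene$pos)

  # precondition: panel ref allele must match the reference
  badpan <- fscene$panel
  badpan$ref[1] <- fscene$altb[1]; badpan$alt[1] <- fscene$refb[1]
  expect_error(build_modified_reference(fscene$ref, badpan, 1),
               "differs from the reference")
})

test_that("modified-reference filter treats ref and alt carriers symmetrically", {
  md <- build_modified_reference(fscene$ref, fscene$panel, seed = 5)
  b <- maxdiff(50)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  noise <- lapply(seq(3982L, by = 4L, length.out = b), function(p)
    list(p, unname(flip[ref_subseq(fscene$ref, "chr1", p, p)])))
  recs <- c(
    fread("ref_carrier", 3990L),
    fread("alt_carrier", 3990L, subs = list(list(4000L, fscene$altb[3]))),
    fread("no_snp", 100L),
    # already at the budget: the third allele pushes it over
    fread("at_budget", 3980L, subs = noise))
  aln <- aln_from_records(recs, fscene$ref)
  res <- modified_reference_filter(aln, fscene$panel, md$reference, md$table)
  ids <- res$alignments$read_id
  expect_true(all(c("ref_carrier", "alt_carrier", "no_snp") %in% ids))
  expect_false("at_budget" %in% ids)
  expect_equal(res$report$n_flipped_or_remapped, 3L)

  # substitution table must match the panel
  other <- snp_panel("chr1", 123L, "A", "C")
  expect_error(modified_reference_filter(aln, other, md$reference, md$table),
               "substitution table")
})

test_that("with error-free reads the modified-reference filter passes both alleles at equal rates", {
  cfg <- sim_config(genome_length = 20000L, snp_density = 2, coverage = 12,
                    length_dist = list(name = "constant", mode = 45),
                    deamination = c(0, 0), error_rate = 0, seed = 13)
  ref <- simulate_reference(cfg)
  ind <- simulate_individual(ref, cfg)
  al <- filter_short(remove_duplicates(
    map_reads(simulate_fragments(ref, ind$genotypes, cfg), ref)))
  md <- build_modified_reference(ref, ind$panel, seed = 2)
  res <- modified_reference_filter(al, ind$panel, md$reference, md$table)
  h_in <- refbias:::aln_snp_overlap(al, ind$panel)
  h_out <- refbias:::aln_snp_overlap(res$alignments, ind$panel)
  # exact equality of pass rates by construction
  expect_equal(sum(h_out$is_ref) / sum(h_in$is_ref),
               sum(h_out$is_alt) / sum(h_in$is_alt))
})

test_that("combined filter is the intersection and all filters are idempotent", {
  md <- build_modified_reference(fscene$ref, fscene$panel, seed = 5)
  b <- maxdiff(50)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  noise <- lapply(seq(3982L, by = 4L, length.out = b), function(p)
    list(p, unname(flip[ref_subseq(fscene$ref, "chr1", p, p)])))
  recs <- c(
    fread("both_pass", 1990L),
    # alt carrier with b extra mismatches: untouched by the reads filter,
    # but the third allele adds one more mismatch -> fails the reference
    # remap
    fread("one_pass", 3980L,
          subs = c(noise, list(list(4000L, fscene$altb[3]))), mapq = 37L),
    fread("no_snp", 100L))
  aln <- aln_from_records(recs, fscene$ref)
  a <- modified_read_filter(aln, fscene$panel, fscene$ref)
  bb <- modified_reference_filter(aln, fscene$panel, md$reference, md$table)
  cc <- combined_filter(aln, fscene$panel, fscene$ref, md$reference, md$table)
  expect_true("one_pass" %in% a$alignments$read_id)
  expect_false("one_pass" %in% bb$alignments$read_id)
  expect_equal(sort(cc$alignments$read_id),
               sort(intersect(a$alignments$read_id, bb$alignments$read_id)))
  with(cc$report, expect_equal(n_passed + n_failed_position + n_failed_indel +
                                 n_failed_mapq, n_flipped_or_remapped))

  # idempotence
  a2 <- modified_read_filter(a$alignments, fscene$panel, fscene$ref)
  expect_equal(as.data.frame(a2$alignments), as.data.frame(a$alignments))
  b2 <- modified_reference_filter(bb$alignments, fscene$panel, md$reference,
                                  md$table)
  expect_equal(as.data.frame(b2$alignments), as.data.frame(bb$alignments))

  # reads without SNP overlap are never removed
  expect_true(all(c("no_snp") %in% intersect(a$alignments$read_id,
                                             bb$alignments$read_id)))
})
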