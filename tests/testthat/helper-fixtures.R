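# shared fixtures, all generated in code

# small deterministic reference without repeats
tiny_ref <- function(len = 5000L, seed = 3L) {
  simulate_reference(sim_config(genome_length = max(1000L, len), seed = seed))
}

# build a read_alignments object through the SAM text surface
aln_from_records <- function(records, ref) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(unclass(ref))))
  writeLines(c(hdr, records), path)
  aln <- read_sam(path)
  aln <- aln[order(aln$chrom, aln$start), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

sam_rec <- function(id, chrom, pos1, seq, mapq = 37L, flag = 0L,
                    cigar = paste0(nchar(seq), "M"), qual = strrep("I", nchar(seq)),
                    nm = 0L, rg = NULL) {
  r <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
               id, flag, chrom, pos1, mapq, cigar, seq, qual, nm)
  if (!is.null(rg)) r <- paste0(r, "\tRG:Z:", rg)
  r
}

# reference with an extra chromosome holding a modified copy of a window
# of chr1 (used for paralog fixtures)
ref_with_paralog <- function(ref, start1, end1, edits = list()) {
  win <- ref_subseq(ref, "chr1", start1, end1)
  for (e in edits) substr(win, e[[1]], e[[1]]) <- e[[2]]
  ref_genome(c(unclass(ref), chr2 = win))
}

# cached heavy simulations shared between acceptance checks
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# the biased study conditions: repeat-containing genome, short lognormal
# fragments, heavy non-UDG terminal deamination, low sequencing error
biased_sim <- function() {
  cached("biased", {
    cfg <- sim_config(genome_length = 100000L, repeat_spec = list(c(500, 2)),
                      snp_density = 8, het_fraction = 1, coverage = 100,
                      length_dist = list(name = "lognormal", mode = 48,
                                         sdlog = 0.3),
                      deamination = c(0.6, 0.2), contamination = c(0, 1),
                      error_rate = 0.002, seed = 11L)
    ref <- simulate_reference(cfg)
    ind <- simulate_individual(ref, cfg)
    fr <- simulate_fragments(ref, ind$genotypes, cfg)
    al <- filter_short(remove_duplicates(map_reads(fr, ref)))
    panel <- apply_mappability_mask(ind$panel, compute_mappability(ref, 35))
    list(ref = ref, panel = panel, alignments = al)
  })
}
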