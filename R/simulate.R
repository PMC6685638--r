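# Synthetic ancient-DNA data: reference genomes with controllable
# repeats, diploid individuals with transversion panels, degraded
# fragments, and admixture genotype tables. Everything is deterministic
# under the config seed, so end-to-end pipeline properties can be
# asserted on seed-fixed runs.

#' Simulation configuration
#'
#' Study conditions for the closed-loop simulations. Defaults emulate a
#' shotgun-sequenced ancient genome at medium-high coverage: short
#' fragments (lognormal with mode 45 bp), non-UDG terminal deamination
#' (30 percent C-to-T at the first base, exponentially decaying inward),
#' a low per-base sequencing error rate, and no contamination. All SNPs
#' are heterozygous by default since the bias metrics condition on known
#' heterozygous sites.
#'
#' @param genome_length reference length in bases (>= 1000).
#' @param repeat_spec list of c(length, copies) segment duplications, to
#'   create multi-mapping loci.
#' @param snp_density SNPs per kb.
#' @param het_fraction fraction of SNPs heterozygous (rest homozygous
#'   alternative).
#' @param coverage mean sequencing depth.
#' @param length_dist list(name = "lognormal", mode, sdlog) or
#'   list(name = "constant", mode); fragments below 30 bp are redrawn.
#' @param deamination c(p0, lambda): terminal C-to-T (5') and G-to-A
#'   (3') probability p0 * exp(-lambda * offset).
#' @param contamination c(fraction, ref_bias): fraction of fragments
#'   drawn from a contaminant haplotype carrying the reference allele
#'   with probability ref_bias at each SNP (1 = worst case: fully
#'   reference-matching contaminant).
#' @param error_rate per-base sequencing error probability.
#' @param seed integer; fixes every random draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, repeat_spec = list(),
                       snp_density = 2.5, het_fraction = 1,
                       coverage = 20,
                       length_dist = list(name = "lognormal", mode = 45,
                                          sdlog = 0.35),
                       deamination = c(p0 = 0.3, lambda = 0.3),
                       contamination = c(fraction = 0, ref_bias = 1),
                       error_rate = 0.002, seed = 1L) {
  stopifnot(genome_length >= 1000, coverage > 0,
            het_fraction >= 0, het_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            deamination[1] >= 0, deamination[1] <= 1, deamination[2] >= 0,
            contamination[1] >= 0, contamination[1] <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 repeat_spec = repeat_spec, snp_density = snp_density,
                 het_fraction = het_fraction, coverage = coverage,
                 length_dist = length_dist,
                 deamination = unname(deamination),
                 contamination = unname(contamination),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. bases, then for each c(length, copies) entry a randomly chosen
#' source segment is copied over copies-1 additional randomly chosen
#' non-source locations, creating exact repeats that defeat unique
#' mapping. Byte-identical under the config seed.
#'
#' @param config a [sim_config].
#' @return A single-chromosome [ref_genome] named `chr1`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  len <- config$genome_length
  with_seed(config$seed, {
    bases <- sample(DNA_BASES, len, replace = TRUE)
    for (rs in config$repeat_spec) {
      rlen <- as.integer(rs[1]); copies <- as.integer(rs[2])
      if (rlen > len) stopf("repeat longer than the genome")
      src <- sample.int(len - rlen + 1L, 1L)
      seg <- bases[src:(src + rlen - 1L)]
      for (k in seq_len(copies - 1L)) {
        repeat {
          dst <- sample.int(len - rlen + 1L, 1L)
          if (dst + rlen <= src || dst >= src + rlen) break
        }
        bases[dst:(dst + rlen - 1L)] <- seg
      }
    }
    ref_genome(c(chr1 = paste0(bases, collapse = "")))
  })
}

# transversion partner chosen uniformly between the two candidates
transversion_partner <- function(base, u) {
  partners <- list(A = c("C", "T"), C = c("A", "G"),
                   G = c("C", "T"), T = c("A", "G"))
  vapply(seq_along(base), function(i)
    partners[[base[i]]][1L + (u[i] > 0.5)], character(1))
}

#' Simulate a diploid individual and its SNP panel
#'
#' Places SNPs at distinct positions, assigns each a transversion
#' alternative allele, and makes `het_fraction` of them heterozygous
#' (one chromosome reference, one alternative; which copy carries the
#' alternative is random) and the rest homozygous alternative. The truth
#' is returned alongside the panel for recovery tests.
#'
#' @param reference a [ref_genome] from [simulate_reference].
#' @param config a [sim_config].
#' @return List with `genotypes` (chrom, pos, ref, alt, hap1, hap2, het)
#'   and `panel` (a [snp_panel]).
#' @export
simulate_individual <- function(reference, config) {
  stopifnot(inherits(reference, "ref_genome"), inherits(config, "sim_config"))
  chrom <- names(reference)[1]
  len <- ref_lengths(reference)[[1]]
  n_snps <- round(config$snp_density * len / 1000)
  if (n_snps > len) stopf("snp_density too high for the genome")
  if (n_snps < 1) stopf("snp_density places no SNPs")
  with_seed(config$seed + 1L, {
    pos <- sort(sample.int(len, n_snps))
    ref <- strsplit(ref_subseq(reference, chrom, 1L, len), "")[[1]][pos]
    alt <- transversion_partner(ref, runif(n_snps))
    het <- rep(FALSE, n_snps)
    het[sample.int(n_snps, round(config$het_fraction * n_snps))] <- TRUE
    alt_on_hap1 <- runif(n_snps) < 0.5
    hap1 <- ifelse(het, ifelse(alt_on_hap1, alt, ref), alt)
    hap2 <- ifelse(het, ifelse(alt_on_hap1, ref, alt), alt)
    list(genotypes = data.frame(chrom = chrom, pos = pos, ref = ref,
                                alt = alt, hap1 = hap1, hap2 = hap2,
                                het = het, stringsAsFactors = FALSE),
         panel = snp_panel(chrom, pos, ref, alt))
  })
}

draw_lengths <- function(n, length_dist) {
  if (length_dist$name == "constant")
    return(rep(as.integer(length_dist$mode), n))
  sdlog <- length_dist$sdlog %||% 0.35
  # lognormal parameterised by its mode: mode = exp(meanlog - sdlog^2)
  meanlog <- log(length_dist$mode) + sdlog^2
  out <- integer(0)
  while (length(out) < n) {
    l <- as.integer(round(rlnorm(n - length(out) + 50L, meanlog, sdlog)))
    out <- c(out, l[l >= 30L])
  }
  out[seq_len(n)]
}

#' Simulate degraded sequencing fragments
#'
#' Fragments are drawn from the configured length distribution
#' (truncated at 30 bp), each copying one uniformly chosen chromosome
#' copy of the individual (or, with the contamination probability, a
#' reference-allele-enriched contaminant haplotype). Per-base sequencing
#' errors are applied at `error_rate`; post-mortem deamination converts
#' C to T near the 5' end and G to A near the 3' end of the read as
#' sequenced, with probability p0 * exp(-lambda * offset). Base
#' qualities are constant Phred 40 -- damage is invisible to qualities,
#' as in real data.
#'
#' @param reference a [ref_genome].
#' @param genotypes truth data frame from [simulate_individual].
#' @param config a [sim_config].
#' @return Data frame read_id, seq, qual with attribute `truth` (chrom,
#'   start 0-based, length, strand, hap, contaminant).
#' @export
simulate_fragments <- function(reference, genotypes, config) {
  stopifnot(inherits(reference, "ref_genome"), inherits(config, "sim_config"))
  chrom <- names(reference)[1]
  clen <- ref_lengths(reference)[[1]]
  chromseq <- unclass(reference)[[chrom]]
  mean_len <- if (config$length_dist$name == "constant")
    config$length_dist$mode else {
      sdlog <- config$length_dist$sdlog %||% 0.35
      exp(log(config$length_dist$mode) + sdlog^2 + sdlog^2 / 2)
    }
  n <- ceiling(config$coverage * clen / mean_len)
  with_seed(config$seed + 2L, {
    len <- draw_lengths(n, config$length_dist)
    len <- pmin(len, clen)
    start0 <- as.integer(floor(runif(n) * (clen - len + 1L)))
    hap <- sample.int(2L, n, replace = TRUE)
    contam <- runif(n) < config$contamination[1]
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    seqs <- substring(chromseq, start0 + 1L, start0 + len)

    # substitute individual / contaminant alleles at overlapping SNPs
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = start0 + 1L, width = len),
      IRanges::IRanges(start = genotypes$pos, width = 1L))
    fi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    contam_ref <- runif(length(fi)) >= config$contamination[2]
    for (k in seq_along(fi)) {
      f <- fi[k]; s <- si[k]
      al <- if (contam[f]) {
        # contaminant: reference allele with prob ref_bias
        if (contam_ref[k]) genotypes$alt[s] else genotypes$ref[s]
      } else if (hap[f] == 1L) genotypes$hap1[s] else genotypes$hap2[s]
      off <- genotypes$pos[s] - start0[f]
      substr(seqs[f], off, off) <- al
    }

    # orientation as sequenced
    minus <- strand == "-"
    seqs[minus] <- revcomp(seqs[minus])

    if (config$deamination[1] > 0 || config$error_rate > 0) {
      chars <- strsplit(seqs, "", fixed = TRUE)
      flat <- unlist(chars, use.names = FALSE)
      fl <- rep.int(seq_len(n), len)
      off5 <- sequence(len) - 1L
      off3 <- len[fl] - 1L - off5
      p0 <- config$deamination[1]; lam <- config$deamination[2]
      if (p0 > 0) {
        d5 <- flat == "C" & runif(length(flat)) < p0 * exp(-lam * off5)
        flat[d5] <- "T"
        d3 <- flat == "G" & runif(length(flat)) < p0 * exp(-lam * off3)
        flat[d3] <- "A"
      }
      if (config$error_rate > 0) {
        err <- runif(length(flat)) < config$error_rate
        if (any(err)) {
          shift <- sample.int(3L, sum(err), replace = TRUE)
          cur <- match(flat[err], DNA_BASES)
          flat[err] <- DNA_BASES[1L + (cur - 1L + shift) %% 4L]
        }
      }
      seqs <- vapply(split(flat, fl), paste0, character(1), collapse = "")
      names(seqs) <- NULL
    }

    out <- data.frame(read_id = sprintf("frag%07d", seq_len(n)),
                      seq = seqs, qual = strrep("I", len),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- data.frame(
      chrom = chrom, start = start0, length = len, strand = strand,
      hap = hap, contaminant = contam, stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a genotype table with known admixture
#'
#' A five-population table supporting f4-ratio recovery tests: per site,
#' an ancestral frequency is drawn Uniform(0.05, 0.95); a Mbuti-like
#' frequency adds bounded drift noise Uniform(-drift, drift); a
#' Neandertal-like frequency adds heavy drift Uniform(-0.5, 0.5)
#' (clipped to \[0, 1\]), shared by two Neandertal samples drawn
#' independently from it; the outgroup is fixed at 0; the target
#' frequency is alpha * Neandertal + (1 - alpha) * Mbuti. All calls are
#' haploid Bernoulli draws. Sites are spaced 2.5 kb apart so a 5-Mbp
#' jackknife has at least 20 blocks for 40,000+ sites.
#'
#' @param n_sites number of sites.
#' @param alpha true admixture proportion in \[0, 1\].
#' @param drift half-width of the Mbuti drift noise.
#' @param seed integer seed.
#' @return A `geno_table` with populations Target, Mbuti, AltaiNea,
#'   VindijaNea, Chimp; attribute `alpha` records the truth.
#' @export
simulate_admixture_table <- function(n_sites, alpha, drift = 0.2, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_sites >= 1)
  with_seed(seed, {
    anc <- runif(n_sites, 0.05, 0.95)
    pm <- pmin(1, pmax(0, anc + runif(n_sites, -drift, drift)))
    pn <- pmin(1, pmax(0, anc + runif(n_sites, -0.5, 0.5)))
    pt <- alpha * pn + (1 - alpha) * pm
    tb <- genotype_table(
      chrom = "1", pos = as.integer(seq_len(n_sites)) * 2500L,
      Target = rbinom(n_sites, 1L, pt),
      Mbuti = rbinom(n_sites, 1L, pm),
      AltaiNea = rbinom(n_sites, 1L, pn),
      VindijaNea = rbinom(n_sites, 1L, pn),
      Chimp = rep(0, n_sites))
    attr(tb, "alpha") <- alpha
    tb
  })
}
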