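# Pseudo-haploid sampling, D / f4 statistics with the weighted block
# jackknife, and the f4-ratio ancestry estimator.

#' Genotype table
#'
#' Per-site alternative-allele frequencies for a set of populations (or
#' single individuals), aligned to panel coordinates. Haploid
#' (pseudo-haploid) calls are frequencies in {0, 1}; diploid calls in
#' {0, 0.5, 1}; population frequencies anywhere in \[0, 1\]; `NA` marks
#' missing data. Sites are sorted by (chrom, pos).
#'
#' @param chrom,pos site coordinates (pos 1-based).
#' @param ... named numeric vectors, one per population.
#' @return A data frame of class `geno_table`.
#' @export
genotype_table <- function(chrom, pos, ...) {
  pops <- list(...)
  if (!length(pops) || is.null(names(pops)) || any(!nzchar(names(pops))))
    stopf("populations must be named")
  if (anyDuplicated(names(pops))) stopf("duplicate population names")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  for (nm in names(pops)) {
    v <- as.numeric(pops[[nm]])
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stopf("frequencies for '%s' outside [0, 1]", nm)
    df[[nm]] <- v
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("geno_table", "data.frame")
  df
}

geno_pops <- function(table) setdiff(names(table), c("chrom", "pos"))

#' Read / write a genotype table as TSV
#'
#' Columns: chrom, pos, then one column per population; empty fields or
#' `NA` are missing.
#' @param path file path.
#' @export
read_geno_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  do.call(genotype_table,
          c(list(chrom = df[[1]], pos = df[[2]]), as.list(df[-(1:2)])))
}

#' @rdname read_geno_tsv
#' @param table a `geno_table`.
#' @export
write_geno_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an EIGENSTRAT genotype trio
#'
#' Reads `.geno` (one row per SNP, one character per individual: count of
#' the `.snp` reference allele, 9 = missing), `.snp` (6 columns) and
#' `.ind` (individual, sex, population). Individuals are grouped by
#' population and the per-population alternative-allele frequency is the
#' mean of individual frequencies (2 - count)/2 over non-missing calls.
#'
#' @param geno,snp,ind file paths.
#' @return A `geno_table` with one column per population.
#' @export
read_eigenstrat <- function(geno, snp, ind) {
  panel <- read_panel(snp, "eigenstrat_snp")
  gl <- readLines(geno)
  gl <- gl[nzchar(gl)]
  if (length(gl) != nrow(panel))
    stopf("geno has %d rows but snp has %d", length(gl), nrow(panel))
  im <- read.table(ind, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(im) < 3) stopf("%s: .ind needs 3 columns", ind)
  pops <- im[[3]]
  g <- do.call(rbind, lapply(strsplit(gl, ""), as.integer))
  if (ncol(g) != nrow(im))
    stopf("geno has %d individuals but ind has %d", ncol(g), nrow(im))
  g[g == 9L] <- NA_integer_
  p_alt <- (2 - g) / 2
  cols <- lapply(unique(pops), function(pp)
    rowMeans(p_alt[, pops == pp, drop = FALSE], na.rm = TRUE))
  names(cols) <- unique(pops)
  cols <- lapply(cols, function(v) { v[is.nan(v)] <- NA_real_; v })
  do.call(genotype_table,
          c(list(chrom = panel$chrom, pos = panel$pos), cols))
}

#' Pseudo-haploid genotype sampling
#'
#' Represents an individual by a single allele per site: `random` mode
#' draws one ref/alt observation uniformly (the common practice in
#' palaeogenomics), `majority` mode takes the modal allele with seeded
#' coin-flip tie-breaking. Sites with no ref/alt observations are
#' missing. Quality thresholds are those the pileup was built with.
#'
#' @param x a [pileup].
#' @param mode `"random"` or `"majority"`.
#' @param seed integer seed driving the draws.
#' @return Data frame chrom, pos, p with p in {0, 1} or NA.
#' @export
pseudo_haploid_sample <- function(x, mode = c("random", "majority"),
                                  seed = 1L) {
  stopifnot(inherits(x, "pileup"))
  mode <- match.arg(mode)
  sc <- site_counts(x)
  tot <- sc$n_ref + sc$n_alt
  p <- rep(NA_real_, nrow(sc))
  with_seed(seed, {
    if (mode == "random") {
      cov <- tot > 0L
      # P(draw alt) = n_alt / (n_ref + n_alt) per site
      p[cov] <- as.numeric(runif(sum(cov)) < sc$n_alt[cov] / tot[cov])
    } else {
      cov <- tot > 0L
      p[cov & sc$n_alt > sc$n_ref] <- 1
      p[cov & sc$n_alt < sc$n_ref] <- 0
      tie <- cov & sc$n_alt == sc$n_ref
      p[tie] <- as.numeric(runif(sum(tie)) < 0.5)
    }
  })
  data.frame(chrom = sc$chrom, pos = sc$pos, p = p, stringsAsFactors = FALSE)
}

#' Naive diploid caller
#'
#' A deliberately simple threshold caller used as plumbing for
#' comparisons against pseudo-haploid data: missing below `min_depth`
#' reads, heterozygous (0.5) when the alternative fraction is inside the
#' band, otherwise the majority homozygote. Not a substitute for a
#' likelihood-based caller on real data.
#'
#' @param x a [pileup].
#' @param min_depth minimum ref+alt depth (default 10).
#' @param band heterozygote band (default \[0.25, 0.75\]).
#' @return Data frame chrom, pos, p with p in {0, 0.5, 1} or NA.
#' @export
naive_diploid_call <- function(x, min_depth = 10L, band = c(0.25, 0.75)) {
  stopifnot(inherits(x, "pileup"))
  sc <- site_counts(x, min_depth, band)
  tot <- sc$n_ref + sc$n_alt
  p <- rep(NA_real_, nrow(sc))
  deep <- tot >= min_depth
  p[deep & sc$is_het] <- 0.5
  hom <- deep & !sc$is_het
  p[hom] <- ifelse(sc$n_alt[hom] > sc$n_ref[hom], 1, 0)
  data.frame(chrom = sc$chrom, pos = sc$pos, p = p, stringsAsFactors = FALSE)
}

# contiguous block index: `block_size` windows per chromosome from pos 1
block_index <- function(chrom, pos, block_size) {
  paste(chrom, (pos - 1L) %/% block_size)
}

#' Weighted block jackknife standard error
#'
#' Delete-one-block jackknife for unequal block sizes: with g blocks of
#' weight m_j, n = sum(m_j) and h_j = n / m_j,
#' theta_J = g * theta - sum_j (1 - m_j/n) * theta_{-j} and
#' var = (1/g) * sum_j (h_j*theta - (h_j - 1)*theta_{-j} - theta_J)^2 /
#' (h_j - 1). With equal weights this reduces to the standard delete-one
#' jackknife variance.
#'
#' @param theta_hat the estimate on all blocks.
#' @param loo per-block delete-one estimates.
#' @param weights positive block weights (typically site counts).
#' @return The jackknife standard error.
#' @export
weighted_block_jackknife <- function(theta_hat, loo, weights) {
  g <- length(loo)
  if (g < 2L) stopf("need >= 2 jackknife blocks")
  if (length(weights) != g) stopf("weights and estimates differ in length")
  if (any(weights <= 0)) stopf("block weights must be positive")
  n <- sum(weights)
  if (any(weights == n)) stopf("degenerate jackknife: a single block holds all weight")
  h <- n / weights
  theta_j <- g * theta_hat - sum((1 - weights / n) * loo)
  v <- sum((h * theta_hat - (h - 1) * loo - theta_j)^2 / (h - 1)) / g
  sqrt(v)
}

# shared core: per-site numerator/denominator terms -> ratio-of-sums
# statistic with delete-one-block jackknife
ratio_stat_jackknife <- function(chrom, pos, num, den, block_size,
                                 zero_zero_is_zero = FALSE) {
  sn <- sum(num); sd_ <- sum(den)
  if (sd_ == 0) {
    if (zero_zero_is_zero && sn == 0) {
      blocks <- block_index(chrom, pos, block_size)
      return(list(est = 0, se = 0, n_sites = length(num),
                  n_blocks = length(unique(blocks))))
    }
    stopf("no informative sites (denominator is zero)")
  }
  est <- sn / sd_
  blocks <- block_index(chrom, pos, block_size)
  bn <- tapply(num, blocks, sum)
  bd <- tapply(den, blocks, sum)
  bw <- tapply(rep(1, length(num)), blocks, sum)
  ok <- (sd_ - bd) != 0
  loo <- ifelse(ok, (sn - bn) / (sd_ - bd), est)
  g <- length(loo)
  se <- if (g >= 2 && sum(bw) > max(bw))
    weighted_block_jackknife(est, as.numeric(loo), as.numeric(bw))
  else NA_real_
  list(est = est, se = se, n_sites = length(num), n_blocks = g)
}

#' D statistic with weighted block jackknife
#'
#' The four-population allele-sharing test
#' D = sum (pW - pX)(pY - pZ) / sum (pW + pX - 2 pW pX)(pY + pZ - 2 pY pZ),
#' summed over sites where all four populations are non-missing. Under
#' tree-ness ((W, X), (Y, Z)) the expectation is 0; with W an outgroup,
#' negative values indicate excess allele sharing of X with Y, positive
#' values of X with Z. Standard errors use the weighted block jackknife
#' over contiguous `block_size` windows (weights = per-block site
#' counts). The degenerate case Y identical to Z (every numerator term
#' zero, and for haploid calls every denominator term too) returns D = 0
#' with se 0.
#'
#' @param table a `geno_table`.
#' @param W,X,Y,Z population column names.
#' @param block_size jackknife block size in bp (default 5 Mbp).
#' @return An object of class `d_stat`: d, se, z, n_sites, n_blocks.
#' @export
d_statistic <- function(table, W, X, Y, Z, block_size = 5e6) {
  stopifnot(inherits(table, "geno_table"))
  for (p in c(W, X, Y, Z))
    if (!p %in% geno_pops(table)) stopf("no population '%s' in table", p)
  cc <- stats::complete.cases(table[c(W, X, Y, Z)])
  if (!any(cc)) stopf("no sites with all four populations non-missing")
  t2 <- table[cc, , drop = FALSE]
  pw <- t2[[W]]; px <- t2[[X]]; py <- t2[[Y]]; pz <- t2[[Z]]
  num <- (pw - px) * (py - pz)
  den <- (pw + px - 2 * pw * px) * (py + pz - 2 * py * pz)
  r <- ratio_stat_jackknife(t2$chrom, t2$pos, num, den, block_size,
                            zero_zero_is_zero = TRUE)
  z <- if (!is.na(r$se) && r$se > 0) r$est / r$se else NA_real_
  structure(list(d = r$est, se = r$se, z = z, n_sites = r$n_sites,
                 n_blocks = r$n_blocks,
                 pops = c(W = W, X = X, Y = Y, Z = Z)),
            class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("D(%s, %s; %s, %s) = %.6f  se %.6f  Z %s  (%d sites, %d blocks)\n",
              x$pops["W"], x$pops["X"], x$pops["Y"], x$pops["Z"],
              x$d, x$se, ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)),
              x$n_sites, x$n_blocks))
  invisible(x)
}

#' f4 statistic
#'
#' Mean over complete sites of (pA - pB)(pC - pD), with a weighted block
#' jackknife standard error.
#'
#' @param table a `geno_table`.
#' @param A,B,C,D population column names.
#' @param block_size jackknife block size in bp.
#' @return List with f4, se, n_sites, n_blocks.
#' @export
f4_statistic <- function(table, A, B, C, D, block_size = 5e6) {
  stopifnot(inherits(table, "geno_table"))
  for (p in c(A, B, C, D))
    if (!p %in% geno_pops(table)) stopf("no population '%s' in table", p)
  cc <- stats::complete.cases(table[c(A, B, C, D)])
  if (!any(cc)) stopf("no complete sites")
  t2 <- table[cc, , drop = FALSE]
  num <- (t2[[A]] - t2[[B]]) * (t2[[C]] - t2[[D]])
  r <- ratio_stat_jackknife(t2$chrom, t2$pos, num, rep(1, length(num)),
                            block_size)
  list(f4 = r$est, se = r$se, n_sites = r$n_sites, n_blocks = r$n_blocks)
}

#' f4-ratio admixture proportion
#'
#' alpha = f4(T, O1; N1, Out) / f4(N2, O1; N1, Out), computed on the
#' intersection of sites complete for all populations involved; the
#' standard error is the weighted block jackknife of the ratio itself
#' (numerator and denominator are recomputed jointly with each block
#' deleted). With T a test individual, O1 an unadmixed outgroup
#' population, N1/N2 two samples of the introgressing lineage and Out a
#' distant outgroup, alpha estimates the admixture proportion.
#'
#' @param table a `geno_table`.
#' @param num,den character vectors of four population names each,
#'   (T, O1, N1, Out) and (N2, O1, N1, Out).
#' @param block_size jackknife block size in bp.
#' @return List with alpha, se, n_sites, n_blocks.
#' @export
f4_ratio <- function(table, num, den, block_size = 5e6) {
  stopifnot(inherits(table, "geno_table"),
            length(num) == 4L, length(den) == 4L)
  pops <- unique(c(num, den))
  for (p in pops)
    if (!p %in% geno_pops(table)) stopf("no population '%s' in table", p)
  cc <- stats::complete.cases(table[pops])
  if (!any(cc)) stopf("no complete sites")
  t2 <- table[cc, , drop = FALSE]
  f4t <- function(v) (t2[[v[1]]] - t2[[v[2]]]) * (t2[[v[3]]] - t2[[v[4]]])
  nu <- f4t(num); de <- f4t(den)
  if (sum(de) == 0) stopf("denominator f4 is zero")
  r <- ratio_stat_jackknife(t2$chrom, t2$pos, nu, de, block_size)
  list(alpha = r$est, se = r$se, n_sites = r$n_sites, n_blocks = r$n_blocks)
}

#' Ancestry-stratified D statistics
#'
#' Recomputes [d_statistic] separately on the table sites falling in each
#' local-ancestry class of the reference assembly (panel annotated with
#' [annotate_ancestry]); jackknife blocks are re-derived within each
#' stratum. Strata with no informative sites are reported as missing.
#'
#' @param table a `geno_table` aligned to `panel` sites.
#' @param W,X,Y,Z population column names.
#' @param panel an ancestry-annotated [snp_panel].
#' @param block_size jackknife block size in bp.
#' @return Named list of `d_stat` objects (or `NULL` for empty strata).
#' @export
stratified_d <- function(table, W, X, Y, Z, panel, block_size = 5e6) {
  stopifnot(inherits(table, "geno_table"), inherits(panel, "snp_panel"))
  if (all(is.na(panel$ancestry)))
    stopf("panel has no ancestry annotation; run annotate_ancestry first")
  key_t <- paste(table$chrom, table$pos)
  key_p <- paste(panel$chrom, panel$pos)
  anc <- panel$ancestry[match(key_t, key_p)]
  out <- list()
  for (lab in intersect(ANCESTRY_LABELS, unique(anc[!is.na(anc)]))) {
    sub <- table[!is.na(anc) & anc == lab, , drop = FALSE]
    class(sub) <- class(table)
    out[[lab]] <- tryCatch(d_statistic(sub, W, X, Y, Z, block_size),
                           error = function(e) NULL)
  }
  out
}
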