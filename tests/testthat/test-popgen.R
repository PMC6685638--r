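# independent brute-force oracles, written directly from the definitions
d_oracle <- function(tb, W, X, Y, Z) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(tb))) {
    p <- c(tb[[W]][i], tb[[X]][i], tb[[Y]][i], tb[[Z]][i])
    if (anyNA(p)) next
    num <- num + (p[1] - p[2]) * (p[3] - p[4])
    den <- den + (p[1] + p[2] - 2 * p[1] * p[2]) *
      (p[3] + p[4] - 2 * p[3] * p[4])
  }
  num / den
}

f4_oracle <- function(tb, A, B, C, D) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(tb))) {
    p <- c(tb[[A]][i], tb[[B]][i], tb[[C]][i], tb[[D]][i])
    if (anyNA(p)) next
    s <- s + (p[1] - p[2]) * (p[3] - p[4]); n <- n + 1
  }
  s / n
}

rand_table <- function(n, seed, miss = 0) {
  set.seed(seed)
  mk <- function() {
    v <- runif(n)
    if (miss > 0) v[runif(n) < miss] <- NA
    v
  }
  genotype_table("1", (1:n) * 3000L, W = mk(), X = mk(), Y = mk(), Z = mk())
}

test_that("d_statistic matches the brute-force per-site summation to 1e-12", {
  for (seed in 1:3) {
    tb <- rand_table(1000, seed, miss = 0.1)
    d <- d_statistic(tb, "W", "X", "Y", "Z")
    expect_equal(d$d, d_oracle(tb, "W", "X", "Y", "Z"), tolerance = 1e-12)
  }
})

test_that("direct formula evaluations: single-site D, nulls and symmetries", {
  tb1 <- genotype_table("1", 1000L, W = 0, X = 1, Y = 1, Z = 0)
  expect_equal(d_statistic(tb1, "W", "X", "Y", "Z")$d, -1)

  # Y column identical to Z column -> exactly zero
  set.seed(4)
  tb2 <- genotype_table("1", (1:500) * 2000L, W = rbinom(500, 1, .5),
                        X = rbinom(500, 1, .5), Y = rbinom(500, 1, .5))
  tb2$Z <- tb2$Y
  class(tb2) <- c("geno_table", "data.frame")
  d0 <- d_statistic(tb2, "W", "X", "Y", "Z")
  expect_identical(d0$d, 0)
  expect_identical(d0$se, 0)

  # exact antisymmetries on arbitrary frequency tables
  tb <- rand_table(400, 9)
  d <- d_statistic(tb, "W", "X", "Y", "Z")$d
  expect_equal(d_statistic(tb, "W", "X", "Z", "Y")$d, -d)
  expect_equal(d_statistic(tb, "X", "W", "Y", "Z")$d, -d)
  expect_lte(abs(d), 1)

  # fixed differences saturate at +/- 1
  tbf <- genotype_table("1", (1:10) * 1000L, W = rep(0, 10), X = rep(1, 10),
                        Y = rep(1, 10), Z = rep(0, 10))
  expect_equal(d_statistic(tbf, "W", "X", "Y", "Z")$d, -1)
})

test_that("f4 matches brute force, vanishes for A=B, and is antisymmetric", {
  tb <- rand_table(1000, 11, miss = 0.05)
  f <- f4_statistic(tb, "W", "X", "Y", "Z")
  expect_equal(f$f4, f4_oracle(tb, "W", "X", "Y", "Z"), tolerance = 1e-12)
  expect_equal(f4_statistic(tb, "W", "W", "Y", "Z")$f4, 0)
  expect_equal(f4_statistic(tb, "X", "W", "Y", "Z")$f4, -f$f4)
})

test_that("weighted jackknife matches a direct evaluation and its equal-weight limit", {
  # 4-block toy input evaluated symbolically from the definition
  theta <- 0.25; loo <- c(0.20, 0.30, 0.22, 0.28); m <- c(10, 20, 30, 40)
  n <- sum(m); g <- 4; h <- n / m
  theta_j <- g * theta - sum((1 - m / n) * loo)
  direct <- sqrt(sum((h * theta - (h - 1) * loo - theta_j)^2 / (h - 1)) / g)
  expect_equal(weighted_block_jackknife(theta, loo, m), direct)

  # equal weights: standard delete-one jackknife variance
  loo2 <- c(1.2, 0.9, 1.05, 1.1)
  se_w <- weighted_block_jackknife(1.06, loo2, rep(7, 4))
  se_d1 <- sqrt((4 - 1) / 4 * sum((loo2 - mean(loo2))^2))
  expect_equal(se_w, se_d1)

  # all delete-one estimates equal to the estimate -> se 0
  expect_equal(weighted_block_jackknife(0.5, rep(0.5, 5), 1:5), 0)

  expect_error(weighted_block_jackknife(1, 2, 3), "blocks")
  expect_error(weighted_block_jackknife(1, c(1, 2), c(0, 1)), "positive")
})

test_that("jackknife standard errors are calibrated on i.i.d. sites", {
  set.seed(12)
  reps <- replicate(200, {
    n <- 1000
    tb <- genotype_table("1", (1:n) * 250000L,
                         W = rbinom(n, 1, .1), X = rbinom(n, 1, .4),
                         Y = rbinom(n, 1, .45), Z = rbinom(n, 1, .55))
    d <- d_statistic(tb, "W", "X", "Y", "Z")
    c(d$d, d$se)
  })
  ratio <- sd(reps[1, ]) / mean(reps[2, ])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("f4-ratio hits its algebraic anchors and errors on a zero denominator", {
  tb <- simulate_admixture_table(5000, 0.3, seed = 2)
  # target identical to N2 -> alpha = 1
  tb$Target <- tb$VindijaNea
  class(tb) <- c("geno_table", "data.frame")
  r1 <- f4_ratio(tb, c("Target", "Mbuti", "AltaiNea", "Chimp"),
                 c("VindijaNea", "Mbuti", "AltaiNea", "Chimp"))
  expect_equal(r1$alpha, 1)
  # target identical to the outgroup population -> alpha = 0
  tb$Target <- tb$Mbuti
  class(tb) <- c("geno_table", "data.frame")
  r0 <- f4_ratio(tb, c("Target", "Mbuti", "AltaiNea", "Chimp"),
                 c("VindijaNea", "Mbuti", "AltaiNea", "Chimp"))
  expect_equal(r0$alpha, 0)

  cz <- genotype_table("1", (1:10) * 1000L, A = rep(.5, 10), B = rep(.5, 10),
                       C = runif(10), D = runif(10))
  expect_error(f4_ratio(cz, c("C", "D", "A", "B"), c("A", "B", "C", "D")),
               "denominator")
})

test_that("pseudo-haploid sampling is uniform over reads and majority mode is modal", {
  n <- 1000L
  panel <- snp_panel("c", (1:n) * 50L, rep("A", n), rep("T", n))
  obs <- do.call(rbind, lapply(1:n, function(i)
    data.frame(site = i, chrom = "c", pos = i * 50L,
               read_id = sprintf("r%d_%d", i, 1:10),
               allele = rep(c("alt", "ref"), c(5, 5)), baseq = 40L,
               mapq = 37L, fragment_length = 50L,
               read_group = NA_character_, stringsAsFactors = FALSE)))
  pu <- structure(list(obs = obs, panel = panel, min_mapq = 30L,
                       min_baseq = 30L), class = "pileup")
  ph <- pseudo_haploid_sample(pu, "random", seed = 3)
  # binomial oracle: mean call within 3 se of 0.5
  expect_lt(abs(mean(ph$p) - 0.5), 3 * sqrt(0.25 / n))
  # determinism under seed
  expect_identical(ph, pseudo_haploid_sample(pu, "random", seed = 3))

  obs2 <- obs
  obs2$allele <- rep(rep(c("alt", "ref"), c(7, 3)), n)
  pu2 <- structure(list(obs = obs2, panel = panel, min_mapq = 30L,
                        min_baseq = 30L), class = "pileup")
  expect_true(all(pseudo_haploid_sample(pu2, "majority", seed = 1)$p == 1))

  # single ref read -> call 0; uncovered site -> missing
  obs3 <- obs[obs$site == 1 & obs$allele == "ref", ][1, ]
  pu3 <- structure(list(obs = obs3, panel = panel, min_mapq = 30L,
                        min_baseq = 30L), class = "pileup")
  ph3 <- pseudo_haploid_sample(pu3, "random", seed = 1)
  expect_equal(ph3$p[1], 0)
  expect_true(all(is.na(ph3$p[-1])))
})

test_that("the naive diploid caller follows depth and band rules", {
  mkpu <- function(n_ref, n_alt) {
    panel <- snp_panel("c", 100L, "A", "T")
    depth <- n_ref + n_alt
    obs <- data.frame(site = 1L, chrom = "c", pos = 100L,
                      read_id = sprintf("r%d", seq_len(depth)),
                      allele = rep(c("alt", "ref"), c(n_alt, n_ref)),
                      baseq = 40L, mapq = 37L, fragment_length = 50L,
                      read_group = NA_character_, stringsAsFactors = FALSE)
    structure(list(obs = obs, panel = panel, min_mapq = 30L,
                   min_baseq = 30L), class = "pileup")
  }
  expect_equal(naive_diploid_call(mkpu(5L, 5L))$p, 0.5)
  expect_equal(naive_diploid_call(mkpu(10L, 0L))$p, 0)
  expect_equal(naive_diploid_call(mkpu(0L, 10L))$p, 1)
  expect_true(is.na(naive_diploid_call(mkpu(5L, 4L))$p))
})

test_that("ancestry-stratified D isolates a stratum-specific signal", {
  set.seed(6)
  n <- 600L
  pos <- (1:n) * 40000L
  panel <- snp_panel("1", pos, rep("A", n), rep("T", n))
  seg <- data.frame(chrom = "1", start = c(0L, 12000000L),
                    end = c(12000000L, 40000000L),
                    label = c("European", "African"))
  panel <- annotate_ancestry(panel, seg)
  w <- rbinom(n, 1, .2); x <- rbinom(n, 1, .5)
  y <- rbinom(n, 1, .5)
  z <- y
  eu <- panel$ancestry == "European"
  # inject disagreement between Y and Z only in the European stratum,
  # correlated with X so D moves away from zero there
  z[eu] <- ifelse(runif(sum(eu)) < 0.6, x[eu], y[eu])
  tb <- genotype_table("1", pos, W = w, X = x, Y = y, Z = z)
  res <- stratified_d(tb, "W", "X", "Y", "Z", panel)
  expect_true(abs(res$European$d) > abs(res$African$d))
  expect_identical(res$African$d, 0)

  # a single stratum reproduces the unstratified statistic
  pan1 <- panel; pan1$ancestry <- "European"
  res1 <- stratified_d(tb, "W", "X", "Y", "Z", pan1)
  expect_equal(res1$European$d, d_statistic(tb, "W", "X", "Y", "Z")$d)
})

test_that("eigenstrat trios and the TSV dialect round-trip genotype tables", {
  snp <- tempfile(fileext = ".snp"); geno <- tempfile(fileext = ".geno")
  ind <- tempfile(fileext = ".ind")
  writeLines(c("rs1\t1\t0\t100\tA\tT", "rs2\t1\t0\t200\tG\tC",
               "rs3\t1\t0\t300\tC\tA"), snp)
  # individuals: two in popA, one in popB; values = ref-allele counts
  writeLines(c("029", "120", "999"), geno)
  writeLines(c("i1\tU\tpopA", "i2\tU\tpopA", "i3\tU\tpopB"), ind)
  tb <- read_eigenstrat(geno, snp, ind)
  # popA at rs1: ref counts 0 and 2 -> alt freqs 1 and 0 -> 0.5
  expect_equal(tb$popA, c(0.5, 0.25, NA))
  expect_equal(tb$popB, c(NA, 1, NA))

  f <- tempfile(fileext = ".tsv")
  write_geno_tsv(tb, f)
  tb2 <- read_geno_tsv(f)
  expect_equal(as.data.frame(tb2), as.data.frame(tb))
})
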