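---
title: "Measuring and mitigating reference bias in ancient DNA: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and mitigating reference bias in ancient DNA: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refbias)
```

## The problem

Resequencing studies align reads against a single haploid reference
genome. At a biallelic SNP, a read carrying the alternative allele starts
one mismatch behind an otherwise identical reference-allele read. Under
the length-scaled edit budgets used by short-read aligners, that single
mismatch changes the probability that the read maps at all, maps
uniquely, or maps above a quality threshold. The result is *reference
bias*: at a true heterozygote, mapped reads over-represent the reference
allele.

Ancient DNA is unusually exposed to this artifact. Fragments are short
(most under 100 bp, many near 35-50 bp), so the absolute mismatch budget
is small; post-mortem deamination adds extra mismatches; and the dominant
analysis style is *pseudo-haploid* genotyping -- one read drawn per site
-- which converts any read-level skew directly into genotype-level skew.
Downstream, that skew propagates into heterozygosity estimates, D
statistics and f4-ratio ancestry proportions.

This package implements the full measurement-diagnosis-mitigation loop
for this problem on a pre-defined panel of known biallelic SNPs, plus the
synthetic-data generators needed to exercise it end to end without any
external data or aligner.

## Allelic balance at known heterozygous sites

All metrics are restricted to a SNP panel (`snp_panel`), in practice
filtered to transversions (`filter_transversions`) so that C-to-T /
G-to-A deamination damage cannot masquerade as an allele, to a minimum
minor-allele frequency (the reference panels this mirrors used 5%), and
to regions uniquely mappable with 35-bp reads (`compute_mappability`,
`apply_mappability_mask`).

A site counts as *heterozygous* when at least 10 reads carry one of the
two panel alleles and between 25% and 75% of them (closed band -- the
verbal definition does not fix openness, and the closed choice keeps the
rule symmetric) carry the alternative allele. The headline metric
(`bias_summary`) is the mean per-site alternative-allele fraction over
heterozygous sites, with the standard error of the mean; an unbiased
pipeline is expected at 0.5. Third-allele observations are excluded from
both numerator and denominator so triallelic noise cannot dilute the
balance. Base qualities are used exactly as stored: no rescaling model
exists anywhere in the package, because rescalers typically consult the
reference allele and can amplify the bias being measured.

Supporting metrics follow the same conditioning: `stratify_by_fragment_length`
re-applies the 10-read rule inside each length bin;
`heterozygosity_proxy` reports the share of sufficiently covered sites
classified heterozygous (a relative heterozygosity measure that reference
bias depresses); `bias_correlation` correlates per-site balances between
two samples over sites heterozygous in both, with a two-sided p-value
from the exact t transform on n-2 degrees of freedom (the choice of test
was open; the t reference is exact under bivariate normality and standard
practice at these sample sizes).

## The internal mapper and its budget model

The analyses only need an aligner's *behaviour* -- a length-scaled edit
budget, a gap-open cap, both strands, a uniqueness-driven MAPQ -- not any
particular implementation. The package therefore ships a deterministic
seed-and-extend mapper (`map_reads`), used both for primary mapping of
simulated fragments and for the remapping steps of the filters and the
balance diagnostic:

* **Budget.** `maxdiff(L)` is the smallest k with P(X > k) < `miss_frac`
  for X ~ Poisson(L * `err_rate`), defaults 0.02 and 0.01. This
  reproduces the shape of the classic length-scaled budget: 3 mismatches
  for 35-41 bp, 4 for 42-63 bp, 5 for 64 bp and up.
* **Candidates.** Every overlapping 7-mer of the read is looked up in a
  genome index and projected onto diagonals; diagonal runs are kept if
  they collect at least (L - 6) - 7k hits (the q-gram bound), which is
  complete for alignments within the budget and prunes random hits.
* **Verification.** A windowed semi-global dynamic program (read global,
  reference ends free) minimises (edits, gap opens) lexicographically,
  with gap opens capped at 2. Among minimal-edit alignments the fewest
  gap opens win; remaining ties break deterministically by chromosome
  name, start, then + strand.
* **MAPQ.** 37 for a single hit within the budget, 25 for a unique best
  hit with worse secondary hits inside the budget, 0 for two or more
  co-optimal hits. The downstream analyses only threshold MAPQ, so any
  monotone uniqueness score works; these values document what the
  thresholds 10/20/30 mean *for this mapper*. They are not transferable
  to BAMs produced by other aligners.

N bases count as mismatches everywhere. Mapped sequences are stored
reference-forward with the original orientation kept in the strand flag,
which makes allele inspection at SNPs strand-free.

## The virtual opposite-allele diagnostic

Averages hide structure, so the package also implements the doubled
read-set diagnostic (`build_balanced_readset`): every read that carries
ref or alt (MAPQ >= 30, base quality >= 30 at the SNP) is paired with a
copy whose allele is swapped at *every* overlapping panel SNP. Swapping
all SNPs on multi-SNP reads (rather than one at a time) keeps per-SNP
balance exact with a single copy per read -- the joint set is perfectly
balanced at every SNP by construction. After remapping
(`remap_and_classify`, by default restricted to reads that return to
their original locus), any SNP whose alternative fraction deviates from
1/2 has been skewed by mapping alone. Fractions are kept as integer
(alt, total) pairs and binned by exact rational comparison
(`balance_histogram`) into {0}, (0, 0.4), [0.4, 0.5), {0.5}, (0.5, 0.6],
(0.6, 1), {1} -- the singleton bins would be meaningless under floating
point.

## The two remapping filters

Both filters interrogate only reads overlapping panel SNPs; reads
touching no SNP are never removed.

* **Modified reads** (`modified_read_filter`): each read carrying the
  reference allele is copied, flipped to the alternative allele at all
  its ref-carrying SNPs, and remapped. The original is kept only if the
  flipped copy maps to the identical (chrom, start, strand), without
  indels, with MAPQ >= 30. In words: keep a reference-allele read only
  if it would also have survived as an alternative-allele read.
* **Modified reference** (`modified_reference_filter`): a copy of the
  reference carries a seeded random *third* allele at every SNP
  (`build_modified_reference`; the substitution table is written out so
  the genome is reproducible bit for bit). Every SNP-overlapping read is
  remapped against it; ref- and alt-carriers then face exactly one
  mismatch each at the SNP, so the filter is allele-symmetric by
  construction.
* **Combined** (`combined_filter`): the intersection of the two pass
  sets. Both filters are per-read predicates, so intersection and
  sequential filtering coincide.

Design points that the verbal description leaves open, fixed here: the
remap must reach MAPQ 30 (matching the analysis-side threshold -- a remap
that limps back ambiguously should not count); "same position" means the
identical (chrom, start, strand) triple; multi-SNP reads are flipped at
all ref-carrying SNPs simultaneously, one remap per read. The filters
cannot restore reads already lost at the first mapping, so filtered data
approaches but does not generally reach 50/50 -- the residual-bias tests
assert exactly this.

## Population-genetic statistics

`d_statistic` implements

D = sum (pW - pX)(pY - pZ) / sum (pW + pX - 2 pW pX)(pY + pZ - 2 pY pZ)

over sites where all four populations are non-missing, the
heterozygosity-normalised form of the classic four-population test. The
sign convention is locked so that with W an outgroup, negative D means
excess sharing of X with Y. One degenerate case needs a convention: with
Y and Z the same haploid column, every numerator term *and* every
denominator term vanishes. The tree-consistent value is 0, and the
package returns D = 0 with se 0 in exactly this case (a zero denominator
with a nonzero numerator remains an error). `f4_statistic` is the plain
mean of (pA - pB)(pC - pD); `f4_ratio` estimates an admixture proportion
as the ratio of two f4 sums on the intersection of complete sites.

Standard errors use a weighted block jackknife over contiguous 5-Mbp
windows per chromosome (trailing partial windows kept), with block
weights equal to per-block site counts and the delete-m_j formula: with
n = sum m_j and h_j = n/m_j,

theta_J = g theta - sum_j (1 - m_j/n) theta_{-j},
var = (1/g) sum_j (h_j theta - (h_j - 1) theta_{-j} - theta_J)^2 / (h_j - 1).

At equal weights this reduces to the standard delete-one jackknife (a
property the tests verify numerically). For the f4-ratio the jackknife
deletes blocks from numerator and denominator jointly and resamples the
ratio itself, not the two f4s separately. `stratified_d` recomputes D
within each local-ancestry class of the reference assembly, re-deriving
blocks per stratum.

Pseudo-haploid sampling (`pseudo_haploid_sample`) draws one ref/alt read
per site (uniform, seeded) or takes the majority allele with a seeded
coin for ties. `naive_diploid_call` is deliberately simple plumbing --
depth >= 10, heterozygote inside the 25-75% band, otherwise the majority
homozygote -- sufficient for haploid-versus-diploid comparisons on known
sites, and not a variant caller.

## Synthetic data: what it emulates and what it does not

`sim_config` fixes the study conditions; every generator is byte-identical
under the seed.

* **Reference** (`simulate_reference`): i.i.d. bases plus optional exact
  segment duplications to create multi-mapping loci. Defaults to 200 kb.
* **Individual** (`simulate_individual`): transversion-only SNPs at 2.5
  per kb by default, all heterozygous by default -- the metrics condition
  on known heterozygous sites, so the generator's default produces
  exactly the sites of interest; `het_fraction` scales down for
  heterozygosity-proxy scenarios.
* **Fragments** (`simulate_fragments`): lengths from a lognormal
  parameterised by its mode (default 45 bp, sdlog 0.35, truncated at
  30 bp) -- the mode is the length statistic that correlates with bias,
  so it is the natural control; terminal deamination as C-to-T at the 5'
  end and G-to-A at the 3' end with probability p0 exp(-lambda i)
  (defaults 0.3 and 0.3, typical of non-UDG libraries); uniform per-base
  sequencing error (default 0.002); contamination as a fraction of
  fragments from a reference-matching haplotype (worst case for
  reference bias; off by default). Qualities are constant Phred 40:
  damage is invisible to qualities, as in real data. The deamination
  model is deliberately minimal -- a terminal exponential, not an
  empirical damage profile -- because the analysis design (transversions
  only) is meant to make the metrics robust to damage, and a simple
  model suffices to demonstrate that.
* **Admixture tables** (`simulate_admixture_table`): five populations
  with haploid calls; ancestral frequencies Uniform(0.05, 0.95), bounded
  Mbuti-like drift (half-width 0.2), heavy Neandertal-like drift
  (half-width 0.5, clipped) shared by two Neandertal samples, outgroup
  fixed at zero, target = alpha Neandertal + (1 - alpha) Mbuti. The heavy
  archaic drift keeps the denominator f4 well away from zero so the
  ratio is estimable at desk scale.

What passing the closed-loop tests shows: the pipeline is internally
unbiased, the bias that appears under repeats/damage/short fragments is
mechanistically the budget effect, and the filters remove it in the way
the theory predicts. What it does not show: behaviour under real damage
profiles, real repeat structure, UDG chemistry, or another aligner's
MAPQ semantics.

## Numerical choices and problem sizes

* Exact integer arithmetic for balance bins; all other statistics in
  double precision, with oracle tests at 1e-12.
* The closed-loop suites run at desk scale, chosen so every check has
  clear statistical power while the whole suite stays light: the
  unbiased null uses a 200-kb genome, 500 heterozygous transversion
  SNPs, 20x; the balance-by-design check 100 kb / 200 SNPs / 15x; the
  biased study 100 kb with a duplicated 500-bp segment, 8 SNPs per kb,
  100x, lognormal mode 48, deamination p0 = 0.6, lambda = 0.2 (heavy,
  single-stranded-library-like damage, which gives the length gradient
  comfortable power at these depths); f4-ratio recovery 20,000 sites per
  replicate, 100 replicates per alpha.
* Fragment-length bins in the biased study are 35-41, 42-63 and 64-80
  bp, aligned with the internal mapper's budget plateaus (3, 4, 5
  mismatches). Within a plateau the expected balance *falls* slightly
  with length (the budget is fixed while expected non-allelic mismatches
  grow), so very fine bins would saw-tooth; plateau-aligned bins measure
  the budget effect itself.
* `d_statistic` returns z = NA when se = 0 (including the degenerate
  Y = Z case); jackknife requires at least two blocks and at least one
  block must not hold all the weight.

## Known limitations

* The mapper's MAPQ is a three-level uniqueness score; thresholds are
  meaningful relative to this mapper only.
* Mappability is exact k-mer uniqueness, not an alignment-aware
  mappability (no mismatched multi-mappers).
* The EIGENSTRAT reader averages individual frequencies within a
  population and does not weight by call counts.
* Filters operate per read; paired information (none in merged aDNA
  fragments) and within-read base-quality structure are ignored.
* `naive_diploid_call` is plumbing for comparisons, not a genotyper.
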