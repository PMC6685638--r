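#' Reference genome container
#'
#' A named set of chromosome sequences stored as plain upper-case strings
#' (bases A, C, G, T, N). Substitution and subsequence extraction return new
#' objects; nothing is modified in place.
#'
#' @param sequences named character vector of sequences.
#' @return An object of class `ref_genome`.
#' @examples
#' ref_genome(c(chr1 = "ACGTACGT"))
#' @export
ref_genome <- function(sequences) {
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stopf("reference sequences must be named")
  if (anyDuplicated(names(sequences)))
    stopf("duplicate sequence names in reference")
  if (any(grepl("[^ACGTN]", sequences)))
    stopf("reference bases must be in A, C, G, T, N")
  structure(sequences, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("Reference genome: %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(unclass(x))), big.mark = ",")))
  for (nm in names(x))
    cat(sprintf("  %s  %d bp\n", nm, nchar(unclass(x)[[nm]])))
  invisible(x)
}

#' @export
length.ref_genome <- function(x) length(unclass(x))

ref_lengths <- function(ref) nchar(unclass(ref))

#' Extract a subsequence (1-based, inclusive)
#' @param ref a [ref_genome].
#' @param chrom sequence name.
#' @param start,end 1-based inclusive coordinates.
#' @export
ref_subseq <- function(ref, chrom, start, end) {
  stopifnot(inherits(ref, "ref_genome"))
  s <- unclass(ref)[[chrom]]
  if (is.null(s)) stopf("no sequence named '%s'", chrom)
  substring(s, start, end)
}

#' Point-substitute bases, returning a new genome
#' @param ref a [ref_genome].
#' @param chrom,pos,base vectors of equal length; `pos` is 1-based.
#' @export
ref_substitute <- function(ref, chrom, pos, base) {
  stopifnot(inherits(ref, "ref_genome"))
  seqs <- unclass(ref)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    s <- seqs[[ch]]
    if (is.null(s)) stopf("no sequence named '%s'", ch)
    p <- pos[i]
    if (any(p < 1L | p > nchar(s))) stopf("substitution outside '%s'", ch)
    sp <- strsplit(s, "")[[1]]
    sp[p] <- base[i]
    seqs[[ch]] <- paste0(sp, collapse = "")
  }
  ref_genome(seqs)
}

#' Read / write FASTA
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ref_genome(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
}

#' @rdname read_fasta
#' @param ref a [ref_genome].
#' @export
write_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "ref_genome"))
  x <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
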