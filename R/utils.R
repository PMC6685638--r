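# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# complement / reverse complement on plain character vectors
comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

revcomp <- function(x) {
  .cpp_revcomp(as.character(x))
}

# run `code` with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Phred+33 encoding of per-base qualities
qual_to_phred <- function(qualstr) {
  lapply(qualstr, function(q) as.integer(charToRaw(q)) - 33L)
}

phred_to_qual <- function(phred) {
  vapply(phred, function(p) rawToChar(as.raw(p + 33L)), character(1))
}

# quality of the base at 1-based offset `off` in each read (vectorised)
qual_at <- function(qualstr, off) {
  as.integer(charToRaw(paste0(substring(qualstr, off, off), collapse = ""))) - 33L
}

is_transversion <- function(ref, alt) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  purine[ref] != purine[alt]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
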