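# Low-level string utilities shared by the simulator and read-processing code.
# Sequences are manipulated as raw-byte matrices so that per-base comparisons
# across tens of thousands of reads stay vectorised.

#' @importFrom stats rbinom rpois rnorm rmultinom sd uniroot aggregate setNames
#' @importFrom utils adist read.delim write.table head
NULL

# one fixed-width character vector -> raw matrix (rows = sequences)
seq_raw_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(raw(0), 0L, 0L))
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("sequences must have equal length")
  matrix(charToRaw(paste(x, collapse = "")), ncol = L, byrow = TRUE)
}

# raw matrix (rows = sequences) -> character vector
raw_matrix_seqs <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  big <- rawToChar(as.raw(t(m)))
  L <- ncol(m)
  substring(big, (seq_len(nrow(m)) - 1L) * L + 1L, seq_len(nrow(m)) * L)
}

# Hamming distance of each element of x (all nchar == nchar(ref)) to ref
hamming_to_ref <- function(x, ref) {
  if (length(x) == 0L) return(integer(0))
  m <- seq_raw_matrix(x)
  r <- matrix(charToRaw(ref), nrow(m), nchar(ref), byrow = TRUE)
  as.integer(rowSums(m != r))
}

# pairwise Hamming distance between equal-length strings a[i], b[i]
hamming_pairwise <- function(a, b) {
  if (length(a) == 0L) return(integer(0))
  ma <- seq_raw_matrix(a)
  mb <- seq_raw_matrix(b)
  as.integer(rowSums(ma != mb))
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse each string (used for quality strings alongside revcomp)
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# n random DNA strings of width len
rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  do.call(paste0, split(m, col(m)))
}

# replace the bases of `seq` at 0-based offset spanning nchar(ref) with `alt`
substitute_allele <- function(seq, offset, ref, alt) {
  paste0(substr(seq, 1L, offset),
         alt,
         substr(seq, offset + nchar(ref) + 1L, nchar(seq)))
}

# stop() with a consistent prefix for user-facing configuration errors
config_error <- function(...) stop(..., call. = FALSE)
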