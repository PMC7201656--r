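# Small shared helpers: sequence string utilities and seeded evaluation.

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement for plain character vectors, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGGA"))
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of given lengths, from the current RNG stream.
random_dna <- function(lengths) {
  vapply(lengths, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Apply point substitutions to a single sequence at the given rate.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) == 0) return(seq)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  chars[hit] <- vapply(chars[hit], function(b) {
    choices <- strsplit(alt[[b]], "")[[1]]
    sample(choices, 1)
  }, character(1))
  paste(chars, collapse = "")
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Derive a reproducible child seed (kept below 2^31).
child_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483587L
}

# Number of mismatches between equal-length string pairs (vectorised).
mismatch_count <- function(a, b) {
  if (length(a) == 0) return(integer())
  cpp_mismatch_count(a, b)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
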