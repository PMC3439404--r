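# Internal helpers shared across modules.

# Validate a proportion-valued argument.
check_prop <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || !hi_ok) {
    stop(sprintf("'%s' must be a proportion in [0, %s]", name,
                 if (allow_one) "1" else "1)"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Random DNA of a given length and GC fraction, as a character scalar.
random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Truncate (not round) to k decimal places; used where published tables
# print truncated percentages.
trunc_dp <- function(x, k) floor(x * 10^k) / 10^k

`%||%` <- function(a, b) if (is.null(a)) b else a
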