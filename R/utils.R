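BASES <- c("A", "C", "G", "T")

# Random DNA string of length n (uses the current RNG stream).
rand_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Reverse complement of a DNA string.
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Substring with 0-based half-open coordinates.
subseq0 <- function(x, start, end) substr(x, start + 1L, end)

# Replace bases of a string at 0-based positions with given characters.
replace_bases <- function(x, pos0, chars) {
  v <- strsplit(x, "")[[1]]
  v[pos0 + 1L] <- chars
  paste(v, collapse = "")
}

# A base different from `b`, chosen from the current RNG stream.
other_base <- function(b) {
  vapply(b, function(bb) sample(setdiff(BASES, bb), 1L), character(1),
         USE.NAMES = FALSE)
}

# log(sum(exp(x))) without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
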