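#' @import Biostrings
#' @importFrom IRanges IRanges
#' @importFrom stats dbinom pchisq phyper rbinom rmultinom rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

# Reverse complement of an A/C/G/T/N character string.
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Uniform-random DNA (50% GC), vector of n sequences of length len.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES4, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Mutate each position independently with probability rate to one of the
# three other bases.  Used to diverge pseudo-species copies of a transcript.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES4, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

# substr with 0-based half-open coordinates (the internal convention).
substr0 <- function(seq, start, end) substr(seq, start + 1L, end)

# Translate a nucleotide string; returns an amino-acid string with "*" for
# stop codons.  Trailing incomplete codons are dropped.
translate_dna <- function(seq) {
  n <- 3L * (nchar(seq) %/% 3L)
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

# Overlap length of two 0-based half-open intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

# Deterministic sub-seed derivation: one master seed fans out to stage seeds.
derive_seed <- function(seed, stage) {
  (seed * 48271 + sum(utf8ToInt(stage))) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}
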