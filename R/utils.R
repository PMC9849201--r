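# Small shared helpers.

# Round half away from zero (spreadsheet convention), unlike base round()
# which rounds half to even.  Accuracy tables are reported this way.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Check a nucleotide string over the DNA alphabet, return uppercase
check_dna <- function(seq, what = "sequence") {
  if (!is_string(seq) || nchar(seq) == 0L)
    stopf("%s must be a non-empty character scalar", what)
  s <- toupper(seq)
  if (grepl("[^ACGT]", s))
    stopf("%s contains non-ACGT characters: %s", what, seq)
  s
}
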