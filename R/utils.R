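DNA_BASES <- c("A", "C", "G", "T")

## reverse complement of plain character vectors (delegates to Biostrings)
revComp <- function(x) {
  out <- character(length(x))
  nonempty <- nchar(x) > 0L
  if (any(nonempty)) {
    out[nonempty] <- as.character(reverseComplement(DNAStringSet(x[nonempty])))
  }
  out
}

## round half away from zero (base round() is banker's rounding)
roundHalfAway <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
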