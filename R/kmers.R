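# Integer k-mer encoding shared by the anchor aligner and the read mapper.
# Codes are base-4 integers stored in doubles; exact for k <= 26 (4^26 < 2^53).

#' @importFrom data.table rbindlist as.data.table
.datatable.aware <- TRUE

.BASE_CODE <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

# numeric vector of k-mer codes for every 0-based offset 0..(n-k); NA where
# the window contains a non-ACGT character
encode_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1, k <= 26)
  b <- .BASE_CODE[utf8ToInt(seq)]
  n <- length(b)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (j in seq_len(k)) code <- code * 4 + b[j:(m + j - 1L)]
  code
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# indices (1-based) of codes occurring exactly once, NA excluded
.unique_code_idx <- function(codes) {
  ok <- which(!is.na(codes))
  if (length(ok) < 2L) return(ok)
  o <- ok[order(codes[ok])]
  s <- codes[o]
  dup_prev <- c(FALSE, s[-1L] == s[-length(s)])
  dup <- dup_prev | c(dup_prev[-1L], FALSE)
  o[!dup]
}
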