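#' @importFrom stats median rnorm runif rbinom rmultinom rlnorm pt t.test var sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

DNA <- c("A", "C", "G", "T")

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# round() uses banker's rounding; CN states need conventional half-up.
round_half_up <- function(x) floor(x + 0.5)

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

# Substitute each selected position by a uniformly chosen different base.
substitute_bases <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  old <- chars[idx]
  # draw an offset 1..3 and rotate within the alphabet: always a different base
  shift <- sample.int(3L, length(idx), replace = TRUE)
  pos <- match(old, DNA)
  chars[idx] <- DNA[((pos - 1L + shift) %% 4L) + 1L]
  chars
}

# data.frame() without its validation overhead; columns must already be
# equal-length atomic vectors.
fast_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1L]])))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
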