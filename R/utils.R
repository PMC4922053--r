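# shared helpers (internal)

.datatable.aware <- TRUE

# centred moving-average smoothing; window must be odd
smooth_ma <- function(x, window = 3L) {
  if (window <= 1L || length(x) < window) return(as.numeric(x))
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, as.numeric(x)))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# indices of strict-or-plateau local maxima of a numeric vector
local_maxima <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(if (x[1] > 0) 1L else integer(0))
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x > left & x >= right)
}

# random DNA as a character string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# coerce a file path or DNAStringSet to DNAStringSet
as_assembly <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  stop("cannot interpret input as an assembly (FASTA path or DNAStringSet)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
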