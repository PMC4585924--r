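#' Shortest distance between two positions on a circle
#'
#' @param a,b 0-based positions, `0 <= a,b < L`. Vectorised.
#' @param L circle (genome) length in bp.
#' @return `min((b-a) mod L, (a-b) mod L)`; symmetric and never more than `L/2`.
#' @export
#' @examples
#' circular_distance(0, 10, 100)   # 10
#' circular_distance(95, 5, 100)   # 10, across the origin
circular_distance <- function(a, b, L) {
  if (length(L) != 1L || is.na(L) || L <= 0) {
    stop("genome length L must be a single positive number")
  }
  if (any(a < 0 | a >= L) || any(b < 0 | b >= L)) {
    stop("positions must satisfy 0 <= pos < L")
  }
  d <- (b - a) %% L
  pmin(d, L - d)
}

#' Reverse complement of a nucleotide string
#' @param x character scalar over A,C,G,T,N (case-insensitive).
#' @return reverse complement, upper case.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' A+T percentage of a nucleotide string (N ignored)
#' @param x nucleotide string.
#' @return percentage in \[0, 100\]; `NaN` for an all-N or empty string.
#' @export
at_percent <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(ch) == 0L) return(NaN)
  100 * sum(ch %in% c("A", "T")) / length(ch)
}

#' G+C percentage of a nucleotide string (N ignored)
#' @param x nucleotide string.
#' @return percentage in \[0, 100\].
#' @export
gc_percent <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(ch) == 0L) return(NaN)
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

# Extract [start, end) from a circular sequence, 0-based half-open.
# end <= start means the interval wraps through the origin.
circular_substr <- function(seq, start, end) {
  L <- nchar(seq)
  if (end > start) {
    substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, L), substr(seq, 1L, end))
  }
}

# random nucleotide string with a given A+T fraction (A/T and G/C equiprobable
# within their class); uses the current RNG stream
random_seq <- function(n, at = 0.5) {
  if (n <= 0L) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}
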