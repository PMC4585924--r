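# Per-genome compactness statistics and inverted-repeat detection.

#' Compactness statistics for one genome
#'
#' Computes the standard descriptive row for a plastid genome: size, G+C and
#' A+T percentages (over the full sequence, N ignored), percentage of
#' positions covered by no annotated gene (non-coding DNA), the mean length
#' of the maximal intergenic gaps on the circle, and gene counts by type.
#' Coding coverage is the union of all gene features, so overlapping genes
#' are counted once.
#'
#' @param genome an [annotated_genome()].
#' @return list of class `genome_stats` with fields `id`, `size_bp`,
#'   `gc_percent`, `at_percent`, `noncoding_percent`, `mean_intergenic_bp`,
#'   `n_gaps`, `n_protein`, `n_rRNA`, `n_tRNA`, `n_genes`.
#'   For a genome with zero features, `noncoding_percent` is 100 and
#'   `mean_intergenic_bp` is the full length (flagged via `degenerate`).
#' @export
genome_stats <- function(genome) {
  L <- genome$length
  f <- genome$features
  out <- list(id = genome$id, size_bp = L,
              gc_percent = gc_percent(genome$sequence),
              at_percent = at_percent(genome$sequence),
              n_protein = sum(f$gene_type == "protein"),
              n_rRNA = sum(f$gene_type == "rRNA"),
              n_tRNA = sum(f$gene_type == "tRNA"),
              n_genes = nrow(f), degenerate = FALSE)
  if (nrow(f) == 0L) {
    out$noncoding_percent <- 100
    out$mean_intergenic_bp <- L
    out$n_gaps <- NA_integer_
    out$degenerate <- TRUE
    class(out) <- "genome_stats"
    return(out)
  }
  gaps <- intergenic_gaps(genome)
  uncovered <- sum(gaps)
  out$noncoding_percent <- 100 * uncovered / L
  out$n_gaps <- length(gaps)
  out$mean_intergenic_bp <- if (length(gaps) == 0L) 0 else uncovered / length(gaps)
  class(out) <- "genome_stats"
  out
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf("%s: %s bp | GC %.1f%% | AT %.1f%% | non-coding %.2f%% | mean intergenic %.0f bp | %d protein, %d rRNA, %d tRNA\n",
              x$id, format(x$size_bp, big.mark = ","), x$gc_percent, x$at_percent,
              x$noncoding_percent, x$mean_intergenic_bp,
              x$n_protein, x$n_rRNA, x$n_tRNA))
  invisible(x)
}

# Lengths of the maximal runs of positions covered by no feature, walking
# the circle. Zero-length gaps (abutting genes) do not exist as runs and are
# therefore excluded by construction.
intergenic_gaps <- function(genome) {
  mask <- coverage_mask(genome)
  L <- length(mask)
  if (all(mask)) return(integer(0))
  if (!any(mask)) return(L)
  # rotate so position 1 is covered; uncovered runs are then interior
  first_cov <- which(mask)[1L]
  mask <- c(mask[first_cov:L], mask[seq_len(first_cov - 1L)])
  r <- rle(mask)
  r$lengths[!r$values]
}

#' Tabulate compactness statistics for several genomes
#' @param genomes list of [annotated_genome()] objects.
#' @return data.frame, one row per genome, mirroring the usual
#'   plastid-genome feature table (size, %ncDNA, mean intergenic distance,
#'   gene counts, G+C, inverted repeat length).
#' @export
stats_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    s <- genome_stats(g)
    ir <- detect_inverted_repeat(g)
    data.frame(id = s$id, size_bp = s$size_bp,
               ncDNA_percent = s$noncoding_percent,
               mean_intergenic_bp = s$mean_intergenic_bp,
               n_protein = s$n_protein, n_rRNA = s$n_rRNA, n_tRNA = s$n_tRNA,
               gc_percent = s$gc_percent,
               ir_length = if (ir$found) ir$length else 0L)
  })
  do.call(rbind, rows)
}

#' Detect a large inverted repeat
#'
#' Seed-and-extend scan for the longest pair of reverse-complement repeats at
#' distinct loci: exact `k`-mer seeds between the sequence and its reverse
#' complement are extended to maximal exact matches, and the longest
#' non-self-overlapping pair of length `>= min_len` is reported.
#'
#' @param genome an [annotated_genome()].
#' @param min_len minimum repeat arm length to report (default 1000 bp, the
#'   scale of the canonical plastid IR; must be >= 100).
#' @param k seed length (default 25).
#' @return list with `found`, `length`, and when found `arm1`/`arm2`
#'   (0-based half-open intervals of the two arms).
#' @export
detect_inverted_repeat <- function(genome, min_len = 1000L, k = 25L) {
  stopifnot(min_len >= 100L, k >= 10L)
  S <- genome$sequence
  L <- nchar(S)
  none <- list(found = FALSE, length = 0L)
  if (L < 2L * min_len) return(none)
  rc <- revcomp(S)
  # non-overlapping seeds from S every k bp; any repeat arm >= min_len
  # contains at least one full seed, so none is missed
  seed_starts <- seq(1L, L - k + 1L, by = k)
  seeds <- substring(S, seed_starts, seed_starts + k - 1L)
  rc_kmers <- substring(rc, 1L:(L - k + 1L), k:L)
  hit <- match(rc_kmers, seeds)                 # rc position -> seed index
  hp <- which(!is.na(hit))
  best <- none
  s_chars <- strsplit(S, "", fixed = TRUE)[[1L]]
  rc_chars <- strsplit(rc, "", fixed = TRUE)[[1L]]
  for (j in hp) {
    i <- seed_starts[hit[j]]                    # position in S (1-based)
    # extend the exact match S[i..] == rc[j..] in both directions
    a <- 0L
    while (i - a - 1L >= 1L && j - a - 1L >= 1L &&
           s_chars[i - a - 1L] == rc_chars[j - a - 1L]) a <- a + 1L
    b <- 0L
    while (i + k + b <= L && j + k + b <= L &&
           s_chars[i + k + b] == rc_chars[j + k + b]) b <- b + 1L
    len <- k + a + b
    if (len < min_len || len <= best$length) next
    arm1 <- c(i - a - 1L, i + k + b - 1L)       # 0-based half-open in S
    # rc interval back to S coordinates: rc position p == S position L-p+1
    arm2 <- c(L - (j + k + b - 1L), L - (j - a) + 1L)
    lo <- if (arm1[1L] <= arm2[1L]) arm1 else arm2
    hi <- if (arm1[1L] <= arm2[1L]) arm2 else arm1
    if (hi[1L] < lo[2L]) next                   # self-overlapping palindrome
    best <- list(found = TRUE, length = len, arm1 = lo, arm2 = hi)
  }
  best
}
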