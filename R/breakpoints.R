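# Deletion-breakpoint identification and junction characterization:
# maximal runs of reference genes absent from a reduced genome, the fused
# junctions in the reduced genome, their AT content and tRNA adjacency.

#' Find deletion-breakpoint regions in a reduced genome
#'
#' Walks the reference circle (all gene types, tRNAs included, since lost
#' tRNAs participate in deletion runs); maximal runs of consecutive genes
#' absent from the reduced genome become breakpoint regions, labelled BP1,
#' BP2, ... in reference order. For each region the retained flanking genes
#' are located in the reduced genome; the junction window is the intergenic
#' sequence between them, extended symmetrically into the flanks to a
#' minimum width `window` when the gap is shorter. A region is `clean`
#' when its flanks are directly adjacent (no intervening gene) in the
#' reduced genome.
#'
#' @param reference,reduced [annotated_genome()] objects.
#' @param window minimum junction window width in bp (default 100).
#' @return data.frame of class `breakpoint_regions`, one row per region:
#'   `bp_id`, `missing_genes` (comma-joined, reference order), `n_missing`,
#'   `left_flank`, `right_flank`, `deleted_span_bp` (reference distance from
#'   end of left flank to start of right flank), `junction_start`,
#'   `junction_end` (reduced-genome coordinates of the inter-flank gap),
#'   `junction_len`, `junction_seq`, `junction_at_percent`, `trna_adjacent`,
#'   `clean`. Empty (0-row) when nothing is missing.
#' @export
find_breakpoints <- function(reference, reduced, window = 100L) {
  fr <- reference$features[!duplicated(reference$features$name), , drop = FALSE]
  fr <- fr[order(fr$start), , drop = FALSE]
  red_names <- unique(reduced$features$name)
  missing <- !(fr$name %in% red_names)
  empty <- data.frame(bp_id = character(0), missing_genes = character(0),
                      n_missing = integer(0), left_flank = character(0),
                      right_flank = character(0), deleted_span_bp = integer(0),
                      junction_start = integer(0), junction_end = integer(0),
                      junction_len = integer(0), junction_seq = character(0),
                      junction_at_percent = numeric(0),
                      trna_adjacent = logical(0), clean = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("breakpoint_regions", "data.frame")
  n <- nrow(fr)
  if (!any(missing)) return(empty)
  if (all(missing)) stop("every reference gene is missing from the reduced genome")

  # rotate the gene list so index 1 is retained; runs are then interior
  first_ret <- which(!missing)[1L]
  ord <- c(seq(first_ret, n), if (first_ret > 1L) seq_len(first_ret - 1L))
  fr2 <- fr[ord, , drop = FALSE]
  miss2 <- missing[ord]
  r <- rle(miss2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  Lr <- reference$length

  rows <- lapply(seq_along(runs), function(kk) {
    k <- runs[kk]
    i1 <- starts[k]; i2 <- ends[k]
    genes <- fr2$name[i1:i2]
    left <- fr2[i1 - 1L, ]                               # retained by rotation
    right <- fr2[if (i2 == nrow(fr2)) 1L else i2 + 1L, ] # circular successor
    span <- (right$start - left$end) %% Lr
    if (span == 0L) span <- Lr                           # flanks abut over the run
    jn <- junction_window(reduced, left$name, right$name, window)
    data.frame(bp_id = NA_character_,
               missing_genes = paste(genes, collapse = ","),
               n_missing = length(genes),
               left_flank = left$name, right_flank = right$name,
               deleted_span_bp = span,
               junction_start = jn$gap_start, junction_end = jn$gap_end,
               junction_len = jn$gap_len, junction_seq = jn$window_seq,
               junction_at_percent = at_percent(jn$window_seq),
               trna_adjacent = left$gene_type == "tRNA" || right$gene_type == "tRNA",
               clean = jn$clean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # stable labels in reference-coordinate order of the run start
  ref_pos <- fr2$start[starts[runs]]
  out <- out[order(ref_pos), , drop = FALSE]
  out$bp_id <- sprintf("BP%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("breakpoint_regions", "data.frame")
  out
}

# Intergenic gap between two named genes in the reduced genome, walking the
# circle from the end of `left` to the start of `right`; the window is
# extended symmetrically into the flanks up to `min_window` bp.
junction_window <- function(reduced, left, right, min_window = 100L) {
  f <- reduced$features
  il <- which(f$name == left)[1L]
  ir <- which(f$name == right)[1L]
  if (is.na(il) || is.na(ir)) {
    stop("flank gene absent from reduced genome: ", if (is.na(il)) left else right)
  }
  L <- reduced$length
  fl <- f[il, ]; frt <- f[ir, ]
  gap_start <- fl$end %% L
  gap_end <- frt$start
  gap_len <- (gap_end - gap_start) %% L
  # clean junction: no other feature starts strictly inside the gap
  others <- f$start[-c(il, ir)]
  inside <- if (gap_len == 0L) FALSE else {
    if (gap_end > gap_start) any(others >= gap_start & others < gap_end)
    else any(others >= gap_start | others < gap_end)
  }
  half <- ceiling(pmax(0L, min_window - gap_len) / 2)
  w_start <- (gap_start - half) %% L
  w_end <- (gap_end + half) %% L
  if (w_end == 0L) w_end <- L
  wseq <- circular_substr(reduced$sequence, w_start,
                          if (w_end == w_start) w_start + 1L else w_end)
  list(gap_start = gap_start, gap_end = gap_end, gap_len = gap_len,
       window_seq = wseq, clean = !inside)
}

#' Aggregate junction report for breakpoint regions
#'
#' @param regions output of [find_breakpoints()].
#' @return list with the per-region table plus `n_regions`,
#'   `mean_at_percent` (mean junction AT% over regions), `n_trna_adjacent`,
#'   `span_range_bp`.
#' @export
junction_report <- function(regions) {
  list(regions = regions,
       n_regions = nrow(regions),
       mean_at_percent = if (nrow(regions)) mean(regions$junction_at_percent) else NaN,
       n_trna_adjacent = sum(regions$trna_adjacent),
       span_range_bp = if (nrow(regions)) range(regions$deleted_span_bp) else c(NA, NA))
}

#' Pairwise sequence similarity among junction windows
#'
#' Globally aligns every pair of junction windows and flags pairs whose
#' identity exceeds a threshold, as a screen for shared sequence at
#' deletion junctions (independent junctions are expected to show none).
#'
#' @param regions output of [find_breakpoints()].
#' @param min_identity identity threshold for flagging (default 0.70).
#' @param min_len minimum window length for a pair to be testable
#'   (default 30 bp).
#' @return data.frame of flagged pairs (`bp_a`, `bp_b`, `identity`);
#'   0 rows when no pair is similar or fewer than two regions exist.
#' @export
junction_similarity <- function(regions, min_identity = 0.70, min_len = 30L) {
  empty <- data.frame(bp_a = character(0), bp_b = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(regions)
  if (n < 2L) return(empty)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sa <- regions$junction_seq[i]
      sb <- regions$junction_seq[j]
      if (nchar(sa) < min_len || nchar(sb) < min_len) next
      idn <- alignment_identity(align_nucleotide(sa, sb))$identity
      if (idn > min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          bp_a = regions$bp_id[i], bp_b = regions$bp_id[j],
          identity = idn, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) empty else do.call(rbind, rows)
}
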