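# Name-based gene-content comparison and pairwise identity profiles.

#' Compare gene content of two genomes by normalized name
#'
#' Set algebra on distinct normalized gene names (tRNAs keep their anticodon,
#' so isoacceptors are distinct). Duplicate copies within one genome (e.g.
#' genes duplicated inside an inverted repeat) collapse to one name for the
#' set accounting but are reported separately.
#'
#' @param A,B [annotated_genome()] objects.
#' @return list of class `content_comparison`: `genomes`, `shared`,
#'   `only_in_A`, `only_in_B` (character vectors of names), `nA`, `nB`,
#'   `n_shared`, `lost_by_category` (losses from A per functional category),
#'   `duplicated_in_A`, `duplicated_in_B`.
#' @export
compare_content <- function(A, B) {
  nmA <- A$features$name
  nmB <- B$features$name
  uA <- unique(nmA)
  uB <- unique(nmB)
  shared <- intersect(uA, uB)
  onlyA <- setdiff(uA, uB)
  onlyB <- setdiff(uB, uA)
  catA <- stats::setNames(A$features$category, A$features$name)
  lost_cat <- table(factor(unname(catA[onlyA]), levels = GENE_CATEGORIES))
  out <- list(genomes = c(A$id, B$id), shared = sort(shared),
              only_in_A = sort(onlyA), only_in_B = sort(onlyB),
              nA = length(uA), nB = length(uB), n_shared = length(shared),
              lost_by_category = lost_cat,
              duplicated_in_A = sort(unique(nmA[duplicated(nmA)])),
              duplicated_in_B = sort(unique(nmB[duplicated(nmB)])))
  class(out) <- "content_comparison"
  out
}

#' @export
print.content_comparison <- function(x, ...) {
  cat(sprintf("Gene content %s vs %s: %d vs %d distinct genes, %d shared, %d lost from %s, %d unique to %s\n",
              x$genomes[1], x$genomes[2], x$nA, x$nB, x$n_shared,
              length(x$only_in_A), x$genomes[2], length(x$only_in_B), x$genomes[2]))
  invisible(x)
}

# Global pairwise nucleotide alignment used for identity statistics.
# Scoring: match +1, mismatch -1, gap open 2, gap extend 1.
align_nucleotide <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                substitutionMatrix = mat, gapOpening = 2,
                                gapExtension = 1, type = "global")
}

# identity = matching columns / alignment columns, plus per-window identity
# over fixed-width windows of alignment columns
alignment_identity <- function(aln, window = 100L) {
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ncol <- length(pa)
  match_col <- pa == sa & pa != "-"
  idx <- ceiling(seq_len(ncol) / window)
  win_id <- tapply(match_col, idx, mean)
  list(identity = sum(match_col) / ncol,
       window_identity = as.numeric(win_id),
       n_columns = ncol)
}

#' Per-gene identity profile between two genomes
#'
#' For each shared gene, globally aligns the two coding sequences and the two
#' 5' upstream windows (default 50 bp upstream of the start codon) and
#' reports identity (matches / alignment columns) plus the mean identity over
#' fixed windows of alignment columns. The gene class is recorded so
#' conservation can be contrasted across tRNA/rRNA/protein genes.
#'
#' @param A,B [annotated_genome()] objects.
#' @param window window width in alignment columns (default 100).
#' @param upstream_bp upstream window in bp (default 50).
#' @return data.frame with one row per shared gene: `gene`, `gene_type`,
#'   `category`, `identity`, `window_mean_identity`, `upstream_identity`.
#' @export
gene_identity_profile <- function(A, B, window = 100L, upstream_bp = 50L) {
  cc <- compare_content(A, B)
  if (cc$n_shared == 0L) stop("no shared genes between ", A$id, " and ", B$id)
  rows <- lapply(cc$shared, function(g) {
    xa <- tryCatch(extract_cds_and_upstream(A, g, upstream_bp), error = function(e) NULL)
    xb <- tryCatch(extract_cds_and_upstream(B, g, upstream_bp), error = function(e) NULL)
    if (is.null(xa) || is.null(xb)) {
      warning("gene skipped (missing in one genome): ", g)
      return(NULL)
    }
    ft <- A$features[A$features$name == g, ][1L, ]
    gi <- alignment_identity(align_nucleotide(xa$cds, xb$cds), window)
    ui <- if (upstream_bp > 0L) {
      alignment_identity(align_nucleotide(xa$upstream, xb$upstream), window)$identity
    } else NA_real_
    data.frame(gene = g, gene_type = ft$gene_type, category = ft$category,
               identity = gi$identity,
               window_mean_identity = mean(gi$window_identity),
               upstream_identity = ui, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}
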