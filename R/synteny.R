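# Circular signed gene-order comparison: shared-gene permutations,
# conserved adjacencies, collinear blocks, breakpoint distance, and
# all-pairs similarity matrices.
#
# Conserved adjacencies are counted on unsigned gene adjacency: a pair of
# genes scores when it is adjacent on both circles, under either reading
# direction. Orientation enters the collinear-block structure (blocks are
# maximal chains of conserved adjacencies) and the reported
# same-orientation fraction, not the adjacency count; this keeps the
# statistic's null expectation for random signed circular permutations at
# 2/(n-1) and makes it reflection-invariant by construction.

#' Signed permutation of shared genes around the circle
#'
#' @param genome an [annotated_genome()].
#' @param shared character vector of gene names to keep (typically from
#'   [compare_content()]).
#' @param include_tRNA keep tRNA genes (default FALSE: gene-order comparison
#'   conventionally uses protein-coding and rRNA genes).
#' @return object of class `signed_permutation`: list with `id`, `name`
#'   (ordered by start position around the circle) and `sign` (+1/-1 from
#'   strand). Duplicated shared names (inverted-repeat copies) keep the
#'   first occurrence, with a warning.
#' @export
to_signed_permutation <- function(genome, shared = NULL, include_tRNA = FALSE) {
  f <- genome$features
  if (!include_tRNA) f <- f[f$gene_type != "tRNA", , drop = FALSE]
  if (!is.null(shared)) f <- f[f$name %in% shared, , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  if (anyDuplicated(f$name)) {
    warning(genome$id, ": duplicated shared gene name(s) collapsed to first occurrence: ",
            paste(unique(f$name[duplicated(f$name)]), collapse = ", "))
    f <- f[!duplicated(f$name), , drop = FALSE]
  }
  structure(list(id = genome$id, name = f$name, sign = as.integer(f$strand)),
            class = "signed_permutation")
}

#' Canonicalize a signed permutation
#'
#' Optionally reflects (reverse order, flip signs), then rotates so the
#' anchor gene comes first. Canonicalization never changes any synteny
#' statistic against any partner; it only fixes the reading frame for
#' display, the way published maps are redrawn to start at a chosen gene.
#'
#' @param P a `signed_permutation`.
#' @param anchor gene name to rotate to the front.
#' @param reflect reflect before rotating (default FALSE).
#' @return canonicalized `signed_permutation`.
#' @export
canonicalize <- function(P, anchor, reflect = FALSE) {
  stopifnot(inherits(P, "signed_permutation"))
  nm <- P$name
  sg <- P$sign
  if (reflect) {
    nm <- rev(nm)
    sg <- -rev(sg)
  }
  i <- match(anchor, nm)
  if (is.na(i)) stop("anchor gene not in permutation: ", anchor)
  ord <- c(seq(i, length(nm)), if (i > 1L) seq_len(i - 1L))
  structure(list(id = P$id, name = nm[ord], sign = sg[ord]),
            class = "signed_permutation")
}

# Unsigned circular adjacency set: canonical "x|y" keys with x < y.
adjacency_keys <- function(nm) {
  n <- length(nm)
  if (n < 2L) return(character(0))
  nxt <- c(nm[-1L], nm[1L])
  paste(pmin(nm, nxt), pmax(nm, nxt), sep = "|")
}

#' Compare gene order of two signed permutations
#'
#' Core synteny statistic on two circles restricted to their shared genes:
#' `conserved_adjacencies` (gene pairs adjacent on both circles),
#' `adjacency_fraction` (conserved / n_shared, a circle of n genes having n
#' adjacencies), collinear blocks (maximal chains of conserved adjacencies),
#' and `breakpoint_distance = n_shared - conserved_adjacencies`. The
#' orientation agreement of B relative to A is reported for the better of
#' the two reading directions of B.
#'
#' @param pa,pb `signed_permutation` objects over the same gene set.
#' @return list of class `synteny_result`.
#' @export
compare_perms <- function(pa, pb) {
  common <- intersect(pa$name, pb$name)
  keep_a <- pa$name %in% common
  keep_b <- pb$name %in% common
  nmA <- pa$name[keep_a]; sgA <- pa$sign[keep_a]
  nmB <- pb$name[keep_b]; sgB <- pb$sign[keep_b]
  n <- length(nmA)
  out <- list(genomes = c(pa$id, pb$id), n_shared = n)
  if (n < 2L) {
    out$conserved_adjacencies <- NA_integer_
    out$adjacency_fraction <- NA_real_
    out$n_blocks <- n
    out$breakpoint_distance <- NA_integer_
    out$orientation_agreement <- NA_real_
    out$degenerate <- TRUE
    class(out) <- "synteny_result"
    return(out)
  }
  keyA <- adjacency_keys(nmA)
  keyB <- adjacency_keys(nmB)
  conserved <- keyA %in% keyB
  cons <- sum(conserved)
  out$conserved_adjacencies <- cons
  out$adjacency_fraction <- cons / n
  out$breakpoint_distance <- n - cons
  # blocks: maximal chains of conserved adjacencies around circle A
  out$n_blocks <- if (cons == n) 1L else n - cons
  # orientation agreement under the better reading direction of B
  sB <- stats::setNames(sgB, nmB)
  agree_as_read <- mean(sB[nmA] == sgA)
  out$orientation_agreement <- max(agree_as_read, 1 - agree_as_read)
  out$degenerate <- FALSE
  class(out) <- "synteny_result"
  out
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf("Synteny %s vs %s: %d shared genes, %s conserved adjacencies (fraction %s), %s blocks, breakpoint distance %s\n",
              x$genomes[1], x$genomes[2], x$n_shared,
              format(x$conserved_adjacencies), format(round(x$adjacency_fraction, 3)),
              format(x$n_blocks), format(x$breakpoint_distance)))
  invisible(x)
}

#' Compare gene order of two genomes
#'
#' Restricts both genomes to their shared (normalized-name) genes, builds
#' signed circular permutations, and computes the synteny statistics of
#' [compare_perms()]. All statistics are invariant under rotation and
#' reflection of either genome.
#'
#' @param A,B [annotated_genome()] objects.
#' @param include_tRNA include tRNA genes (default FALSE).
#' @return a `synteny_result`.
#' @export
compare_order <- function(A, B, include_tRNA = FALSE) {
  cc <- compare_content(A, B)
  pa <- to_signed_permutation(A, cc$shared, include_tRNA = include_tRNA)
  pb <- to_signed_permutation(B, cc$shared, include_tRNA = include_tRNA)
  compare_perms(pa, pb)
}

#' All-pairs synteny matrices
#'
#' @param genomes list of [annotated_genome()] objects.
#' @param include_tRNA include tRNA genes (default FALSE).
#' @return list with symmetric matrices `adjacency_fraction` (diagonal 1)
#'   and `breakpoint_distance` (diagonal 0); pairs with fewer than 2 shared
#'   genes are NA.
#' @export
pairwise_matrix <- function(genomes, include_tRNA = FALSE) {
  stopifnot(length(genomes) >= 2L)
  ids <- vapply(genomes, function(g) g$id, character(1))
  m <- length(genomes)
  af <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  bd <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  diag(af) <- 1
  diag(bd) <- 0
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      sr <- compare_order(genomes[[i]], genomes[[j]], include_tRNA = include_tRNA)
      af[i, j] <- af[j, i] <- sr$adjacency_fraction
      bd[i, j] <- bd[j, i] <- sr$breakpoint_distance
    }
  }
  list(adjacency_fraction = af, breakpoint_distance = bd)
}

#' Random signed circular permutation
#'
#' Null-model generator: uniform arrangement of `genes` around a circle with
#' independent uniform signs. Used for the adjacency-fraction null, whose
#' expectation for n genes is 2/(n-1).
#'
#' @param genes character vector of gene names.
#' @param id label for the permutation.
#' @return a `signed_permutation`.
#' @export
random_signed_perm <- function(genes, id = "random") {
  structure(list(id = id, name = sample(genes),
                 sign = sample(c(-1L, 1L), length(genes), replace = TRUE)),
            class = "signed_permutation")
}
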