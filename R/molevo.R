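# Protein-guided codon alignment, Nei-Gojobori (1986) Ks/Ka estimation with
# Jukes-Cantor correction, and the generation-time molecular clock.

#' Protein-guided codon alignment of two coding sequences
#'
#' Translates both CDS under table 11, globally aligns the proteins
#' (BLOSUM62, gap open 11 / extend 1), and back-translates the protein
#' alignment to codon columns, so gaps occur only in whole-codon units.
#' Terminal stop codons are trimmed first; a length not divisible by 3 is
#' trimmed to the largest codon multiple with a warning; an internal stop
#' rejects the gene.
#'
#' @param cdsA,cdsB coding sequences (nucleotide strings).
#' @param gene gene name carried through to results.
#' @return object of class `codon_alignment`: `gene`, `codons_a`,
#'   `codons_b` (character vectors of codon columns, `"---"` = gap),
#'   `n_codons_compared` (columns where both are non-gap), `rejected`
#'   (logical), `reason`.
#' @export
align_codons <- function(cdsA, cdsB, gene = NA_character_) {
  prep <- function(cds, label) {
    cds <- toupper(cds)
    extra <- nchar(cds) %% 3L
    if (extra != 0L) {
      warning(gene, " ", label, ": length not divisible by 3, trimming ",
              extra, " nt")
      cds <- substr(cds, 1L, nchar(cds) - extra)
    }
    cods <- split_codons(cds)
    gc <- genetic_code_11()
    aa <- unname(gc[cods])
    aa[is.na(aa)] <- "X"
    if (length(aa) > 0L && aa[length(aa)] == "*") {
      cods <- cods[-length(cods)]
      aa <- aa[-length(aa)]
    }
    list(cods = cods, aa = aa)
  }
  a <- prep(cdsA, "A")
  b <- prep(cdsB, "B")
  rejected <- function(reason) {
    structure(list(gene = gene, codons_a = character(0), codons_b = character(0),
                   n_codons_compared = 0L, rejected = TRUE, reason = reason),
              class = "codon_alignment")
  }
  if (any(a$aa == "*") || any(b$aa == "*")) return(rejected("internal stop codon"))
  if (length(a$cods) == 0L || length(b$cods) == 0L) return(rejected("empty CDS"))

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(a$aa, collapse = "")),
    Biostrings::AAString(paste(b$aa, collapse = "")),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ca <- character(length(pa))
  cb <- character(length(sa))
  ia <- 0L; ib <- 0L
  for (i in seq_along(pa)) {
    if (pa[i] == "-") ca[i] <- "---" else { ia <- ia + 1L; ca[i] <- a$cods[ia] }
    if (sa[i] == "-") cb[i] <- "---" else { ib <- ib + 1L; cb[i] <- b$cods[ib] }
  }
  structure(list(gene = gene, codons_a = ca, codons_b = cb,
                 n_codons_compared = sum(ca != "---" & cb != "---"),
                 rejected = FALSE, reason = NA_character_),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) Ks/Ka estimation on a codon alignment
#'
#' Counting estimator: synonymous/non-synonymous site counts are obtained by
#' enumerating the three single-nucleotide neighbours of each codon position
#' under table 11 (neighbours that are stop codons are excluded from the
#' denominator) and averaging the two sequences; differences are counted by
#' averaging over all minimal substitution pathways between differing codons
#' (pathways through stop codons excluded). The proportions `pS = Sd/S` and
#' `pN = Nd/N` are Jukes-Cantor corrected; `p >= 3/4` leaves the distance
#' undefined with the `saturated` flag set. The flag is also set when a
#' defined Ks reaches 1, the conventional saturation caution for plastid
#' comparisons.
#'
#' @param alignment a `codon_alignment` from [align_codons()], or a list
#'   with `codons_a`/`codons_b` character vectors of equal length.
#' @return object of class `kska_result`: `gene`, `n_codons_compared`, `S`,
#'   `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`, `saturated`.
#' @export
ng86 <- function(alignment) {
  if (isTRUE(alignment$rejected)) {
    stop("cannot estimate Ks/Ka on a rejected alignment (", alignment$reason, ")")
  }
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  stopifnot(length(ca) == length(cb))
  tb <- ng86_tables()
  sense <- sense_codons()
  keep <- ca %in% sense & cb %in% sense
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  if (n < 1L) stop("no comparable codon columns")
  S <- (sum(tb$sites[ca]) + sum(tb$sites[cb])) / 2
  N <- 3 * n - S
  Sd <- sum(tb$SD[cbind(ca, cb)])
  Nd <- sum(tb$ND[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(Ks) && Ks >= 1)
  structure(list(gene = alignment$gene, n_codons_compared = n,
                 S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, omega = omega, saturated = saturated),
            class = "kska_result")
}

#' @export
print.kska_result <- function(x, ...) {
  cat(sprintf("%s: %d codons | S %.2f N %.2f | Sd %.2f Nd %.2f | Ks %s Ka %s%s\n",
              x$gene, x$n_codons_compared, x$S, x$N, x$Sd, x$Nd,
              format(round(x$Ks, 4)), format(round(x$Ka, 4)),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Per-gene Ks/Ka table for the shared protein genes of two genomes
#'
#' Extracts each shared protein-coding gene from both genomes, builds the
#' protein-guided codon alignment and applies [ng86()]. Genes rejected at
#' alignment (internal stops) are reported with NA estimates.
#'
#' @param A,B [annotated_genome()] objects.
#' @return data.frame: `gene`, `n_codons`, `S`, `N`, `Sd`, `Nd`, `Ks`, `Ka`,
#'   `omega`, `saturated`, `rejected`.
#' @export
kska_table <- function(A, B) {
  cc <- compare_content(A, B)
  shared_prot <- intersect(cc$shared,
                           A$features$name[A$features$gene_type == "protein"])
  rows <- lapply(sort(shared_prot), function(g) {
    na_row <- data.frame(gene = g, n_codons = NA_integer_, S = NA_real_,
                         N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                         Ks = NA_real_, Ka = NA_real_, omega = NA_real_,
                         saturated = NA, rejected = TRUE,
                         stringsAsFactors = FALSE)
    aln <- align_codons(extract_cds_and_upstream(A, g, 0L)$cds,
                        extract_cds_and_upstream(B, g, 0L)$cds, gene = g)
    if (aln$rejected) {
      warning("gene rejected: ", g, " (", aln$reason, ")")
      return(na_row)
    }
    r <- ng86(aln)
    data.frame(gene = g, n_codons = r$n_codons_compared, S = r$S, N = r$N,
               Sd = r$Sd, Nd = r$Nd, Ks = r$Ks, Ka = r$Ka, omega = r$omega,
               saturated = r$saturated, rejected = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average Ks over genes
#'
#' Unweighted per-gene mean by default, or a synonymous-site-weighted mean.
#' Genes whose Jukes-Cantor correction is undefined (pS >= 3/4) are excluded
#' and counted in `n_excluded`; genes with a defined Ks >= 1 are retained
#' (the saturation flag on such genes is advisory).
#'
#' @param kska data.frame from [kska_table()], or list of `kska_result`.
#' @param policy `"unweighted"` (default) or `"site_weighted"`.
#' @return list: `mean_Ks`, `n_genes`, `n_excluded`, `policy`.
#' @export
mean_ks <- function(kska, policy = c("unweighted", "site_weighted")) {
  policy <- match.arg(policy)
  if (!is.data.frame(kska)) {
    kska <- do.call(rbind, lapply(kska, function(r) {
      data.frame(gene = r$gene, Ks = r$Ks, S = r$S)
    }))
  }
  ok <- !is.na(kska$Ks)
  if (!any(ok)) stop("all genes saturated or undefined; no Ks to average")
  v <- kska$Ks[ok]
  m <- if (policy == "unweighted") mean(v) else {
    stats::weighted.mean(v, kska$S[ok])
  }
  list(mean_Ks = m, n_genes = sum(ok), n_excluded = sum(!ok), policy = policy)
}

#' Generation-based divergence-time estimate
#'
#' Converts a mean synonymous distance into generations via a per-generation
#' substitution rate, and into years via lifestyle-specific generation
#' times: `n_generations = mean_Ks / mu` and
#' `T[lifestyle] = n_generations * generation_time`. The convention divides
#' by `mu`, not `2*mu`; set `per_lineage = TRUE` to halve the estimate if
#' the divergence is to be split over the two descendant lineages.
#'
#' @param mean_Ks average synonymous substitutions per synonymous site.
#' @param mu substitution rate per site per generation (default 3.23e-10,
#'   the measured nuclear rate of a unicellular green alga, conventionally
#'   applied to the plastid as well).
#' @param generation_times named numeric vector of years per generation
#'   (defaults: heterotroph 24 h = 0.00274 y, autotroph 72 h = 0.008219 y).
#' @param per_lineage halve the generation count (default FALSE).
#' @return list of class `divergence_estimate`: `mean_Ks`, `mu`,
#'   `n_generations`, `generation_times`, `T_years` (named), `T_low`,
#'   `T_high`.
#' @export
#' @examples
#' divergence_time(0.816)  # ~2.5e9 generations, ~7-21 Myr window
divergence_time <- function(mean_Ks, mu = 3.23e-10,
                            generation_times = c(heterotroph = 0.00274,
                                                 autotroph = 0.008219),
                            per_lineage = FALSE) {
  if (mu <= 0) stop("mu must be positive")
  if (mean_Ks < 0) stop("mean_Ks must be non-negative")
  ngen <- mean_Ks / mu
  if (per_lineage) ngen <- ngen / 2
  Ty <- ngen * generation_times
  structure(list(mean_Ks = mean_Ks, mu = mu, n_generations = ngen,
                 generation_times = generation_times, T_years = Ty,
                 T_low = min(Ty), T_high = max(Ty)),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("mean Ks %.3f, mu %.3g/generation -> %.3g generations; divergence %.2g-%.2g Myr\n",
              x$mean_Ks, x$mu, x$n_generations, x$T_low / 1e6, x$T_high / 1e6))
  invisible(x)
}
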