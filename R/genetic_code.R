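# Genetic code (translation table 11, bacterial/plastid) and the
# precomputed per-codon site and pathway tables used by the NG86 estimator
# and by the codon-substitution simulator.

.plastidcomp_env <- new.env(parent = emptyenv())

#' The plastid genetic code (NCBI translation table 11)
#'
#' @return named character vector mapping all 64 codons to one-letter amino
#'   acids, with `"*"` for stop codons.
#' @export
genetic_code_11 <- function() {
  if (is.null(.plastidcomp_env$gc11)) {
    .plastidcomp_env$gc11 <- Biostrings::getGeneticCode("11")
  }
  .plastidcomp_env$gc11
}

#' Translate a coding sequence under translation table 11
#'
#' @param cds nucleotide string; length must be a multiple of 3.
#' @return one-letter amino-acid string (`*` = stop).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  cods <- split_codons(cds)
  gc <- genetic_code_11()
  aa <- gc[cods]
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  paste(aa, collapse = "")
}

# nucleotide string -> character vector of codons
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

sense_codons <- function() {
  gc <- genetic_code_11()
  names(gc)[gc != "*"]
}

# Per-codon NG86 synonymous site count. For each of the three positions the
# three single-nucleotide neighbours are enumerated; neighbours that are stop
# codons are excluded from the denominator, so each position contributes
# (#synonymous valid changes / #valid changes) synonymous sites and the
# complement non-synonymous sites; positions always sum to 1 site.
ng86_codon_sites <- function(codon, gc = genetic_code_11()) {
  aa <- gc[[codon]]
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    cur <- substr(codon, p, p)
    neigh <- vapply(setdiff(nts, cur), function(nt) {
      x <- codon
      substr(x, p, p) <- nt
      x
    }, character(1))
    ok <- gc[neigh] != "*"
    nvalid <- sum(ok)
    if (nvalid > 0) s <- s + sum(gc[neigh][ok] == aa) / nvalid
  }
  s
}

# Pathway-averaged synonymous/non-synonymous difference counts between two
# sense codons. All orderings of the differing positions are enumerated;
# pathways passing through a stop codon are excluded; if every pathway is
# blocked (does not occur between sense codons under table 11, but kept for
# safety) all pathways are used. Returns c(sd, nd).
ng86_pair_diffs <- function(c1, c2, gc = genetic_code_11()) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- switch(k,
    list(pos),
    list(pos, rev(pos)),
    {
      pm <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(seq_len(6), function(i) pos[pm[i, ]])
    })
  walk <- function(ord) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && nxt != c2) return(NULL)  # blocked pathway
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(orders, walk)
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) {
    res <- lapply(orders, function(ord) {  # fallback: count through stops
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
    keep <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[keep])
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Cached lookup tables over all codons: $sites named numeric (synonymous
# sites per sense codon), $SD/$ND 64x64 pathway-averaged difference matrices
# (NA where either codon is a stop or contains ambiguity).
ng86_tables <- function() {
  tb <- .plastidcomp_env$ng86_tables
  if (!is.null(tb)) return(tb)
  gc <- genetic_code_11()
  codons <- names(gc)
  sense <- sense_codons()
  sites <- stats::setNames(rep(NA_real_, 64L), codons)
  for (cd in sense) sites[[cd]] <- ng86_codon_sites(cd, gc)
  SD <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  ND <- SD
  for (c1 in sense) {
    for (c2 in sense) {
      d <- ng86_pair_diffs(c1, c2, gc)
      SD[c1, c2] <- d[["sd"]]
      ND[c1, c2] <- d[["nd"]]
    }
  }
  tb <- list(sites = sites, SD = SD, ND = ND)
  .plastidcomp_env$ng86_tables <- tb
  tb
}

# Integer-indexed variants of the NG86 tables for the hot simulation loop:
# codon indices 1..64, neighbour array NEI[codon, position, nt], stop/amino
# lookups, and SD/ND matrices with stop rows zeroed (never indexed by the
# proposal loop, which rejects stop codons first).
ng86_itables <- function() {
  it <- .plastidcomp_env$ng86_itables
  if (!is.null(it)) return(it)
  tb <- ng86_tables()
  gc <- genetic_code_11()
  codons <- names(gc)
  nts <- c("A", "C", "G", "T")
  NEI <- array(0L, dim = c(64L, 3L, 4L))
  for (ci in seq_len(64L)) {
    for (p in 1:3) {
      for (t in 1:4) {
        x <- codons[ci]
        substr(x, p, p) <- nts[t]
        NEI[ci, p, t] <- match(x, codons)
      }
    }
  }
  SD <- tb$SD; SD[is.na(SD)] <- 0
  ND <- tb$ND; ND[is.na(ND)] <- 0
  SITES <- tb$sites; SITES[is.na(SITES)] <- 0
  it <- list(codons = codons, NEI = NEI, STOP = unname(gc == "*"),
             AA = match(gc, unique(gc)), SITES = unname(SITES),
             SD = unname(SD), ND = unname(ND))
  .plastidcomp_env$ng86_itables <- it
  it
}

# Jukes-Cantor multiple-hit correction of a proportion of differences.
# Undefined (NA) at or beyond the p = 3/4 saturation bound.
jc_correct <- function(p) {
  ifelse(!is.na(p) & p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

# inverse: expected proportion of sites differing at JC distance d
jc_p_from_d <- function(d) 0.75 * (1 - exp(-4 * d / 3))
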