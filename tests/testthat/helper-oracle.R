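# Independent oracles, written separately from the package implementation
# and kept deliberately naive: recursive pathway enumeration for NG86,
# plain-loop adjacency counting for synteny, k-mer set intersection for
# inverted repeats.

oracle_gc <- Biostrings::getGeneticCode("11")

# synonymous sites of one codon: per position, fraction of non-stop
# single-nucleotide changes that preserve the amino acid
oracle_sites <- function(codon) {
  aa <- oracle_gc[[codon]]
  total <- 0
  for (p in 1:3) {
    syn <- 0
    valid <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (nt == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- nt
      if (oracle_gc[[alt]] == "*") next
      valid <- valid + 1
      if (oracle_gc[[alt]] == aa) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# recursive depth-first enumeration of all substitution orders between two
# codons; paths through stops are dropped; returns average c(sd, nd) over
# surviving paths (all paths if every one is blocked)
oracle_diffs <- function(c1, c2) {
  recurse <- function(cur, allow_stops) {
    remaining <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(remaining) == 0) return(list(c(0, 0)))
    paths <- list()
    for (p in remaining) {
      step <- cur
      substr(step, p, p) <- substr(c2, p, p)
      if (!allow_stops && oracle_gc[[step]] == "*" && step != c2) next
      inc <- if (oracle_gc[[step]] == oracle_gc[[cur]]) c(1, 0) else c(0, 1)
      for (tail in recurse(step, allow_stops)) {
        paths[[length(paths) + 1]] <- inc + tail
      }
    }
    paths
  }
  paths <- recurse(c1, allow_stops = FALSE)
  if (length(paths) == 0) paths <- recurse(c1, allow_stops = TRUE)
  colMeans(do.call(rbind, paths))
}

# full oracle estimate on paired codon vectors (no gaps, sense codons only)
oracle_ng86 <- function(codsA, codsB) {
  keep <- oracle_gc[codsA] != "*" & oracle_gc[codsB] != "*"
  codsA <- codsA[keep]
  codsB <- codsB[keep]
  S <- mean(c(sum(vapply(codsA, oracle_sites, 0)),
              sum(vapply(codsB, oracle_sites, 0))))
  N <- 3 * length(codsA) - S
  d <- rowSums(vapply(seq_along(codsA),
                      function(i) oracle_diffs(codsA[i], codsB[i]),
                      numeric(2)))
  pS <- d[1] / S
  pN <- d[2] / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = d[1], Nd = d[2], pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# number of unsigned gene adjacencies shared by two circular orders,
# counted by scanning every neighbouring pair of the first circle and
# searching the second circle's neighbour lists
oracle_conserved_adjacencies <- function(orderA, orderB) {
  n <- length(orderA)
  neighB <- list()
  m <- length(orderB)
  for (i in seq_len(m)) {
    g <- orderB[i]
    neighB[[g]] <- c(orderB[if (i == 1) m else i - 1], orderB[if (i == m) 1 else i + 1])
  }
  cons <- 0
  for (i in seq_len(n)) {
    a <- orderA[i]
    b <- orderA[if (i == n) 1 else i + 1]
    if (b %in% neighB[[a]]) cons <- cons + 1
  }
  cons
}

# sound screen for inverted repeats: an IR with arm length >= k implies a
# k-mer shared between the sequence and its reverse complement
oracle_shared_kmers <- function(seq, k = 25) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  km <- function(s) unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  length(intersect(km(seq), km(rc)))
}
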