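# Small genomes built in code for unit tests.

# a genome from an explicit feature table laid over a given sequence
toy_genome <- function(sequence, ..., id = "toy") {
  rows <- list(...)
  feats <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], gene_type = r[[2]], strand = as.integer(r[[3]]),
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               stringsAsFactors = FALSE)
  }))
  annotated_genome(id, sequence, feats)
}

# deterministic unique-ish sequence, no RNG involvement
patterned_seq <- function(n) {
  paste(rep(c("A", "C", "G", "T", "A", "T", "G", "C"), length.out = n), collapse = "")
}

# circular genome of n single-codon-multiple genes with given names/strands,
# each gene 30 bp, spacers 10 bp, deterministic sequence
named_gene_circle <- function(names, strands = rep(1L, length(names)), id = "circle") {
  n <- length(names)
  gene_len <- 30L
  sp <- 10L
  L <- n * (gene_len + sp)
  feats <- data.frame(
    name = names,
    gene_type = ifelse(grepl("^trn", names), "tRNA",
                       ifelse(names %in% c("rrs", "rrl", "rrf"), "rRNA", "protein")),
    strand = as.integer(strands),
    start = (seq_len(n) - 1L) * (gene_len + sp) + sp,
    end = (seq_len(n) - 1L) * (gene_len + sp) + sp + gene_len,
    stringsAsFactors = FALSE)
  annotated_genome(id, patterned_seq(L), feats)
}

# the shared study fixture: built once per test run, reused across files
study_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_study_fixture(20240915)
    cache
  }
})
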