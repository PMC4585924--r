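# Synthetic-data generator: ancestral circular plastome and evolved
# descendant pairs with known synonymous/non-synonymous divergence, planted
# deletions (breakpoints) and optional inversions. The generator is the
# no-download test substrate for every other module: evolution is driven by
# the realized NG86-counted divergence (tracked incrementally from the same
# codon tables), and the recorded truth is an exact recomputation on the
# true column correspondence, so estimators are always tested against
# realized, not target, divergence.

GENE_POOLS <- list(
  photosynthesis = c("psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH",
                     "psbI", "psbJ", "psbK", "psbL", "psbM", "psbN", "psbT",
                     "psbZ", "psaA", "psaB", "psaC", "psaI", "psaJ", "psaM",
                     "rbcL", "chlB", "chlL", "chlN"),
  atp_synthase = c("atpA", "atpB", "atpE", "atpF", "atpH", "atpI"),
  cytochrome = c("petA", "petB", "petD", "petG", "petL", "ccsA"),
  ribosomal_protein = c("rps2", "rps3", "rps4", "rps7", "rps8", "rps9",
                        "rps11", "rps12", "rps14", "rps18", "rps19", "rpl2",
                        "rpl5", "rpl12", "rpl14", "rpl16", "rpl19", "rpl20",
                        "rpl23", "rpl36"),
  rna_polymerase = c("rpoA", "rpoB", "rpoC1", "rpoC2"),
  rRNA = c("rrs", "rrl", "rrf"),
  tRNA = c("trnA(UGC)", "trnC(GCA)", "trnD(GUC)", "trnE(UUC)", "trnF(GAA)",
           "trnG(GCC)", "trnG(UCC)", "trnH(GUG)", "trnI(GAU)", "trnI(CAU)",
           "trnK(UUU)", "trnL(UAA)", "trnL(UAG)", "trnL(GAG)", "trnM(CAU)",
           "trnN(GUU)", "trnP(UGG)", "trnQ(UUG)", "trnR(ACG)", "trnR(UCU)",
           "trnS(GCU)", "trnS(UGA)", "trnS(GGA)", "trnT(UGU)", "trnT(GGU)",
           "trnV(UAC)", "trnW(CCA)", "trnY(GUA)"),
  other_conserved = c("tufA", "clpP", "infA", "cemA", "ftsH", "minD",
                      "ycf1", "ycf3", "ycf4", "ycf12")
)

#' Simulation configuration
#'
#' Defaults emulate a compact AT-rich plastome: gene counts per functional
#' category on the scale of a reduced trebouxiophyte plastid genome,
#' AT-rich intergenic spacers (fraction 0.85), and deletion junctions drawn
#' even more AT-rich (fraction 0.9) to mirror the very AT-rich junctions of
#' reduced plastomes. `target_ks`/`target_ka` are per-branch divergence
#' targets; tRNA/rRNA and non-coding sequence evolve at per-site rates
#' scaled from `target_ks` (defaults: 0.1x for structural RNAs, which are
#' the most conserved sequences in these genomes, and 1.5x for spacers,
#' which are the least conserved).
#'
#' @param n_genes named integer vector of gene counts per category
#'   (photosynthesis, atp_synthase, cytochrome, ribosomal_protein,
#'   rna_polymerase, rRNA, tRNA, other_conserved, orf).
#' @param protein_len_codons min/max protein length in codons (uniform).
#' @param trna_len,rrna_len tRNA length range; named rRNA lengths.
#' @param intergenic_len spacer length range in bp.
#' @param intergenic_at A+T fraction of spacers.
#' @param coding_at A+T bias of codon sampling.
#' @param target_ks,target_ka realized NG86 divergence targets
#'   (`target_ks < 3`, the Jukes-Cantor correction range): [evolve()]
#'   drives a single branch from the ancestor to them, [simulate_pair()]
#'   drives the pairwise divergence of the two descendants to them.
#' @param rna_rate_scale,noncoding_rate_scale per-site substitution
#'   distances for RNA genes / spacers as multiples of `target_ks`.
#' @param junction_at,junction_len AT fraction and length range of the
#'   spacer fused in at each planted deletion.
#' @param strand_plus_prob probability a gene is on the plus strand.
#' @param deletions list of character vectors, each a run of consecutive
#'   genes to delete on the evolved lineage.
#' @param inversions list of character vectors, each a run of consecutive
#'   genes to invert in place.
#' @param layout optional data.frame (`name`, `gene_type`, `category`)
#'   fixing gene order; otherwise order is shuffled.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = c(photosynthesis = 20, atp_synthase = 6,
                                   cytochrome = 5, ribosomal_protein = 20,
                                   rna_polymerase = 4, rRNA = 3, tRNA = 28,
                                   other_conserved = 8, orf = 4),
                       protein_len_codons = c(100L, 500L),
                       trna_len = c(72L, 90L),
                       rrna_len = c(rrs = 1480L, rrl = 2890L, rrf = 120L),
                       intergenic_len = c(60L, 300L),
                       intergenic_at = 0.85,
                       coding_at = 0.70,
                       target_ks = 0.4, target_ka = 0.03,
                       rna_rate_scale = 0.1, noncoding_rate_scale = 1.5,
                       junction_at = 0.9, junction_len = c(120L, 200L),
                       strand_plus_prob = 0.8,
                       deletions = NULL, inversions = NULL, layout = NULL) {
  stopifnot(all(n_genes >= 0), target_ks >= 0, target_ka >= 0,
            intergenic_at >= 0, intergenic_at <= 1,
            junction_at >= 0, junction_at <= 1)
  if (target_ks >= 3) stop("target_ks beyond the Jukes-Cantor correction range")
  cfg <- list(n_genes = n_genes, protein_len_codons = protein_len_codons,
              trna_len = trna_len, rrna_len = rrna_len,
              intergenic_len = intergenic_len, intergenic_at = intergenic_at,
              coding_at = coding_at, target_ks = target_ks,
              target_ka = target_ka, rna_rate_scale = rna_rate_scale,
              noncoding_rate_scale = noncoding_rate_scale,
              junction_at = junction_at, junction_len = junction_len,
              strand_plus_prob = strand_plus_prob,
              deletions = deletions, inversions = inversions, layout = layout)
  class(cfg) <- "sim_config"
  cfg
}

# random stop-free codon string of n_codons total, ATG start + TAA stop
random_cds <- function(n_codons, at) {
  stopifnot(n_codons >= 3L)
  gc <- genetic_code_11()
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  n_inner <- n_codons - 2L
  draw <- function(m) {
    nt <- sample(c("A", "C", "G", "T"), 3L * m, replace = TRUE, prob = p)
    m3 <- matrix(nt, ncol = 3L, byrow = TRUE)
    paste0(m3[, 1L], m3[, 2L], m3[, 3L])
  }
  cods <- draw(n_inner)
  bad <- which(gc[cods] == "*")
  while (length(bad) > 0L) {
    cods[bad] <- draw(length(bad))
    bad <- bad[gc[cods[bad]] == "*"]
  }
  paste0("ATG", paste(cods, collapse = ""), "TAA")
}

#' Generate an ancestral circular plastome
#'
#' Assembles a circle of gene-spacer alternations from the configured gene
#' counts (or explicit layout): protein genes are random stop-free codon
#' sequences under an AT-biased nucleotide model (table 11), structural
#' RNAs are random sequences of realistic lengths, and spacers are AT-rich.
#' Deterministic given the RNG state (call `set.seed()` first or use
#' [simulate_pair()]).
#'
#' @param config a [sim_config()].
#' @param id genome label.
#' @return an [annotated_genome()].
#' @export
generate_ancestor <- function(config, id = "SYNANC") {
  layout <- config$layout
  if (is.null(layout)) {
    rows <- list()
    orf_i <- 0L
    for (cat in names(config$n_genes)) {
      k <- config$n_genes[[cat]]
      if (k == 0L) next
      if (cat == "orf") {
        nms <- sprintf("orf%d", seq_len(k) * 7L + 100L)
      } else {
        pool <- GENE_POOLS[[cat]]
        if (k > length(pool)) stop("not enough gene names in pool for ", cat)
        nms <- pool[seq_len(k)]
      }
      gt <- switch(cat, rRNA = "rRNA", tRNA = "tRNA", "protein")
      rows[[cat]] <- data.frame(name = nms, gene_type = gt, category = cat,
                                stringsAsFactors = FALSE)
    }
    layout <- do.call(rbind, rows)
    layout <- layout[sample(nrow(layout)), , drop = FALSE]
  }
  n <- nrow(layout)
  if (n == 0L) stop("infeasible config: no genes")
  pieces <- character(2L * n)
  feats <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    sp_len <- sample(seq(config$intergenic_len[1L], config$intergenic_len[2L]), 1L)
    spacer <- random_seq(sp_len, config$intergenic_at)
    gene_type <- layout$gene_type[i]
    gseq <- switch(gene_type,
      protein = random_cds(sample(seq(config$protein_len_codons[1L],
                                      config$protein_len_codons[2L]), 1L),
                           config$coding_at),
      tRNA = random_seq(sample(seq(config$trna_len[1L], config$trna_len[2L]), 1L), 0.6),
      rRNA = {
        len <- config$rrna_len[[layout$name[i]]]
        if (is.null(len) || is.na(len)) len <- 1000L
        random_seq(len, 0.6)
      })
    strand <- if (gene_type == "rRNA") 1L else {
      if (stats::runif(1) < config$strand_plus_prob) 1L else -1L
    }
    if (strand < 0 && gene_type == "protein") gseq <- revcomp(gseq)
    start <- pos + sp_len
    end <- start + nchar(gseq)
    feats[[i]] <- data.frame(name = layout$name[i], gene_type = gene_type,
                             category = layout$category[i], strand = strand,
                             start = start, end = end, stringsAsFactors = FALSE)
    pieces[2L * i - 1L] <- spacer
    pieces[2L * i] <- gseq
    pos <- end
  }
  closing <- random_seq(sample(seq(config$intergenic_len[1L],
                                   config$intergenic_len[2L]), 1L),
                        config$intergenic_at)
  sequence <- paste0(paste(pieces, collapse = ""), closing)
  annotated_genome(id, sequence, do.call(rbind, feats), circular = TRUE)
}

# Evolve the codons of one gene toward per-branch realized NG86 targets.
# `cods` excludes the terminal stop. Codon 1 (start) is frozen; realized
# Ks/Ka are tracked over all codons so they match what an estimator sees.
evolve_gene_codons <- function(cods, target_ks, target_ka, ref = NULL) {
  it <- ng86_itables()
  n <- length(cods)
  anc <- match(cods, it$codons)
  cur <- anc
  # divergence is tracked against `ref` (another already-evolved copy, for
  # driving a pairwise target) or against the starting state itself
  refi <- if (is.null(ref)) anc else match(ref, it$codons)
  S_anc <- sum(it$SITES[refi])
  S_cur <- sum(it$SITES[anc])
  Sd <- sum(it$SD[cbind(refi, anc)])
  Nd <- sum(it$ND[cbind(refi, anc)])
  n_syn <- 0L; n_nonsyn <- 0L
  realized <- function() {
    S <- (S_anc + S_cur) / 2
    c(ks = jc_correct(Sd / S), ka = jc_correct(Nd / (3 * n - S)))
  }
  # targets compared on the uncorrected proportion scale: monotone in the
  # corrected distance, so the stopping rule is identical but cheaper
  pS_target <- jc_p_from_d(target_ks)
  pN_target <- jc_p_from_d(target_ka)
  if (n < 2L || (target_ks == 0 && target_ka == 0)) {
    r <- realized()
    return(list(codons = cods, applied_syn = 0L, applied_nonsyn = 0L,
                ks = unname(r[["ks"]]), ka = unname(r[["ka"]])))
  }
  max_prop <- 3000L * n
  prop <- 0L
  chunk <- 512L
  repeat {
    S <- (S_anc + S_cur) / 2
    ks_ok <- target_ks == 0 || Sd / S >= pS_target
    ka_ok <- target_ka == 0 || Nd / (3 * n - S) >= pN_target
    if ((ks_ok && ka_ok) || prop >= max_prop) break
    ii <- sample.int(n - 1L, chunk, replace = TRUE) + 1L  # never the start codon
    pp <- sample.int(3L, chunk, replace = TRUE)
    tt <- sample.int(4L, chunk, replace = TRUE)
    for (m in seq_len(chunk)) {
      prop <- prop + 1L
      i <- ii[m]
      c0 <- cur[i]
      c1 <- it$NEI[c0, pp[m], tt[m]]
      if (c1 == c0 || it$STOP[c1]) next
      syn <- it$AA[c1] == it$AA[c0]
      if (syn) {
        if (ks_ok) next
      } else {
        if (ka_ok) next
      }
      a <- refi[i]
      S_cur <- S_cur - it$SITES[c0] + it$SITES[c1]
      Sd <- Sd - it$SD[a, c0] + it$SD[a, c1]
      Nd <- Nd - it$ND[a, c0] + it$ND[a, c1]
      cur[i] <- c1
      S <- (S_anc + S_cur) / 2
      if (syn) {
        n_syn <- n_syn + 1L
        ks_ok <- Sd / S >= pS_target
        if (ks_ok && ka_ok) break
      } else {
        n_nonsyn <- n_nonsyn + 1L
        ka_ok <- Nd / (3 * n - S) >= pN_target
        if (ks_ok && ka_ok) break
      }
    }
  }
  r <- realized()
  list(codons = it$codons[cur], applied_syn = n_syn, applied_nonsyn = n_nonsyn,
       ks = unname(r[["ks"]]), ka = unname(r[["ka"]]))
}

# per-site substitutions over a set of 1-based positions of a char vector
mutate_sites <- function(chars, positions, d) {
  if (d <= 0 || length(positions) == 0L) return(chars)
  p_sub <- jc_p_from_d(d)
  hit <- positions[stats::runif(length(positions)) < p_sub]
  if (length(hit) == 0L) return(chars)
  nts <- c("A", "C", "G", "T")
  repl <- vapply(chars[hit], function(x) sample(nts[nts != x], 1L), character(1))
  chars[hit] <- repl
  chars
}

#' Evolve one descendant from an ancestral genome
#'
#' Protein genes accumulate random single-nucleotide codon changes
#' (stop-creating changes rejected, start codon frozen) accepted until the
#' realized NG86-counted divergence against the ancestor reaches the
#' per-branch `target_ks`/`target_ka`; tRNA/rRNA genes and non-coding
#' positions evolve under per-site substitution at scaled rates; configured
#' inversions reverse-complement their gene runs in place; configured
#' deletions then remove their gene runs plus internal spacers, fusing the
#' flanks with a freshly drawn AT-rich junction spacer.
#'
#' @param ancestor an [annotated_genome()] with non-overlapping features
#'   (as produced by [generate_ancestor()]).
#' @param config a [sim_config()].
#' @param id label for the descendant.
#' @param ref_genome optional already-evolved sister genome: when given
#'   (with `pair_targets`), protein genes are evolved until the realized
#'   NG86 divergence against the sister — not the ancestor — reaches the
#'   targets, which drives the pairwise divergence of the two descendants
#'   to a chosen value.
#' @param pair_targets length-2 numeric `c(ks, ka)` pairwise targets used
#'   with `ref_genome`; RNA and spacer rates still come from `config`.
#' @return list with `genome` (the descendant) and `truth`: `per_gene`
#'   (realized NG86 Ks/Ka — per-branch, or pairwise when tracking a sister —
#'   and applied substitution counts per protein gene), `deletions` (per
#'   planted run: missing genes, flanks, junction coordinates in the
#'   descendant, junction length), `inversions`, and the echoed `config`.
#' @export
evolve <- function(ancestor, config, id = paste0(ancestor$id, "-desc"),
                   ref_genome = NULL, pair_targets = NULL) {
  stopifnot(is.null(ref_genome) == is.null(pair_targets))
  f <- ancestor$features
  chars <- strsplit(ancestor$sequence, "", fixed = TRUE)[[1L]]
  L <- ancestor$length

  per_gene <- list()
  for (i in seq_len(nrow(f))) {
    if (f$gene_type[i] != "protein") next
    ft <- f[i, ]
    cds <- feature_seq(ancestor, ft)
    cods <- split_codons(cds)
    gc <- genetic_code_11()
    has_stop <- length(cods) > 0L && gc[[cods[length(cods)]]] == "*"
    body <- if (has_stop) cods[-length(cods)] else cods
    if (is.null(ref_genome)) {
      ev <- evolve_gene_codons(body, config$target_ks, config$target_ka)
    } else {
      ref_cods <- split_codons(extract_cds_and_upstream(ref_genome, ft$name, 0L)$cds)
      ref_body <- if (has_stop) ref_cods[-length(ref_cods)] else ref_cods
      stopifnot(length(ref_body) == length(body))
      ev <- evolve_gene_codons(body, pair_targets[1L], pair_targets[2L],
                               ref = ref_body)
    }
    new_cds <- paste0(paste(ev$codons, collapse = ""),
                      if (has_stop) cods[length(cods)] else "")
    out_seq <- if (ft$strand < 0) revcomp(new_cds) else new_cds
    idx <- if (ft$wrap) c(seq(ft$start + 1L, L), seq_len(ft$end)) else seq(ft$start + 1L, ft$end)
    chars[idx] <- strsplit(out_seq, "", fixed = TRUE)[[1L]]
    per_gene[[ft$name]] <- data.frame(
      gene = ft$name, n_codons = length(body),
      applied_syn = ev$applied_syn, applied_nonsyn = ev$applied_nonsyn,
      ks_branch = ev$ks, ka_branch = ev$ka, stringsAsFactors = FALSE)
  }

  # structural RNAs: uniform per-site substitution at the scaled rate
  d_rna <- config$target_ks * config$rna_rate_scale
  for (i in which(f$gene_type %in% c("tRNA", "rRNA"))) {
    idx <- if (f$wrap[i]) c(seq(f$start[i] + 1L, L), seq_len(f$end[i])) else seq(f$start[i] + 1L, f$end[i])
    chars[idx] <- mutate_sites(chars[idx], seq_along(idx), d_rna)[seq_along(idx)]
  }

  # non-coding positions
  d_nc <- config$target_ks * config$noncoding_rate_scale
  nc <- which(!coverage_mask(ancestor))
  chars[nc] <- mutate_sites(chars[nc], seq_along(nc), d_nc)[seq_along(nc)]

  genome <- annotated_genome(id, paste(chars, collapse = ""),
                             f[, c("name", "gene_type", "category", "strand",
                                   "start", "end")],
                             circular = ancestor$circular)

  inv_truth <- NULL
  if (length(config$inversions) > 0L) {
    for (run in config$inversions) genome <- invert_run(genome, run)
    inv_truth <- data.frame(genes = vapply(config$inversions, paste,
                                           character(1), collapse = ","))
  }

  del_truth <- NULL
  if (length(config$deletions) > 0L) {
    res <- apply_deletions(genome, config$deletions,
                           config$junction_at, config$junction_len)
    genome <- res$genome
    del_truth <- res$truth
  }

  list(genome = genome,
       truth = list(per_gene = do.call(rbind, unname(per_gene)),
                    deletions = del_truth, inversions = inv_truth,
                    config = config))
}

# reverse-complement the span of a run of consecutive genes, in place
invert_run <- function(genome, run) {
  f <- genome$features
  idx <- match(run, f$name)
  if (anyNA(idx)) stop("inversion names a gene absent from the genome: ",
                       paste(run[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  if (!all(diff(idx) == 1L)) stop("inversion run is not consecutive: ",
                                  paste(run, collapse = ","))
  s <- f$start[idx[1L]]
  e <- f$end[idx[length(idx)]]
  if (e <= s) stop("inversion runs spanning the origin are not supported")
  L <- genome$length
  seg <- substr(genome$sequence, s + 1L, e)
  seq2 <- paste0(substr(genome$sequence, 1L, s), revcomp(seg),
                 substr(genome$sequence, e + 1L, L))
  for (i in idx) {
    os <- f$start[i]; oe <- f$end[i]
    f$start[i] <- s + (e - oe)
    f$end[i] <- s + (e - os)
    f$strand[i] <- -f$strand[i]
  }
  annotated_genome(genome$id, seq2,
                   f[, c("name", "gene_type", "category", "strand", "start", "end")],
                   circular = genome$circular)
}

# Remove each run of consecutive genes (plus internal spacers) and fuse the
# flanks with an AT-rich junction spacer; returns rebuilt genome + truth.
apply_deletions <- function(genome, runs, junction_at, junction_len) {
  f0 <- genome$features
  all_del <- unlist(runs)
  if (anyDuplicated(all_del)) stop("a gene appears in two deletion runs")
  miss <- setdiff(all_del, f0$name)
  if (length(miss) > 0L) stop("deletion names genes absent from the genome: ",
                              paste(miss, collapse = ", "))
  # anchor the origin at a retained gene so no deletion arc wraps
  retained <- setdiff(f0$name, all_del)
  if (length(retained) == 0L) stop("deletions would remove every gene")
  anchor <- f0$name[f0$name %in% retained][1L]
  g <- rotate_genome(genome, f0$start[match(anchor, f0$name)])
  f <- g$features
  ord_names <- f$name[order(f$start)]

  arcs <- lapply(runs, function(run) {
    idx <- sort(match(run, ord_names))
    if (anyNA(idx) || !all(diff(idx) == 1L)) {
      stop("deletion run is not consecutive in the genome: ",
           paste(run, collapse = ","))
    }
    if (idx[1L] == 1L) stop("deletion run includes the anchor gene")
    left <- ord_names[idx[1L] - 1L]
    right <- if (idx[length(idx)] == length(ord_names)) ord_names[1L] else ord_names[idx[length(idx)] + 1L]
    if (left %in% all_del || right %in% all_del) {
      stop("deletion runs abut (flank of one run deleted by another): ",
           paste(run, collapse = ","))
    }
    from <- f$end[match(left, f$name)]
    to <- f$start[match(right, f$name)]
    if (right == anchor) to <- nchar(g$sequence)  # arc runs to the origin
    if (to <= from) stop("degenerate deletion arc for run: ",
                         paste(run, collapse = ","))
    list(genes = ord_names[idx], left = left, right = right,
         from = from, to = to)
  })
  arcs <- arcs[order(vapply(arcs, function(a) a$from, numeric(1)))]

  seq_in <- g$sequence
  pieces <- character(0)
  keep_feats <- f[!(f$name %in% all_del), , drop = FALSE]
  keep_feats <- keep_feats[order(keep_feats$start), , drop = FALSE]
  truth_rows <- list()
  cursor <- 0L
  new_starts <- keep_feats$start
  new_ends <- keep_feats$end
  removed_before <- 0L
  for (a in arcs) {
    jl <- sample(seq(junction_len[1L], junction_len[2L]), 1L)
    jseq <- random_seq(jl, junction_at)
    pieces <- c(pieces, substr(seq_in, cursor + 1L, a$from), jseq)
    junction_start <- a$from - removed_before
    removed_before <- removed_before + (a$to - a$from) - jl
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      genes = paste(a$genes, collapse = ","), n_genes = length(a$genes),
      left_flank = a$left, right_flank = a$right,
      junction_start = junction_start, junction_len = jl,
      stringsAsFactors = FALSE)
    # shift retained features at/after the arc end
    later <- keep_feats$start >= a$to
    new_starts[later] <- new_starts[later] - (a$to - a$from) + jl
    new_ends[later] <- new_ends[later] - (a$to - a$from) + jl
    cursor <- a$to
  }
  pieces <- c(pieces, substr(seq_in, cursor + 1L, nchar(seq_in)))
  seq_out <- paste(pieces, collapse = "")
  keep_feats$start <- new_starts
  keep_feats$end <- new_ends
  genome_out <- annotated_genome(genome$id, seq_out,
                                 keep_feats[, c("name", "gene_type", "category",
                                                "strand", "start", "end")],
                                 circular = genome$circular)
  list(genome = genome_out, truth = do.call(rbind, truth_rows))
}

# Exact NG86 on the true (indel-free) codon correspondence of two CDS.
ng86_pair_cds <- function(cdsA, cdsB, gene = NA_character_) {
  ca <- split_codons(toupper(cdsA))
  cb <- split_codons(toupper(cdsB))
  stopifnot(length(ca) == length(cb))
  ng86(list(gene = gene, codons_a = ca, codons_b = cb, rejected = FALSE))
}

#' Simulate an evolved genome pair with recorded truth
#'
#' Generates an ancestor and evolves two descendants: A (no deletions or
#' inversions) takes a share of the divergence from the ancestor, then B
#' (with any configured deletions/inversions) is evolved until its realized
#' NG86 divergence against A reaches the full `target_ks`/`target_ka` of
#' `config` — so the configured targets are pairwise, and the realized
#' pairwise divergence lands on them up to one substitution of overshoot.
#' The pairwise truth is the exact NG86 divergence between A and B computed
#' on the true codon correspondence.
#'
#' @param config a [sim_config()]; `target_ks`/`target_ka` are interpreted
#'   as the pairwise A-B divergence.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param branch_A_share fraction of the coding divergence placed on the
#'   A branch (default 0.5).
#' @return list: `ancestor`, `A`, `B` (genomes), `truth` with `per_gene`
#'   (pairwise realized `Ks_true`/`Ka_true` per protein gene), `deletions`,
#'   `inversions`, `branch_A`/`branch_B` truths, and `seed`.
#' @export
simulate_pair <- function(config, seed, branch_A_share = 0.5) {
  set.seed(as.integer(seed))
  anc <- generate_ancestor(config)
  cfgA <- config
  cfgA$deletions <- NULL
  cfgA$inversions <- NULL
  cfgA$target_ks <- config$target_ks * branch_A_share
  cfgA$target_ka <- config$target_ka * branch_A_share
  evA <- evolve(anc, cfgA, id = "SYN-A")
  cfgB <- config
  cfgB$target_ks <- config$target_ks * (1 - branch_A_share)
  cfgB$target_ka <- config$target_ka * (1 - branch_A_share)
  evB <- evolve(anc, cfgB, id = "SYN-B", ref_genome = evA$genome,
                pair_targets = c(config$target_ks, config$target_ka))
  shared_prot <- intersect(evA$genome$features$name[evA$genome$features$gene_type == "protein"],
                           evB$genome$features$name[evB$genome$features$gene_type == "protein"])
  rows <- lapply(sort(shared_prot), function(g) {
    r <- ng86_pair_cds(extract_cds_and_upstream(evA$genome, g, 0L)$cds,
                       extract_cds_and_upstream(evB$genome, g, 0L)$cds, gene = g)
    data.frame(gene = g, n_codons = r$n_codons_compared,
               Ks_true = r$Ks, Ka_true = r$Ka, pS_true = r$pS,
               saturated = r$saturated, stringsAsFactors = FALSE)
  })
  list(ancestor = anc, A = evA$genome, B = evB$genome,
       truth = list(per_gene = do.call(rbind, rows),
                    deletions = evB$truth$deletions,
                    inversions = evB$truth$inversions,
                    branch_A = evA$truth$per_gene,
                    branch_B = evB$truth$per_gene),
       seed = as.integer(seed), config = config)
}

# fixed gene order used by the miniature study analog: photosynthesis genes
# arranged in six runs, four of them flanked by a tRNA
study_layout <- function() {
  nm <- c("rrs", "rrl", "rrf", "trnA(UGC)", "rps2",
          "psbA", "psbB", "psbC",
          "trnL(UAA)", "rps4", "rpoA",
          "psbD", "psbE",
          "rpl2", "trnF(GAA)",
          "psaA", "psaB",
          "trnM(CAU)", "rps7", "atpA",
          "psaC",
          "rpl14", "tufA",
          "rbcL", "chlB",
          "trnW(CCA)", "rps8", "clpP",
          "chlL", "chlN",
          "trnD(GUC)", "rps19", "rpl16", "rpoB", "atpB", "rps3",
          "trnG(GCC)", "rpl20", "rps11")
  gt <- ifelse(grepl("^trn", nm), "tRNA", ifelse(nm %in% c("rrs", "rrl", "rrf"), "rRNA", "protein"))
  data.frame(name = nm, gene_type = gt,
             category = mapply(classify_gene, nm, gt, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

STUDY_DELETION_RUNS <- list(c("psbA", "psbB", "psbC"), c("psbD", "psbE"),
                            c("psaA", "psaB"), "psaC", c("rbcL", "chlB"),
                            c("chlL", "chlN"))

#' Miniature analog of a photosynthetic/heterotrophic plastome pair
#'
#' Builds a small two-genome study system: a photosynthetic "reference"
#' of 39 genes including a photosynthesis category, and a "reduced"
#' descendant lacking all 12 photosynthesis genes through six planted
#' deletion runs, at a pairwise synonymous divergence driven to 0.8.
#' Used across the test suite; optionally writes the pair as GenBank flat
#' files plus a truth JSON.
#'
#' @param seed integer seed.
#' @param dir optional output directory for `reference.gb`, `reduced.gb`
#'   and `truth.json`.
#' @param protein_len_codons protein length range (default 100-300 codons
#'   keeps the fixture light).
#' @return the [simulate_pair()] result, with `A` relabelled `SYNPHOTO`
#'   (reference) and `B` `SYNHETERO` (reduced); `$paths` added when `dir`
#'   is given.
#' @export
make_study_fixture <- function(seed, dir = NULL,
                               protein_len_codons = c(100L, 300L)) {
  cfg <- sim_config(layout = study_layout(),
                    protein_len_codons = protein_len_codons,
                    target_ks = 0.8, target_ka = 0.06,
                    deletions = STUDY_DELETION_RUNS)
  sim <- simulate_pair(cfg, seed)
  sim$A$id <- "SYNPHOTO"
  sim$B$id <- "SYNHETERO"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p_ref <- file.path(dir, "reference.gb")
    p_red <- file.path(dir, "reduced.gb")
    p_truth <- file.path(dir, "truth.json")
    write_genbank(sim$A, p_ref)
    write_genbank(sim$B, p_red)
    jsonlite::write_json(list(seed = sim$seed,
                              per_gene = sim$truth$per_gene,
                              deletions = sim$truth$deletions),
                         p_truth, auto_unbox = TRUE, digits = NA)
    sim$paths <- c(reference = p_ref, reduced = p_red, truth = p_truth)
  }
  sim
}

#' Fixture with a chosen number of planted deletion runs
#'
#' Lays out `n_runs` runs of photosynthesis genes (sizes cycling 1-2),
#' each separated by retained genes with tRNAs at alternating flanks, and
#' deletes every run on the reduced lineage. Designed for breakpoint
#' recovery tests where the planted truth must be unambiguous
#' (non-abutting runs, retained flanks).
#'
#' @param seed integer seed.
#' @param n_runs number of deletion runs (1-17).
#' @param target_ks per-branch synonymous divergence (default 0.2).
#' @return a [simulate_pair()] result.
#' @export
make_breakpoint_fixture <- function(seed, n_runs, target_ks = 0.2) {
  stopifnot(n_runs >= 1L, n_runs <= 17L)
  photo <- GENE_POOLS$photosynthesis
  keepers <- c(GENE_POOLS$ribosomal_protein, GENE_POOLS$other_conserved,
               GENE_POOLS$atp_synthase, GENE_POOLS$rna_polymerase,
               GENE_POOLS$cytochrome)
  trnas <- GENE_POOLS$tRNA
  sizes <- rep_len(c(2L, 1L), n_runs)
  if (sum(sizes) > length(photo)) sizes <- rep_len(1L, n_runs)
  runs <- list()
  nm <- c("rrs", "rrl", "rrf")
  gi <- 0L; ki <- 0L; ti <- 0L
  for (r in seq_len(n_runs)) {
    ki <- ki + 1L
    nm <- c(nm, keepers[ki])
    if (r %% 2L == 1L) {        # tRNA on the left flank of odd runs
      ti <- ti + 1L
      nm <- c(nm, trnas[ti])
    }
    run <- photo[gi + seq_len(sizes[r])]
    gi <- gi + sizes[r]
    runs[[r]] <- run
    nm <- c(nm, run)
    ki <- ki + 1L
    nm <- c(nm, keepers[ki])
  }
  nm <- c(nm, keepers[ki + seq_len(3L)])
  gt <- ifelse(grepl("^trn", nm), "tRNA",
               ifelse(nm %in% c("rrs", "rrl", "rrf"), "rRNA", "protein"))
  layout <- data.frame(name = nm, gene_type = gt,
                       category = mapply(classify_gene, nm, gt, USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
  cfg <- sim_config(layout = layout, protein_len_codons = c(100L, 200L),
                    target_ks = target_ks, target_ka = 0.02,
                    deletions = runs)
  simulate_pair(cfg, seed)
}
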