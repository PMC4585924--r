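test_that("the generator is deterministic under a seed", {
  cfg <- sim_config(n_genes = c(photosynthesis = 3, atp_synthase = 2,
                                cytochrome = 0, ribosomal_protein = 4,
                                rna_polymerase = 0, rRNA = 3, tRNA = 5,
                                other_conserved = 2, orf = 1),
                    protein_len_codons = c(60L, 120L))
  s1 <- simulate_pair(cfg, 777)
  s2 <- simulate_pair(cfg, 777)
  expect_identical(s1$A$sequence, s2$A$sequence)
  expect_identical(s1$B$sequence, s2$B$sequence)
  expect_identical(s1$truth$per_gene, s2$truth$per_gene)
  s3 <- simulate_pair(cfg, 778)
  expect_false(identical(s1$A$sequence, s3$A$sequence))
})

test_that("a zero-divergence branch with no deletions is the ancestor", {
  cfg <- sim_config(n_genes = c(photosynthesis = 2, atp_synthase = 0,
                                cytochrome = 0, ribosomal_protein = 3,
                                rna_polymerase = 0, rRNA = 1, tRNA = 2,
                                other_conserved = 0, orf = 0),
                    rrna_len = c(rrs = 300L),
                    protein_len_codons = c(60L, 100L),
                    target_ks = 0, target_ka = 0)
  set.seed(55)
  anc <- generate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  expect_identical(ev$genome$sequence, anc$sequence)
  expect_identical(ev$genome$features$start, anc$features$start)
})

test_that("a single-gene config yields a one-feature genome", {
  cfg <- sim_config(n_genes = c(photosynthesis = 0, atp_synthase = 0,
                                cytochrome = 0, ribosomal_protein = 1,
                                rna_polymerase = 0, rRNA = 0, tRNA = 0,
                                other_conserved = 0, orf = 0))
  set.seed(66)
  g <- generate_ancestor(cfg)
  expect_equal(nrow(g$features), 1L)
  expect_identical(g$features$gene_type, "protein")
  # the CDS translates cleanly with no internal stop
  aa <- translate_cds(extract_cds_and_upstream(g, g$features$name, 0L)$cds)
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
})

test_that("ancestors mimicking a compact plastome have plausible shape", {
  cfg <- sim_config()  # defaults: 98 genes across 9 categories
  set.seed(99)
  g <- generate_ancestor(cfg)
  expect_equal(nrow(g$features), 98L)
  expect_gt(at_percent(g$sequence), 60)
  expect_lt(at_percent(g$sequence), 75)
  expect_true(all(plastidcomp:::GENE_CATEGORIES %in% g$features$category))
  s <- genome_stats(g)
  expect_equal(s$n_rRNA, 3L)
  expect_equal(s$n_tRNA, 28L)
})

test_that("realized branch divergence tracks the target for long genes", {
  cfg <- sim_config(n_genes = c(photosynthesis = 0, atp_synthase = 0,
                                cytochrome = 0, ribosomal_protein = 8,
                                rna_polymerase = 0, rRNA = 0, tRNA = 0,
                                other_conserved = 0, orf = 0),
                    protein_len_codons = c(300L, 400L),
                    target_ks = 0.8, target_ka = 0.05)
  set.seed(123)
  anc <- generate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  expect_true(all(abs(ev$truth$per_gene$ks_branch - 0.8) / 0.8 < 0.05))
  expect_true(all(ev$truth$per_gene$ks_branch >= 0.8))  # stop at first crossing
})

test_that("recorded pairwise truth is an exact NG86 recomputation", {
  sim <- study_sim()
  tg <- sim$truth$per_gene
  for (g in tg$gene[1:5]) {
    o <- oracle_ng86(
      plastidcomp:::split_codons(extract_cds_and_upstream(sim$A, g, 0L)$cds),
      plastidcomp:::split_codons(extract_cds_and_upstream(sim$B, g, 0L)$cds))
    expect_equal(tg$Ks_true[tg$gene == g], o$Ks, info = g)
    expect_equal(tg$Ka_true[tg$gene == g], o$Ka, info = g)
  }
})

test_that("back-translated codon alignment recovers the true correspondence", {
  # no indels are simulated inside genes, so the protein-guided alignment
  # must be gap-free and the estimate must equal the truth exactly
  sim <- study_sim()
  kk <- kska_table(sim$A, sim$B)
  m <- merge(kk, sim$truth$per_gene, by = "gene")
  expect_true(all(!is.na(m$Ks)))
  expect_equal(m$Ks, m$Ks_true)
  expect_equal(m$Ka, m$Ka_true)
})

test_that("planted inversions flip strand and reverse order in place", {
  cfg <- sim_config(n_genes = c(photosynthesis = 0, atp_synthase = 0,
                                cytochrome = 0, ribosomal_protein = 6,
                                rna_polymerase = 0, rRNA = 0, tRNA = 0,
                                other_conserved = 0, orf = 0),
                    protein_len_codons = c(60L, 90L),
                    target_ks = 0, target_ka = 0,
                    layout = data.frame(
                      name = c("rps2", "rps3", "rps4", "rps7", "rps8", "rps9"),
                      gene_type = "protein", category = "ribosomal_protein"),
                    inversions = list(c("rps3", "rps4", "rps7")))
  set.seed(31)
  anc <- generate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  pa <- to_signed_permutation(anc)
  pb <- to_signed_permutation(ev$genome)
  expect_identical(pb$name, c("rps2", "rps7", "rps4", "rps3", "rps8", "rps9"))
  inv_idx <- match(c("rps3", "rps4", "rps7"), pb$name)
  anc_sign <- stats::setNames(pa$sign, pa$name)
  expect_equal(pb$sign[inv_idx], -anc_sign[c("rps3", "rps4", "rps7")],
               ignore_attr = TRUE)
  # the gene sequences themselves are preserved
  expect_identical(extract_cds_and_upstream(ev$genome, "rps4", 0L)$cds,
                   extract_cds_and_upstream(anc, "rps4", 0L)$cds)
  sr <- compare_order(anc, ev$genome)
  expect_equal(sr$breakpoint_distance, 2L)
})

test_that("the study fixture writes a parseable pair with truthful content", {
  dir <- withr::local_tempdir()
  sim <- make_study_fixture(4242, dir = dir)
  ref <- read_genbank(file.path(dir, "reference.gb"))
  red <- read_genbank(file.path(dir, "reduced.gb"))
  expect_identical(ref$sequence, sim$A$sequence)
  expect_identical(red$sequence, sim$B$sequence)
  cc <- compare_content(ref, red)
  planted <- sort(unlist(strsplit(sim$truth$deletions$genes, ",")))
  expect_identical(cc$only_in_A, planted)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 4242)
  expect_equal(truth$per_gene$Ks_true, sim$truth$per_gene$Ks_true)
})

test_that("the full pipeline on the fixture reproduces the truth chain", {
  sim <- study_sim()
  res <- run_pipeline(sim$A, sim$B)
  expect_equal(res$content$nA, 39L)
  expect_equal(res$content$n_shared, 27L)
  expect_length(res$content$only_in_A, 12L)
  expect_equal(res$junctions$n_regions, nrow(sim$truth$deletions))
  expect_equal(res$mean_ks, mean(sim$truth$per_gene$Ks_true))
  expect_equal(res$divergence$n_generations, res$mean_ks / 3.23e-10)
})

test_that("pipeline outputs are byte-identical across reruns", {
  sim <- study_sim()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(sim$A, sim$B, out_dir = d1)
  run_pipeline(sim$A, sim$B, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("comparing a genome against itself yields the null report", {
  sim <- study_sim()
  res <- run_pipeline(sim$A, sim$A)
  expect_length(res$content$only_in_A, 0)
  expect_equal(nrow(res$breakpoints), 0L)
  expect_equal(res$mean_ks, 0)
  expect_equal(res$divergence$T_high, 0)
  expect_equal(res$synteny$adjacency_fraction, 1)
})
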