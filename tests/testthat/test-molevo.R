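test_that("identical CDS align without gaps and score zero divergence", {
  set.seed(12)
  cds <- plastidcomp:::random_cds(120, 0.6)
  aln <- align_codons(cds, cds, gene = "self")
  expect_false(aln$rejected)
  expect_equal(aln$n_codons_compared, 119L)  # terminal stop trimmed
  expect_false(any(aln$codons_a == "---"))
  r <- ng86(aln)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_false(r$saturated)
})

test_that("a deleted codon produces exactly one gap-triplet column", {
  set.seed(13)
  cds <- plastidcomp:::random_cds(100, 0.6)
  cods <- plastidcomp:::split_codons(cds)
  short <- paste(cods[-50], collapse = "")
  aln <- align_codons(cds, short, gene = "del")
  expect_equal(sum(aln$codons_b == "---"), 1L)
  expect_equal(sum(aln$codons_a == "---"), 0L)
  expect_equal(aln$n_codons_compared, 98L)
})

test_that("internal stops reject the gene with a reason", {
  aln <- align_codons("ATGTAACCCGGG", "ATGCCCGGGTAA", gene = "stopper")
  expect_true(aln$rejected)
  expect_match(aln$reason, "stop")
  expect_error(ng86(aln), "rejected")
})

test_that("lengths not divisible by 3 are trimmed with a warning", {
  set.seed(14)
  cds <- plastidcomp:::random_cds(50, 0.6)
  expect_warning(aln <- align_codons(paste0(cds, "AC"), cds, gene = "ragged"),
                 "divisible")
  expect_false(aln$rejected)
  expect_equal(aln$n_codons_compared, 49L)
})

test_that("single-codon examples match hand enumeration", {
  # TTT vs TTC: the only difference is synonymous; Phe codons have 1/3
  # synonymous site at position 3, so pS = 1/(1/3) = 3 and JC is undefined
  r <- ng86(list(gene = "phe", codons_a = "TTT", codons_b = "TTC",
                 rejected = FALSE))
  expect_equal(r$S, 1 / 3)
  expect_equal(r$N, 8 / 3)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 3)
  expect_true(r$saturated)
  expect_true(is.na(r$Ks))

  # GGG vs GGA (synonymous, but GGA loses a site to the TGA stop neighbour)
  # plus an identical AAA pair
  r2 <- ng86(list(gene = "gly", codons_a = c("GGG", "AAA"),
                  codons_b = c("GGA", "AAA"), rejected = FALSE))
  o <- oracle_ng86(c("GGG", "AAA"), c("GGA", "AAA"))
  expect_equal(r2$S, o$S)
  expect_equal(r2$N, o$N)
  expect_equal(r2$Sd, o$Sd)
  expect_equal(r2$Nd, o$Nd)
})

test_that("site and difference counts equal the recursive oracle on codon pairs", {
  set.seed(15)
  sense <- plastidcomp:::sense_codons()
  # all codons' site counts
  tb <- plastidcomp:::ng86_tables()
  for (cd in sense) {
    expect_equal(unname(tb$sites[cd]), oracle_sites(cd), info = cd)
  }
  # a random sample of codon pairs, including all three difference counts
  pairs <- cbind(sample(sense, 120, replace = TRUE),
                 sample(sense, 120, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    d <- oracle_diffs(pairs[i, 1], pairs[i, 2])
    expect_equal(unname(tb$SD[pairs[i, 1], pairs[i, 2]]), unname(d[1]))
    expect_equal(unname(tb$ND[pairs[i, 1], pairs[i, 2]]), unname(d[2]))
  }
})

test_that("ng86 is symmetric in its two sequences", {
  set.seed(16)
  sim <- plastidcomp:::ng86_itables()
  a <- plastidcomp:::random_cds(200, 0.65)
  ev <- plastidcomp:::evolve_gene_codons(
    plastidcomp:::split_codons(substr(a, 1, nchar(a) - 3)), 0.3, 0.05)
  b <- paste0(paste(ev$codons, collapse = ""), "TAA")
  r1 <- ng86(align_codons(a, b, gene = "fw"))
  r2 <- ng86(align_codons(b, a, gene = "rv"))
  for (f in c("S", "N", "Sd", "Nd", "Ks", "Ka")) {
    expect_equal(r1[[f]], r2[[f]], info = f)
  }
})

test_that("S + N equals three sites per compared codon", {
  sim <- study_sim()
  kk <- kska_table(sim$A, sim$B)
  expect_equal(kk$S + kk$N, 3 * kk$n_codons)
})

test_that("mean Ks averaging follows the stated policy", {
  df <- data.frame(gene = c("a", "b"), Ks = c(0.5, 1.1), S = c(100, 300))
  expect_equal(mean_ks(df)$mean_Ks, 0.8)
  expect_equal(mean_ks(df, "site_weighted")$mean_Ks,
               (0.5 * 100 + 1.1 * 300) / 400)
  one <- data.frame(gene = "a", Ks = 0.37, S = 10)
  expect_equal(mean_ks(one)$mean_Ks, 0.37)
  # undefined (JC-saturated) genes are excluded and counted
  mixed <- data.frame(gene = c("a", "b", "c"), Ks = c(0.4, NA, 0.6),
                      S = c(1, 1, 1))
  m <- mean_ks(mixed)
  expect_equal(m$mean_Ks, 0.5)
  expect_equal(m$n_excluded, 1L)
  expect_error(mean_ks(data.frame(gene = "a", Ks = NA_real_, S = 1)), "saturated")
})

test_that("the generation clock follows its published arithmetic", {
  d <- divergence_time(0.816, mu = 3.23e-10,
                       generation_times = c(heterotroph = 0.00274,
                                            autotroph = 0.008219))
  expect_equal(d$n_generations, 0.816 / 3.23e-10)
  expect_equal(d$n_generations, 2.526e9, tolerance = 1e-3)
  expect_equal(d$T_low, d$n_generations * 0.00274)
  expect_equal(d$T_high, d$n_generations * 0.008219)

  z <- divergence_time(0)
  expect_equal(z$n_generations, 0)
  expect_equal(unname(z$T_years), c(0, 0))

  expect_equal(divergence_time(3.23e-4, mu = 3.23e-10)$n_generations, 1e6)
  expect_error(divergence_time(0.5, mu = 0), "positive")
})

test_that("the clock is linear in Ks and generation time", {
  g <- c(slow = 0.002, fast = 0.02)
  d1 <- divergence_time(0.2, mu = 1e-10, generation_times = g)
  d2 <- divergence_time(0.4, mu = 1e-10, generation_times = g)
  expect_equal(d2$n_generations, 2 * d1$n_generations)
  expect_equal(unname(d2$T_years), 2 * unname(d1$T_years))
  expect_equal(unname(d1$T_years[["fast"]]), 10 * d1$T_years[["slow"]])
  # per-lineage halving is exactly a factor of two
  dh <- divergence_time(0.2, mu = 1e-10, generation_times = g, per_lineage = TRUE)
  expect_equal(dh$n_generations, d1$n_generations / 2)
})
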