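test_that("signed permutations read gene order, rotation and reflection correctly", {
  g <- named_gene_circle(c("atpA", "rps2", "rpoB"), strands = c(1L, 1L, -1L))
  p <- to_signed_permutation(g)
  expect_identical(p$name, c("atpA", "rps2", "rpoB"))
  expect_identical(p$sign, c(1L, 1L, -1L))

  # rotation of the genome gives a cyclic rotation of the list
  gr <- rotate_genome(g, g$features$start[2])
  pr <- to_signed_permutation(gr)
  expect_identical(pr$name, c("rps2", "rpoB", "atpA"))
  expect_identical(pr$sign, c(1L, -1L, 1L))

  # reflection reverses order and flips signs
  gf <- reflect_genome(g)
  pf <- to_signed_permutation(gf)
  expect_identical(pf$name, rev(p$name))
  expect_identical(pf$sign, -rev(p$sign))

  # tRNAs are excluded by default, included on request
  gt <- named_gene_circle(c("atpA", "trnF(GAA)", "rps2"))
  expect_identical(to_signed_permutation(gt)$name, c("atpA", "rps2"))
  expect_identical(to_signed_permutation(gt, include_tRNA = TRUE)$name,
                   c("atpA", "trnF(GAA)", "rps2"))
})

test_that("canonicalization rotates to the anchor and is idempotent", {
  g <- named_gene_circle(c("a1", "b2", "c3", "d4"), strands = c(1L, -1L, 1L, 1L))
  p <- to_signed_permutation(g)
  expect_identical(canonicalize(p, "a1"), p)
  pc <- canonicalize(p, "c3")
  expect_identical(pc$name, c("c3", "d4", "a1", "b2"))
  expect_identical(canonicalize(pc, "c3"), pc)
  pr <- canonicalize(p, "c3", reflect = TRUE)
  expect_identical(pr$name[1], "c3")
  expect_error(canonicalize(p, "zz"), "zz")
})

test_that("canonicalization never changes synteny statistics", {
  set.seed(101)
  genes <- paste0("g", 1:20)
  for (rep in 1:10) {
    pa <- random_signed_perm(genes, "pa")
    pb <- random_signed_perm(genes, "pb")
    base <- compare_perms(pa, pb)
    anchor <- sample(genes, 1)
    refl <- sample(c(TRUE, FALSE), 1)
    alt <- compare_perms(canonicalize(pa, anchor, refl), pb)
    expect_equal(alt$conserved_adjacencies, base$conserved_adjacencies)
    expect_equal(alt$breakpoint_distance, base$breakpoint_distance)
    expect_equal(alt$n_blocks, base$n_blocks)
  }
})

test_that("identical circles score perfect synteny under any rotation/reflection", {
  sim <- study_sim()
  g <- sim$A
  for (gg in list(g, rotate_genome(g, 1234L), reflect_genome(g))) {
    sr <- compare_order(g, gg)
    expect_equal(sr$adjacency_fraction, 1)
    expect_equal(sr$breakpoint_distance, 0L)
    expect_equal(sr$n_blocks, 1L)
  }
})

test_that("a 3-gene inversion costs breakpoint distance 2", {
  nms <- paste0("g", 1:10)
  a <- named_gene_circle(nms, id = "A")
  inv <- nms
  inv[4:6] <- rev(inv[4:6])
  b <- named_gene_circle(inv, strands = c(rep(1L, 3), rep(-1L, 3), rep(1L, 4)),
                         id = "B")
  sr <- compare_order(a, b)
  expect_equal(sr$breakpoint_distance, 2L)
  expect_equal(sr$n_blocks, 2L)
  # independent plain-loop count agrees
  expect_equal(sr$conserved_adjacencies, oracle_conserved_adjacencies(nms, inv))
})

test_that("conserved adjacency counting matches the independent oracle", {
  set.seed(202)
  genes <- paste0("g", 1:30)
  for (rep in 1:20) {
    pa <- random_signed_perm(genes, "pa")
    pb <- random_signed_perm(genes, "pb")
    sr <- compare_perms(pa, pb)
    expect_equal(sr$conserved_adjacencies,
                 oracle_conserved_adjacencies(pa$name, pb$name))
    expect_equal(sr$breakpoint_distance, sr$n_shared - sr$conserved_adjacencies)
    # symmetry
    expect_equal(compare_perms(pb, pa)$breakpoint_distance, sr$breakpoint_distance)
  }
})

test_that("block count equals breakpoint distance on a circle", {
  set.seed(303)
  genes <- paste0("g", 1:25)
  for (rep in 1:10) {
    sr <- compare_perms(random_signed_perm(genes), random_signed_perm(genes))
    if (sr$breakpoint_distance == 0) expect_equal(sr$n_blocks, 1L)
    else expect_equal(sr$n_blocks, sr$breakpoint_distance)
  }
})

test_that("pairwise matrix is symmetric with unit diagonal", {
  sim <- study_sim()
  shuffled <- local({
    set.seed(9)
    named_gene_circle(sample(sim$A$features$name), id = "SHUF")
  })
  m <- pairwise_matrix(list(sim$A, sim$A, shuffled))
  expect_equal(m$adjacency_fraction[1, 2], 1)
  expect_equal(m$breakpoint_distance[1, 2], 0)
  expect_true(isSymmetric(m$adjacency_fraction))
  expect_true(isSymmetric(m$breakpoint_distance))
  expect_true(all(diag(m$adjacency_fraction) == 1))
  expect_lt(m$adjacency_fraction[1, 3], 0.5)
})

test_that("degenerate pairs with fewer than 2 shared genes are flagged", {
  a <- named_gene_circle(c("atpA", "rps2"), id = "a")
  b <- named_gene_circle(c("atpA", "rpl5"), id = "b")
  sr <- compare_order(a, b)
  expect_true(sr$degenerate)
  expect_true(is.na(sr$adjacency_fraction))
})
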