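test_that("gene names are normalized to the community convention", {
  expect_identical(normalize_gene_name("ATPI"), "atpI")
  expect_identical(normalize_gene_name("tRNA-Leu(gag)"), "trnL(GAG)")
  expect_identical(normalize_gene_name("16S ribosomal RNA"), "rrs")
  expect_identical(normalize_gene_name("23S rRNA"), "rrl")
  expect_identical(
    normalize_gene_name(c("rbcl", "RPOC1", "trnS-GGA", "trnT(ggt)", "ycf3", "orf42")),
    c("rbcL", "rpoC1", "trnS(GGA)", "trnT(GGU)", "ycf3", "orf42"))
  # determinism / idempotence
  nm <- c("atpI", "trnL(GAG)", "rrs", "rpl12")
  expect_identical(normalize_gene_name(nm), nm)
  # unknown names pass through
  expect_identical(normalize_gene_name("unknown gene 7"), "unknown gene 7")
})

test_that("circular distance is symmetric, wraps, and is bounded by L/2", {
  expect_equal(circular_distance(0, 10, 100), 10)
  expect_equal(circular_distance(95, 5, 100), 10)
  expect_equal(circular_distance(37, 37, 500), 0)
  set.seed(11)
  a <- sample(0:999, 50)
  b <- sample(0:999, 50)
  expect_equal(circular_distance(a, b, 1000), circular_distance(b, a, 1000))
  expect_true(all(circular_distance(a, b, 1000) <= 500))
  expect_error(circular_distance(0, 1, 0), "positive")
})

test_that("CDS and upstream extraction respects strand and the origin", {
  L <- 500L
  s <- patterned_seq(L)
  g <- toy_genome(s, list("geneA", "protein", 1L, 100L, 400L))
  x <- extract_cds_and_upstream(g, "geneA", 50L)
  expect_identical(x$cds, substr(s, 101, 400))
  expect_identical(x$upstream, substr(s, 51, 100))
  expect_false(x$upstream_overlaps)

  gm <- toy_genome(s, list("geneB", "protein", -1L, 100L, 400L))
  xm <- extract_cds_and_upstream(gm, "geneB", 50L)
  expect_identical(xm$cds, revcomp(substr(s, 101, 400)))
  expect_identical(xm$upstream, revcomp(substr(s, 401, 450)))

  expect_error(extract_cds_and_upstream(g, "absent"), "not found")
})

test_that("upstream windows wrap the origin and match the rotated genome", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  g <- toy_genome(s, list("geneW", "protein", 1L, 10L, 100L))
  x <- extract_cds_and_upstream(g, "geneW", 50L)
  expect_identical(nchar(x$upstream), 50L)
  # rotate so the gene is interior; extraction must agree
  g2 <- rotate_genome(g, 300L)
  x2 <- extract_cds_and_upstream(g2, "geneW", 50L)
  expect_identical(x2$cds, x$cds)
  expect_identical(x2$upstream, x$upstream)
})

test_that("origin-spanning features follow the single wrap rule", {
  s <- patterned_seq(200)
  g <- toy_genome(s, list("wrapper", "protein", 1L, 170L, 50L))
  ft <- g$features[1, ]
  expect_true(ft$wrap)
  expect_equal(ft$length_bp, 80L)
  x <- extract_cds_and_upstream(g, "wrapper", 0L)
  expect_identical(x$cds, paste0(substr(s, 171, 200), substr(s, 1, 50)))
  # rotating the wrap away yields the same sequence
  g2 <- rotate_genome(g, 170L)
  expect_false(g2$features$wrap[1])
  expect_identical(extract_cds_and_upstream(g2, "wrapper", 0L)$cds, x$cds)
})

test_that("rotation preserves feature lengths and sequences", {
  sim <- study_sim()
  g <- sim$A
  for (k in c(1L, 137L, g$length - 1L)) {
    gr <- rotate_genome(g, k)
    expect_equal(sort(gr$features$length_bp), sort(g$features$length_bp))
    expect_identical(extract_cds_and_upstream(gr, "rps2", 0L)$cds,
                     extract_cds_and_upstream(g, "rps2", 0L)$cds)
  }
})

test_that("GenBank write/read round-trips a simulated genome", {
  sim <- study_sim()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$B, path)
  g2 <- read_genbank(path)
  expect_identical(g2$id, sim$B$id)
  expect_identical(g2$sequence, sim$B$sequence)
  expect_true(g2$circular)
  cols <- c("name", "gene_type", "strand", "start", "end")
  expect_identical(g2$features[, cols], sim$B$features[, cols])
})

test_that("GenBank output is read identically by an independent parser", {
  sim <- study_sim()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$A, path)
  script <- paste(
    "import sys",
    "from Bio import SeqIO",
    "r = SeqIO.read(sys.argv[1], 'genbank')",
    "print(len(r.seq))",
    "feats = [f for f in r.features if f.type in ('CDS','tRNA','rRNA')]",
    "print(len(feats))",
    "for f in sorted(feats, key=lambda f: int(f.location.start)):",
    "    print(f.qualifiers['gene'][0], int(f.location.start), int(f.location.end), f.location.strand)",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE, stderr = FALSE)
  expect_equal(as.integer(out[1]), sim$A$length)
  expect_equal(as.integer(out[2]), nrow(sim$A$features))
  got <- read.table(text = paste(out[-(1:2)], collapse = "\n"),
                    col.names = c("name", "start", "end", "strand"))
  f <- sim$A$features[order(sim$A$features$start), ]
  expect_identical(got$name, f$name)
  expect_equal(got$start, f$start)
  expect_equal(got$end, f$end)
  expect_equal(got$strand, f$strand)
})

test_that("records without a gene qualifier become flagged ORFs", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTREC 120 bp    DNA     circular PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             10..45",
    "                     /note=\"anonymous\"",
    "     CDS             complement(50..100)",
    "                     /gene=\"psbA\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), path)
  expect_warning(g <- read_genbank(path), "ORF")
  expect_equal(nrow(g$features), 2L)
  orf <- g$features[g$features$name != "psbA", ]
  expect_match(orf$name, "^orf")
  expect_identical(orf$category, "orf")
  psbA <- g$features[g$features$name == "psbA", ]
  expect_equal(psbA$strand, -1L)
  expect_identical(psbA$category, "photosynthesis")
})
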