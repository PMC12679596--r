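test_that("Karlin-Altschul lambda solves the +1/-1 moment equation", {
  ka <- ka_params()
  expect_equal(ka$lambda, log(3), tolerance = 1e-8)
  expect_equal(ka$K, 1 / 3, tolerance = 1e-10)
})

test_that("a perfect substring yields one full-length ungapped HSP", {
  set.seed(1)
  q <- rand_dna(100)
  ref <- paste0(rand_dna(400), q, rand_dna(300))
  h <- local_align(q, ref)
  expect_equal(nrow(h), 1L)
  expect_equal(h$aln_len, 100L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$score, 100L)
  expect_equal(h$q_start, 0L)
  expect_equal(h$q_end, 100L)
  expect_equal(h$r_start, 400L)
  expect_equal(h$r_end, 500L)
})

test_that("planted substitutions are counted as mismatches", {
  set.seed(2)
  for (i in 1:10) {
    base <- rand_dna(100)
    ch <- strsplit(base, "")[[1]]
    pos <- sample(10:90, 5)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    q <- paste(ch, collapse = "")
    ref <- paste0(rand_dna(300), base, rand_dna(300))
    h <- local_align(q, ref)
    expect_equal(sum(h$mismatches), 5L)
  }
})

test_that("reverse-strand homology is found with forward-query coordinates", {
  set.seed(3)
  q <- rand_dna(120)
  rcq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  ref <- paste0(rand_dna(200), rcq, rand_dna(200))
  h <- local_align(q, ref)
  expect_equal(h$strand[1], "-")
  expect_equal(h$q_start[1], 0L)
  expect_equal(h$q_end[1], 120L)
  expect_equal(h$r_start[1], 200L)
  expect_equal(h$r_end[1], 320L)
})

test_that("empty sequences are rejected", {
  expect_error(local_align("", "ACGT"), "empty query")
  expect_error(local_align("ACGT", ""), "empty reference")
})

test_that("conservation metrics follow their definitions", {
  one <- data.table::data.table(q_start = 0L, q_end = 250L, r_start = 0L,
                                r_end = 250L, aln_len = 250L,
                                mismatches = 10L, gap_opens = 0L,
                                score = 230L, strand = "+", evalue = 1e-10)
  met <- conservation_metrics(one, 500)
  expect_equal(met$B, 0.5)
  expect_equal(met$M, 0.04)
  expect_true(met$conserved)

  short <- data.table::copy(one)[, `:=`(q_end = 49L, aln_len = 49L,
                                        mismatches = 0L)]
  met <- conservation_metrics(short, 500)
  expect_equal(met$B, 0.098)
  expect_false(met$conserved)   # 49/500 bp is just under the 10% rule

  met <- conservation_metrics(NULL, 500)
  expect_equal(met$B, 0)
  expect_true(is.na(met$M))     # unBLASTed

  # identical full-length copy end to end
  set.seed(4)
  q <- rand_dna(300)
  met <- acr_vs_region(q, paste0(rand_dna(100), q, rand_dna(100)))
  expect_equal(met$B, 1)
  expect_equal(met$M, 0)
})

test_that("greedy HSP selection never double-counts query coverage", {
  hsps <- data.table::data.table(
    q_start = c(0L, 100L, 150L), q_end = c(200L, 300L, 260L),
    r_start = 0L, r_end = 1L, aln_len = c(200L, 200L, 110L),
    mismatches = c(0L, 20L, 0L), gap_opens = 0L,
    score = c(200L, 160L, 110L), strand = "+", evalue = 0)
  met <- conservation_metrics(hsps, 400)
  # best HSP covers [0,200); [100,300) overlaps and is skipped; [150,260) too
  expect_equal(met$B, 0.5)
  expect_equal(met$M, 0)
  expect_equal(met$n_hsps, 1L)
})

test_that("nearest-gene association uses distance then lexicographic ties", {
  genes <- data.table::data.table(
    gene_id = c("gB", "gA", "gC"), chrom = "chr1",
    start = c(1000L, 5000L, 9000L), end = c(2000L, 6000L, 10000L),
    strand = "+")
  acrs <- data.table::data.table(
    acr_id = c("near_gB", "inside_gA", "tie"), chrom = "chr1",
    start = c(2100L, 5200L, 3500L), end = c(2200L, 5300L, 3501L),
    tissue = NA_character_, ct_label = NA_character_)
  # place the tie ACR so its gap to gB's end equals its gap to gA's start
  acrs$start[3] <- 3499L; acrs$end[3] <- 3501L
  a <- associate_acrs(acrs, genes)
  expect_equal(a$gene_id[a$acr_id == "near_gB"], "gB")
  expect_equal(a$gene_id[a$acr_id == "inside_gA"], "gA")
  expect_equal(a$distance[a$acr_id == "inside_gA"], 0L)
  # brute-force check of the tie rule
  d_gB <- 3499 - 2000; d_gA <- 5000 - 3501
  expect_equal(d_gB, d_gA)
  expect_equal(a$gene_id[a$acr_id == "tie"], "gA")

  acrs2 <- rbind(acrs, data.table::data.table(
    acr_id = "lost", chrom = "chrX", start = 0L, end = 10L,
    tissue = NA_character_, ct_label = NA_character_))
  expect_warning(a2 <- associate_acrs(acrs2, genes), "unassigned")
  expect_true(is.na(a2$gene_id[a2$acr_id == "lost"]))
})

test_that("reference regions span neighbor to neighbor with clipping", {
  genes <- data.table::data.table(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    start = c(0L, 400L, 900L), end = c(100L, 600L, 1000L), strand = "+")
  lens <- c(chr1 = 1200L)
  reg <- reference_region("gB", genes, lens)
  expect_equal(c(reg$start, reg$end), c(0L, 1000L))
  reg <- reference_region("gA", genes, lens)       # first gene: clip to 0
  expect_equal(c(reg$start, reg$end), c(0L, 600L))
  reg <- reference_region("gC", genes, lens)       # last gene: clip to end
  expect_equal(c(reg$start, reg$end), c(400L, 1200L))
  expect_error(reference_region("gX", genes, lens), "not found")
})

test_that("conservation counts map to unique/two-copy/multi-copy states", {
  expect_equal(conservation_state(0:3),
               c("unique", "two_copy", "multi_copy", "multi_copy"))
  expect_error(conservation_state(4))
})

test_that("external tabular hits reproduce built-in conservation metrics", {
  set.seed(5)
  q <- rand_dna(200)
  ref <- paste0(rand_dna(150), q, rand_dna(150))
  h <- local_align(q, ref)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("acr1\tref1\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g",
                     100 * (1 - h$mismatches / h$aln_len), h$aln_len,
                     h$mismatches, h$gap_opens, h$q_start + 1L, h$q_end,
                     h$r_start + 1L, h$r_end, h$evalue, h$score), f)
  ext <- read_tabular_hits(f)
  expect_equal(ext$q_start, h$q_start)
  expect_equal(ext$r_end, h$r_end)
  met_ext <- conservation_metrics(ext, 200)
  met_int <- conservation_metrics(h, 200)
  expect_equal(met_ext$B, met_int$B)
  expect_equal(met_ext$M, met_int$M)
})

test_that("pair summaries report conserved/unBLASTed fractions and count groups", {
  pair <- data.table::data.table(gene1 = "g1", gene2 = "g2")
  cons <- data.table::data.table(
    acr_id = c("a1", "a2", "a3", "a4"),
    source_gene = c("g1", "g1", "g1", "g2"),
    target_gene = c("g2", "g2", "g2", "g1"),
    B = c(1.0, 0.5, 0, 0.9), M = c(0, 0.04, NA, 0.01),
    conserved = c(TRUE, TRUE, FALSE, TRUE))
  s <- pair_acr_summary(pair, cons)
  expect_equal(s$frac_conserved, 3 / 4)
  expect_equal(s$frac_unblasted, 1 / 4)
  expect_equal(s$large_count, 3L)
  expect_equal(s$small_count, 1L)
  expect_equal(s$mean_B_conserved, mean(c(1, 0.5, 0.9)))
  s0 <- pair_acr_summary(pair, cons[0])
  expect_true(is.na(s0$frac_conserved))
  expect_equal(s0$n_acrs, 0L)
})
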