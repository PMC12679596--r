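test_that("mutate_seq plants the expected substitution fraction", {
  set.seed(1)
  s <- rand_dna(5000)
  m <- mutate_seq(s, 0.05)
  diff <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  # binomial 99% interval around 0.05 * 5000 = 250
  expect_gt(diff, stats::qbinom(0.005, 5000, 0.05))
  expect_lt(diff, stats::qbinom(0.995, 5000, 0.05))
  # one contiguous block deletion
  d <- mutate_seq(s, 0, del_frac = 0.2)
  expect_equal(nchar(d), 4000)
})

test_that("no-mutation limit copies partner ACRs verbatim", {
  set.seed(3)
  cfg <- synth_config(n_pairs = 5, n_quads = 0, sub_rate = 0,
                      del_frac = 0, p_acr_loss = 0, p_de_novo = 0)
  sim <- gen_duplicated_genome(cfg)
  tru <- sim$truth$pair_acrs
  expect_true(all(tru$partner_state == "retained"))
  for (i in seq_len(nrow(tru))) {
    a1 <- sim$acrs[sim$acrs$acr_id == tru$acr_id[i]]
    a2 <- sim$acrs[sim$acrs$acr_id == sub("A\\.acr", "B.acr", tru$acr_id[i])]
    s1 <- as.character(Biostrings::subseq(sim$genome[[a1$chrom]],
                                          a1$start + 1, a1$end))
    s2 <- as.character(Biostrings::subseq(sim$genome[[a2$chrom]],
                                          a2$start + 1, a2$end))
    expect_identical(s1, s2)
  }
})

test_that("total ACR loss leaves the partner locus without copies", {
  set.seed(4)
  cfg <- synth_config(n_pairs = 5, n_quads = 0, p_acr_loss = 1, p_de_novo = 0)
  sim <- gen_duplicated_genome(cfg)
  expect_true(all(sim$truth$pair_acrs$partner_state == "lost"))
  expect_false(any(grepl("B\\.acr", sim$acrs$acr_id)))
})

test_that("planted substitution rate is realized on ACR copies", {
  set.seed(5)
  mu <- 0.05
  cfg <- synth_config(n_pairs = 10, n_quads = 0, sub_rate = mu, del_frac = 0,
                      p_acr_loss = 0, p_de_novo = 0,
                      acr_len_range = c(500L, 500L), acrs_per_gene = c(2L, 2L))
  sim <- gen_duplicated_genome(cfg)
  nsub <- 0L; ntot <- 0L
  for (id in sim$truth$pair_acrs$acr_id) {
    a1 <- sim$acrs[sim$acrs$acr_id == id]
    a2 <- sim$acrs[sim$acrs$acr_id == sub("A\\.acr", "B.acr", id)]
    s1 <- strsplit(as.character(Biostrings::subseq(
      sim$genome[[a1$chrom]], a1$start + 1, a1$end)), "")[[1]]
    s2 <- strsplit(as.character(Biostrings::subseq(
      sim$genome[[a2$chrom]], a2$start + 1, a2$end)), "")[[1]]
    nsub <- nsub + sum(s1 != s2); ntot <- ntot + length(s1)
  }
  expect_gt(nsub, stats::qbinom(0.005, ntot, mu))
  expect_lt(nsub, stats::qbinom(0.995, ntot, mu))
})

test_that("identical seeds give identical synthetic outputs", {
  gen <- function() {
    set.seed(77)
    cfg <- synth_config(n_pairs = 4, n_quads = 2)
    sim <- gen_duplicated_genome(cfg)
    expr <- gen_expression(cfg, sim$pairs)
    list(g = as.character(sim$genome), a = sim$acrs,
         c = expr$counts[[1]]$counts, t = expr$truth)
  }
  expect_identical(gen(), gen())
})

test_that("planted mono and non expression zero the right genes", {
  set.seed(6)
  pairs <- data.table::data.table(gene1 = c("a1", "b1"), gene2 = c("a2", "b2"))
  cfg <- synth_config(n_pairs = 2, tissues = "root",
                      pattern_mix = c(dosage_balanced = 0, paralogue_dominance = 0,
                                      specialization = 0, divergence = 0,
                                      others = 0, mono_expressed = 1,
                                      non_expressed = 0))
  e <- gen_expression(cfg, pairs)
  m <- e$counts$root$counts
  zero <- rowSums(m) == 0
  # exactly one gene of each pair silent
  expect_equal(unname(zero["a1"] + zero["a2"]), 1)
  expect_equal(unname(zero["b1"] + zero["b2"]), 1)

  cfg$pattern_mix <- c(dosage_balanced = 0, paralogue_dominance = 0,
                       specialization = 0, divergence = 0, others = 0,
                       mono_expressed = 0, non_expressed = 1)
  e <- gen_expression(cfg, pairs)
  expect_true(all(e$counts$root$counts == 0))
})

test_that("scenario vectors realize the planted agreement structure", {
  set.seed(8)
  v1 <- scenario_vectors(1, 16)
  expect_equal(nrow(unique(v1)), 1L)            # all four identical
  v3 <- scenario_vectors(3, 16)
  expect_equal(nrow(unique(v3)), 2L)
  expect_equal(sort(table(apply(v3, 1, paste, collapse = ""))),
               structure(c(1L, 3L), class = "table",
                         dim = 2L, dimnames = NULL),
               ignore_attr = TRUE)              # one gene differs from three
  v5 <- scenario_vectors(5, 16)
  expect_equal(nrow(unique(v5)), 4L)            # pairwise distinct
})

test_that("expression generation needs at least 3 cell types", {
  cfg <- synth_config(cell_types = 2L)
  expect_error(gen_expression(cfg, data.table::data.table(gene1 = "a", gene2 = "b")),
               "3 cell types")
})

test_that("bit flipping perturbs exactly the requested fraction", {
  set.seed(9)
  m <- matrix(0L, 10, 10)
  f <- flip_bits(m, 0.05)
  expect_equal(sum(f != m), 5L)
})
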