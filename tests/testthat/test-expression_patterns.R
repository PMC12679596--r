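test_that("replicate QC keeps concordant and drops discordant cell types", {
  set.seed(1)
  g <- 50
  good <- rpois(g, 100)
  m <- cbind(good, good,                         # rho = 1
             good, rev(sort(good))[rank(good)],  # anti-ranked, rho = -1
             rpois(g, 100), rpois(g, 100))       # independent
  colnames(m) <- c("a.r1", "a.r2", "b.r1", "b.r2", "c.r1", "c.r2")
  rownames(m) <- paste0("g", 1:g)
  cc <- make_counts(m)
  qc <- qc_cell_types(cc)
  expect_true("a" %in% qc$cell_type)
  expect_false("b" %in% qc$cell_type)
  expect_true("b" %in% attr(qc, "removed"))

  # boundary: a correlation exactly at the cutoff fails ("or below"),
  # so even the perfect replicate (rho = 1) is removed at rho_min = 1
  expect_error(qc_cell_types(cc, rho_min = 1), "no cell types pass QC")
})

test_that("CPM normalization matches its definition and sums to 1e6", {
  m <- matrix(c(10L, 90L), 2, 1, dimnames = list(c("g1", "g2"), "a.r1"))
  expect_equal(unname(cpm_normalize(m)[, 1]), c(1e5, 9e5))
  G <- 40
  m2 <- matrix(1L, G, 2, dimnames = list(paste0("g", 1:G), c("a.r1", "a.r2")))
  expect_true(all(cpm_normalize(m2) == 1e6 / G))
  set.seed(2)
  m3 <- matrix(rpois(300, 30) + 1L, 50,
               dimnames = list(paste0("g", 1:50), paste0("a.r", 1:6)))
  expect_equal(unname(colSums(cpm_normalize(m3))), rep(1e6, 6),
               tolerance = 1e-6)
  m3[, 1] <- 0L
  expect_error(cpm_normalize(m3), "a.r1")
})

test_that("low-expression filter applies the CPM >= 1 in >= 2 samples rule", {
  m <- matrix(0L, 3, 4, dimnames = list(c("keep", "drop", "zero"),
                                        c("a.r1", "a.r2", "b.r1", "b.r2")))
  m["keep", 1:3] <- 500L
  m["drop", 1] <- 500L
  m[1, 4] <- 1L  # avoid zero library
  cpm <- cpm_normalize(m)
  fl <- filter_low_expression(cpm, m)
  expect_true("keep" %in% fl$retained)
  expect_true("drop" %in% fl$dropped)
  expect_equal(fl$non_expressed, "zero")
})

test_that("pair statistics recover closed-form values", {
  cts <- paste0("ct", 1:4)
  # g5 breaks the proportionality of library sizes so CPM profiles keep
  # their shape across cell types
  means <- rbind(g1 = c(1000, 2000, 4000, 8000),
                 g2 = c(1000, 2000, 4000, 8000),
                 g3 = 4 * c(1000, 2000, 4000, 8000),
                 g4 = 0,
                 g5 = 3000)
  colnames(means) <- cts
  cc <- counts_from_means(means)
  cpm <- cpm_normalize(cc)
  # identical profiles
  st <- pair_stats(cpm, cc$cell_type, "g1", "g2")
  expect_equal(st$r, 1)
  expect_equal(st$m, 0)
  expect_equal(st$s, 0)
  # constant 4-fold offset: m -> log2(4) = 2 at high counts
  st <- pair_stats(cpm, cc$cell_type, "g3", "g1")
  expect_gt(st$r, 0.999)
  expect_equal(st$m, 2, tolerance = 0.01)
  expect_lt(st$s, 0.01)
  # silent partner: coexpression undefined
  st <- pair_stats(cpm, cc$cell_type, "g1", "g4")
  expect_true(is.na(st$r))
  expect_true(st$expressed1)
  expect_false(st$expressed2)
  expect_error(pair_stats(cpm, rep("x", ncol(cpm)), "g1", "g2"),
               "3 cell types")
})

test_that("pattern rules classify the documented example triples", {
  cl <- function(r, m, s) {
    classify_pair(list(r = r, m = m, s = s,
                       expressed1 = TRUE, expressed2 = TRUE))$pattern
  }
  expect_equal(cl(0.95, 0.5, 0.3), "dosage_balanced")
  expect_equal(cl(0.95, 2.0, 0.3), "paralogue_dominance")
  expect_equal(cl(0.95, 2.0, 1.5), "specialization")
  expect_equal(cl(0.3, 2.0, 1.5), "divergence")
  expect_equal(cl(0.7, 2.0, 0.5), "others")
  expect_equal(cl(0.95, 0.5, 1.2), "others")  # gap left by the rules
  # boundaries are strict
  expect_equal(cl(0.9, 0.5, 0.5), "others")
  expect_equal(cl(0.5, 2, 2), "others")
  # expression states take precedence
  expect_equal(classify_pair(list(r = NA, m = NA, s = NA, expressed1 = FALSE,
                                  expressed2 = FALSE))$pattern, "non_expressed")
  expect_equal(classify_pair(list(r = NA, m = NA, s = NA, expressed1 = TRUE,
                                  expressed2 = FALSE))$pattern, "mono_expressed")
})

test_that("simplified categories are a pure function of the pattern", {
  expect_equal(simplify_pattern(c("dosage_balanced", "paralogue_dominance",
                                  "specialization")),
               rep("correlated", 3))
  expect_equal(simplify_pattern(c("divergence", "others")),
               rep("uncorrelated", 2))
  expect_equal(simplify_pattern(c("non_expressed", "mono_expressed")),
               c("non", "mono"))
  expect_error(simplify_pattern("nope"), "unknown pattern")
})

test_that("shared-category counting treats non-expression as a distinct case", {
  expect_equal(shared_categories(rep("correlated", 4)), 1L)
  expect_equal(shared_categories(c("non", "non", "correlated", "correlated")), 1L)
  expect_equal(shared_categories(c("mono", "correlated", "uncorrelated", "non")), 3L)
  expect_equal(shared_categories(rep("non", 4)), 1L)
  # permutation invariance
  set.seed(3)
  for (i in 1:20) {
    v <- sample(c("non", "mono", "correlated", "uncorrelated"), 4, replace = TRUE)
    expect_equal(shared_categories(v), shared_categories(sample(v)))
  }
  expect_error(shared_categories(c("non", NA, "mono", "mono")))
})

test_that("cell-type-specific genes are flagged where planted", {
  set.seed(4)
  G <- 60
  base <- rpois(G, 400) + 50
  m <- matrix(0L, G, 8)
  for (ct in 1:4) for (r in 1:2) {
    mu <- base
    if (ct == 1) mu[1:5] <- mu[1:5] * 100   # strong planted enrichment
    m[, (ct - 1) * 2 + r] <- rnbinom(G, mu = mu, size = 20)
  }
  rownames(m) <- paste0("g", 1:G)
  colnames(m) <- as.vector(t(outer(paste0("ct", 1:4), c("r1", "r2"),
                                   paste, sep = ".")))
  de <- celltype_specific_genes(make_counts(m))
  expect_true(all(de$specific[1:5, "ct1"] == 1L))
  expect_true(all(de$is_specific[1:5]))

  # identical counts everywhere: nothing is specific
  m2 <- matrix(500L, G, 8, dimnames = dimnames(m))
  de2 <- celltype_specific_genes(make_counts(m2))
  expect_true(all(de2$specific == 0L))
  expect_error(celltype_specific_genes(
    make_counts(m[, 1:2, drop = FALSE])), "2 cell types")
})

test_that("planted patterns are recovered per tissue by the classifier", {
  set.seed(5)
  n <- 60
  pairs <- data.table::data.table(gene1 = sprintf("p%03dA", 1:n),
                                  gene2 = sprintf("p%03dB", 1:n))
  cfg <- synth_config(n_pairs = n, tissues = "root", noise = "none")
  e <- gen_expression(cfg, pairs)
  calls <- classify_pairs(e$counts$root, pairs, tissue = "root")
  truth <- e$truth[e$truth$tissue == "root"]
  mm <- merge(calls, truth, by = c("gene1", "gene2"))
  expect_equal(mean(mm$pattern.x == mm$pattern.y), 1)
})
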