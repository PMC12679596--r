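test_that("recent pairs come from cherries of the gene tree", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  rp <- recent_pair_partition(t1, c("A", "B", "C", "D"))
  expect_true(any(vapply(rp, setequal, logical(1), c("A", "B"))))
  expect_true(any(vapply(rp, setequal, logical(1), c("C", "D"))))

  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  rp <- recent_pair_partition(t2, c("A", "B", "C", "D"))
  expect_true(any(vapply(rp, setequal, logical(1), c("A", "C"))))

  # caterpillar topology has a single cherry: unresolved
  t3 <- ape::read.tree(text = "(((A,B),C),D);")
  expect_warning(rp <- recent_pair_partition(t3, c("A", "B", "C", "D")),
                 "unresolved")
  expect_null(rp)

  # extra family members are pruned before cherry detection
  t4 <- ape::read.tree(text = "(((A,B),(C,D)),out);")
  rp <- recent_pair_partition(t4, c("A", "B", "C", "D"))
  expect_length(rp, 2L)
  expect_error(recent_pair_partition(t1, c("A", "B", "C", "Z")), "missing")
})

test_that("specificity matrices drop all-zero rows before clustering", {
  m <- rbind(g1 = c(1L, 1L, 0L), g2 = c(1L, 0L, 1L),
             g3 = c(0L, 0L, 0L), g4 = c(1L, 1L, 0L))
  sm <- specificity_matrix(m)
  expect_equal(rownames(sm$mat), c("g1", "g2", "g4"))
  expect_equal(sm$zero_genes, "g3")
  # binary distance is the Jaccard distance on presence sets
  d <- stats::dist(sm$mat[c("g1", "g2"), ], method = "binary")
  expect_equal(as.numeric(d), 2 / 3)
})

test_that("Ward.D2 heights match the hand-computed Lance-Williams recurrence", {
  dm <- matrix(c(0, 2, 6, 10,
                 2, 0, 5, 9,
                 6, 5, 0, 4,
                 10, 9, 4, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  d <- stats::as.dist(dm)
  hc <- stats::hclust(d, method = "ward.D2")
  # manual recurrence on squared distances:
  # merge (a,b) at h1 = 2; merge (c,d) at h2 = 4; then
  # d(ab, cd)^2 = [(2+2)*d_ac^2 + ... ] via two Lance-Williams steps
  d_ab_c2 <- ((1 + 1) * 36 + (1 + 1) * 25 - 1 * 4) / 3
  d_ab_d2 <- ((1 + 1) * 100 + (1 + 1) * 81 - 1 * 4) / 3
  d_ab_cd2 <- ((2 + 1) * d_ab_c2 + (2 + 1) * d_ab_d2 - 2 * 16) / 4
  expect_equal(hc$height, c(2, 4, sqrt(d_ab_cd2)))
})

test_that("clustering recovers planted k on clean profiles", {
  ident <- matrix(rep(c(1L, 1L, 0L, 0L), each = 4), 4,
                  dimnames = list(paste0("g", 1:4), NULL))
  cl <- cluster_genes(ident)
  expect_equal(cl$k, 1L)

  two <- rbind(g1 = c(1L, 1L, 0L, 0L), g2 = c(1L, 1L, 0L, 0L),
               g3 = c(0L, 0L, 1L, 1L), g4 = c(0L, 0L, 1L, 1L))
  cl <- cluster_genes(two)
  expect_equal(cl$k, 2L)
  expect_equal(sort(unname(table(cl$partition))), c(2L, 2L),
               ignore_attr = TRUE)
  expect_equal(unname(cl$sil["2"]), 1)

  # all four distinct, equidistant: no silhouette structure -> all split
  four <- diag(4L); rownames(four) <- paste0("g", 1:4)
  cl <- cluster_genes(four)
  expect_equal(cl$k, 4L)
})

test_that("exact Ward partitions minimize the objective over all partitions", {
  set.seed(4)
  enum_all <- function(n) {
    # Bell(4) = 15 partitions via recursive block assignment
    out <- list()
    rec <- function(assign, i) {
      if (i > n) { out[[length(out) + 1]] <<- assign; return(invisible()) }
      for (b in seq_len(max(assign, 0) + 1)) rec(c(assign, b), i + 1)
    }
    rec(integer(0), 1)
    out
  }
  obj <- function(dm2, p) {
    sum(vapply(split(seq_along(p), p), function(idx) {
      if (length(idx) < 2) return(0)
      sum(dm2[idx, idx]) / (2 * length(idx))
    }, numeric(1)))
  }
  parts15 <- enum_all(4)
  for (i in 1:50) {
    m <- matrix(rbinom(4 * 8, 1, 0.5), 4, dimnames = list(paste0("g", 1:4), NULL))
    d <- stats::dist(m, method = "binary")
    if (anyNA(d)) next
    dm2 <- as.matrix(d)^2
    for (k in 2:3) {
      mine <- dupdiverge:::ward_exact_partition(d, k)
      cand <- Filter(function(p) length(unique(p)) == k, parts15)
      best <- min(vapply(cand, function(p) obj(dm2, p), numeric(1)))
      expect_equal(obj(dm2, mine), best)
    }
  }
})

test_that("cluster structure maps to the five scenarios", {
  rp <- list(c("A", "B"), c("C", "D"))
  p <- function(v) stats::setNames(v, c("A", "B", "C", "D"))
  expect_equal(call_trajectory(p(c(1, 1, 1, 1)), recent_pairs = rp)$scenario,
               "before_first_wgd")
  expect_equal(call_trajectory(p(c(1, 1, 2, 2)), recent_pairs = rp)$scenario,
               "before_second_wgd")
  # strict mode: a 2:2 split across the recent pairs is not scenario 2
  expect_equal(call_trajectory(p(c(1, 2, 1, 2)), recent_pairs = rp)$scenario,
               "unresolved")
  expect_equal(call_trajectory(p(c(1, 2, 1, 2)), recent_pairs = rp,
                               strict = FALSE)$scenario, "before_second_wgd")
  expect_equal(call_trajectory(p(c(1, 1, 1, 2)), recent_pairs = rp)$scenario,
               "after_second_wgd")
  expect_equal(call_trajectory(p(c(1, 1, 2, 3)), recent_pairs = rp)$scenario,
               "combination")
  expect_equal(call_trajectory(p(c(1, 2, 3, 4)), recent_pairs = rp)$scenario,
               "complex")
})

test_that("zero rows rejoin as one implicit no-specificity group", {
  rp <- list(c("A", "B"), c("C", "D"))
  part <- stats::setNames(c(1, 1, 1), c("A", "B", "C"))
  out <- call_trajectory(part, zero_genes = "D", recent_pairs = rp)
  expect_equal(out$sizes, c(1L, 3L))
  expect_equal(out$scenario, "after_second_wgd")
  # two zero rows forming the second half of a 2:2 split obey strict mode
  part2 <- stats::setNames(c(1, 1), c("A", "B"))
  out2 <- call_trajectory(part2, zero_genes = c("C", "D"), recent_pairs = rp)
  expect_equal(out2$scenario, "before_second_wgd")
})

test_that("scenario calls are invariant to gene relabeling within clusters", {
  set.seed(5)
  rp <- list(c("A", "B"), c("C", "D"))
  for (i in 1:20) {
    v <- sample(list(c(1, 1, 1, 1), c(1, 1, 2, 2), c(1, 1, 1, 2),
                     c(1, 1, 2, 3), c(1, 2, 3, 4)), 1)[[1]]
    part <- stats::setNames(v, c("A", "B", "C", "D"))
    relab <- stats::setNames(match(v, unique(sample(unique(v)))), names(part))
    expect_equal(call_trajectory(part, recent_pairs = rp)$scenario,
                 call_trajectory(relab, recent_pairs = rp)$scenario)
  }
})

test_that("end-to-end inference recovers planted scenarios at zero noise", {
  set.seed(6)
  n <- 50
  quads <- data.table::data.table(
    set_id = sprintf("Q%03d", 1:n),
    gene1 = sprintf("Q%03dA", 1:n), gene2 = sprintf("Q%03dB", 1:n),
    gene3 = sprintf("Q%03dC", 1:n), gene4 = sprintf("Q%03dD", 1:n))
  cfg <- synth_config(n_quads = n)
  traj <- gen_trajectories(cfg, quads)
  ok <- vapply(seq_len(n), function(i) {
    g <- unlist(quads[i, -1], use.names = FALSE)
    rp <- list(g[1:2], g[3:4])
    infer_trajectory(traj$specificity[[i]], rp)$scenario ==
      scen_names[traj$truth$scenario[i]]
  }, logical(1))
  expect_true(all(ok))
})
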