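# Clustering of 4-gene sets by binary cell-type-specificity profiles and
# mapping of cluster structure to evolutionary scenarios of cell-type-
# specific expression.

TRAJ_SCENARIOS <- c("before_first_wgd", "before_second_wgd",
                    "after_second_wgd", "combination", "complex",
                    "unresolved")

#' Recent-pair partition of a quad from its gene tree
#'
#' The two cherries (sister-leaf pairs) over the quad's genes define the
#' recently duplicated pairs; the four cross pairs are ancestral. A
#' topology without two cherries over the four genes (caterpillar,
#' polytomy) cannot be partitioned and returns NULL with a warning.
#'
#' @param tree \code{phylo} tree containing the four genes as leaves.
#' @param quad_genes Character vector of the four gene ids.
#' @return List of two character pairs, or NULL when unresolved.
#' @export
recent_pair_partition <- function(tree, quad_genes) {
  stopifnot(length(quad_genes) == 4L)
  if (!all(quad_genes %in% tree$tip.label)) {
    stop("quad genes missing from tree: ",
         paste(setdiff(quad_genes, tree$tip.label), collapse = ", "))
  }
  if (length(tree$tip.label) > 4L) {
    tree <- ape::keep.tip(tree, quad_genes)
  }
  ntip <- length(tree$tip.label)
  cherries <- list()
  for (node in unique(tree$edge[, 1L])) {
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    if (length(kids) == 2L && all(kids <= ntip)) {
      cherries[[length(cherries) + 1L]] <- sort(tree$tip.label[kids])
    }
  }
  cherries <- cherries[vapply(cherries, function(p) all(p %in% quad_genes),
                              logical(1))]
  if (length(cherries) != 2L ||
      !setequal(unlist(cherries), quad_genes)) {
    warning("quad without two cherries over its genes; recent pairs unresolved")
    return(NULL)
  }
  cherries
}

#' Specificity matrix for clustering
#'
#' Rows are genes, columns cell types, entries the presence (1) or
#' absence (0) of significant differential expression. Rows with no
#' variation (all zeros) are removed before clustering and accounted for
#' separately when scenario sizes are computed.
#'
#' @param de_flags Binary gene x cell-type matrix.
#' @return List: \code{mat} (rows with signal), \code{zero_genes}
#'   (removed all-zero rows).
#' @export
specificity_matrix <- function(de_flags) {
  stopifnot(is.matrix(de_flags), !is.null(rownames(de_flags)))
  zero <- rowSums(de_flags != 0) == 0
  list(mat = de_flags[!zero, , drop = FALSE],
       zero_genes = rownames(de_flags)[zero])
}

#' Cluster genes by binary specificity profiles
#'
#' Pairwise Jaccard distances, Ward.D2 agglomeration, and selection of k:
#' when all pairwise distances are at most \code{k1_distance} the genes
#' form a single cluster; otherwise k in 2..n is chosen to maximize the
#' average silhouette width, falling back to k = n (all genes distinct)
#' when no candidate reaches \code{s_min} — silhouette near zero
#' everywhere means no grouping structure, not one group. Within-cluster
#' sums of squared distances (the elbow curve) are reported alongside.
#'
#' @param mat Binary matrix (>= 1 row).
#' @param k1_distance All pairwise distances at or below this give k = 1.
#' @param s_min Minimum average silhouette width to accept a k < n.
#' @return List: \code{k}, \code{partition} (named integer vector),
#'   \code{hclust} (NULL when n < 2), \code{sil} (average widths per
#'   candidate k), \code{wss}.
#' @export
cluster_genes <- function(mat, k1_distance = 0.35, s_min = 0.25) {
  n <- nrow(mat)
  stopifnot(n >= 1L)
  if (n == 1L) {
    return(list(k = 1L, partition = stats::setNames(1L, rownames(mat)),
                hclust = NULL, sil = NULL, wss = NULL))
  }
  d <- stats::dist(mat, method = "binary")
  if (all(d <= k1_distance)) {
    return(list(k = 1L,
                partition = stats::setNames(rep(1L, n), rownames(mat)),
                hclust = NULL, sil = NULL, wss = NULL))
  }
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- 2:n
  # with at most 4 rows the Ward objective is minimized exactly over all
  # partitions of each size, which sidesteps the occasional greedy
  # suboptimality of agglomeration; the dendrogram is still reported
  parts <- lapply(ks, function(k) {
    if (n <= 4L) ward_exact_partition(d, k) else stats::cutree(hc, k = k)
  })
  sil <- vapply(seq_along(ks), function(i) {
    if (ks[i] == n) return(0)
    mean(cluster::silhouette(parts[[i]], d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  wss <- vapply(seq_along(ks), function(i) ward_objective(d, parts[[i]]),
                numeric(1))
  names(wss) <- ks
  # exact silhouette ties are broken toward the larger k: when the width
  # cannot separate a coarse from a fine partition, the finer one carries
  # the information
  best <- ks[max(which(sil == max(sil)))]
  if (max(sil) < s_min) best <- n
  part <- parts[[match(best, ks)]]
  names(part) <- rownames(mat)
  list(k = best, partition = part, hclust = hc, sil = sil, wss = wss)
}

# Ward objective of a partition: sum over clusters of the within-cluster
# sum of squared dissimilarities divided by cluster size.
ward_objective <- function(d, part) {
  dm <- as.matrix(d)^2
  sum(vapply(split(seq_along(part), part), function(idx) {
    if (length(idx) < 2L) return(0)
    sum(dm[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
}

# Exhaustive Ward-objective minimization over all partitions of n items
# (n <= 4: at most 15 partitions) into exactly k blocks. Deterministic
# tie-break: first minimizer in canonical enumeration order.
ward_exact_partition <- function(d, k) {
  n <- attr(d, "Size")
  stopifnot(n <= 4L)
  parts <- enumerate_partitions(n, k)
  objs <- vapply(parts, function(p) ward_objective(d, p), numeric(1))
  parts[[which.min(objs)]]
}

enumerate_partitions <- function(n, k) {
  out <- list()
  assign <- integer(n)
  recur <- function(i, used) {
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (b in seq_len(min(used + 1L, k))) {
      assign[i] <<- b
      recur(i + 1L, max(used, b))
    }
    assign[i] <<- 0L
  }
  recur(1L, 0L)
  out
}

#' Map a cluster partition to an evolutionary scenario
#'
#' All-zero rows removed before clustering rejoin as one implicit
#' no-specificity group for size accounting. Mapping on the resulting
#' (k, sizes): k=1 -> before_first_wgd; k=2 with a 2:2 split ->
#' before_second_wgd (in strict mode the split must coincide with the
#' recent-pair partition, otherwise unresolved); k=2 with 1:3 ->
#' after_second_wgd; k=3 with 1:2:1 -> combination; k=4 -> complex.
#'
#' @param partition Named integer vector, gene -> cluster, for the
#'   clustered (non-zero) genes.
#' @param zero_genes Genes removed as all-zero rows.
#' @param recent_pairs Recent-pair partition
#'   ([recent_pair_partition()]), required for strict mode.
#' @param strict When TRUE (default) a 2:2 split not matching the recent
#'   pairs is unresolved rather than before_second_wgd.
#' @return List: \code{scenario}, \code{k}, \code{sizes} (sorted),
#'   \code{groups} (list of gene-id groups).
#' @export
call_trajectory <- function(partition, zero_genes = character(0),
                            recent_pairs = NULL, strict = TRUE) {
  groups <- split(names(partition), partition)
  if (length(zero_genes)) groups <- c(groups, list(zero_genes))
  sizes <- sort(vapply(groups, length, integer(1)))
  k <- length(groups)
  scenario <- if (k == 1L) {
    "before_first_wgd"
  } else if (k == 2L && identical(unname(sizes), c(2L, 2L))) {
    if (strict) {
      if (is.null(recent_pairs)) {
        "unresolved"
      } else {
        match22 <- all(vapply(groups, function(g) {
          any(vapply(recent_pairs, function(p) setequal(g, p), logical(1)))
        }, logical(1)))
        if (match22) "before_second_wgd" else "unresolved"
      }
    } else "before_second_wgd"
  } else if (k == 2L && identical(unname(sizes), c(1L, 3L))) {
    "after_second_wgd"
  } else if (k == 3L && identical(unname(sizes), c(1L, 1L, 2L))) {
    "combination"
  } else if (k == 4L) {
    "complex"
  } else {
    "unresolved"
  }
  list(scenario = scenario, k = k, sizes = unname(sizes), groups = groups)
}

#' Infer the trajectory scenario of one quad
#'
#' Convenience wrapper: specificity matrix -> clustering -> scenario
#' call.
#'
#' @param de_flags Binary 4 x cell-type matrix (rownames = gene ids).
#' @param recent_pairs Recent-pair partition.
#' @param k1_distance,s_min,strict See [cluster_genes()] and
#'   [call_trajectory()].
#' @return As [call_trajectory()], plus \code{clustering}.
#' @export
infer_trajectory <- function(de_flags, recent_pairs = NULL,
                             k1_distance = 0.35, s_min = 0.25,
                             strict = TRUE) {
  sm <- specificity_matrix(de_flags)
  if (nrow(sm$mat) == 0L) {
    stop("no gene with cell-type-specific signal; quad should be filtered out")
  }
  cl <- cluster_genes(sm$mat, k1_distance = k1_distance, s_min = s_min)
  out <- call_trajectory(cl$partition, sm$zero_genes, recent_pairs,
                         strict = strict)
  out$clustering <- cl
  out
}
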