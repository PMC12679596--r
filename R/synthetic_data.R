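# Synthetic genomes, duplicate pairs/quads, pseudobulk counts and
# specificity trajectories with planted ground truth. The generator is the
# study-conditions module: its defaults define the regime every
# downstream stage is validated under.

#' Synthetic-study configuration
#'
#' @param n_pairs Number of duplicated gene pairs.
#' @param n_quads Number of 4-gene whole-genome-duplication sets.
#' @param acr_len_range ACR length range, bp.
#' @param acrs_per_gene Range of ACR counts per gene.
#' @param sub_rate Per-base substitution probability applied to each ACR
#'   copy (pairs) or per branch (quads).
#' @param del_frac Fraction of each retained pair-ACR copy removed as one
#'   contiguous block.
#' @param p_acr_loss Probability a pair ACR has no copy at the partner
#'   locus.
#' @param p_de_novo Probability of one additional de novo ACR at the
#'   partner locus.
#' @param pattern_mix Named proportions over the 7 planted expression
#'   patterns; must sum to 1.
#' @param state_mix Named proportions over planted quad conservation
#'   states (unique / two_copy / multi_copy).
#' @param scenario_mix Proportions over the 5 planted trajectory
#'   scenarios.
#' @param mech_mix Named proportions over duplication-mechanism labels
#'   attached to pairs (labels are metadata here, not computed).
#' @param nb_dispersion Negative-binomial dispersion of count noise.
#' @param noise Count noise model: \code{"nb"}, \code{"poisson"}
#'   (dispersion -> 0 limit) or \code{"none"} (deterministic rounded
#'   means; the zero-noise limit used by exact-recovery checks).
#' @param cell_types Cell types per tissue for pair expression.
#' @param traj_cell_types Cell types for trajectory specificity vectors.
#' @param replicates Replicates per cell type (>= 2).
#' @param tissues Tissue names; the first four are treated as the
#'   developmental stages, tissues 4..7 as the organs (heart-stage seed
#'   belongs to both, as in the motivating design).
#' @param turnover Per-condition probability that an accessible ACR is
#'   absent from one condition's accessibility profile.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_pairs = 200L, n_quads = 50L,
                         acr_len_range = c(200L, 500L),
                         acrs_per_gene = c(1L, 3L),
                         sub_rate = 0.02, del_frac = 0,
                         p_acr_loss = 0.1, p_de_novo = 0.1,
                         pattern_mix = c(dosage_balanced = 0.25,
                                         paralogue_dominance = 0.15,
                                         specialization = 0.10,
                                         divergence = 0.10,
                                         others = 0.10,
                                         mono_expressed = 0.20,
                                         non_expressed = 0.10),
                         state_mix = c(unique = 0.25, two_copy = 0.25,
                                       multi_copy = 0.50),
                         scenario_mix = rep(0.2, 5),
                         mech_mix = c(WGD = 0.503, DSD = 0.379, TRD = 0.06,
                                      TD = 0.035, PD = 0.023),
                         nb_dispersion = 0.05,
                         noise = c("nb", "poisson", "none"),
                         cell_types = 8L, traj_cell_types = 16L,
                         replicates = 2L,
                         tissues = c("globular", "heart", "cotyledon",
                                     "early_maturation", "hypocotyl",
                                     "root", "nodule"),
                         turnover = 0.15) {
  noise <- match.arg(noise)
  stopifnot(sub_rate >= 0, sub_rate <= 1, del_frac >= 0, del_frac < 1,
            p_acr_loss >= 0, p_acr_loss <= 1, p_de_novo >= 0, p_de_novo <= 1,
            replicates >= 2L, turnover >= 0, turnover <= 1)
  if (abs(sum(pattern_mix) - 1) > 1e-8) stop("pattern_mix must sum to 1")
  if (!setequal(names(pattern_mix), PATTERN_LEVELS)) {
    stop("pattern_mix must be named by the 7 pattern labels")
  }
  cfg <- list(n_pairs = n_pairs, n_quads = n_quads,
              acr_len_range = acr_len_range, acrs_per_gene = acrs_per_gene,
              sub_rate = sub_rate, del_frac = del_frac,
              p_acr_loss = p_acr_loss, p_de_novo = p_de_novo,
              pattern_mix = pattern_mix, state_mix = state_mix,
              scenario_mix = scenario_mix, mech_mix = mech_mix,
              nb_dispersion = nb_dispersion, noise = noise,
              cell_types = cell_types, traj_cell_types = traj_cell_types,
              replicates = replicates, tissues = tissues,
              turnover = turnover,
              # locus template (bp): neighbor | gap | ACR window (2 kb
              # upstream of the TSS) | gene | gap | neighbor. The gap
              # between neighbor and ACR window exceeds the window depth,
              # so every ACR is strictly nearest to its own gene
              neighbor_len = 500L, acr_window = 2000L, gene_len = 1000L,
              up_gap = 2500L, down_gap = 1000L, spacer = 2000L)
  class(cfg) <- "synth_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integers on [lo, hi]; safe when lo == hi (sample() would
# otherwise treat the scalar as 1:n)
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

#' Apply substitutions (and optionally one block deletion) to a sequence
#'
#' Each base is substituted with probability \code{mu}, always to a
#' different base, so the expected mismatch fraction against the source
#' equals \code{mu}. With \code{del_frac > 0} one contiguous block of
#' that fraction of the (post-substitution) sequence is removed.
#'
#' @param seq Character scalar over A/C/G/T.
#' @param mu Per-base substitution probability.
#' @param del_frac Fraction deleted as a single block.
#' @return Mutated sequence.
#' @export
mutate_seq <- function(seq, mu, del_frac = 0) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  if (mu > 0) {
    hit <- which(stats::runif(n) < mu)
    if (length(hit)) {
      alt <- c("A", "C", "G", "T")
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1L), "")
    }
  }
  if (del_frac > 0) {
    dlen <- round(del_frac * length(ch))
    if (dlen > 0 && dlen < length(ch)) {
      start <- sample.int(length(ch) - dlen + 1L, 1L)
      ch <- ch[-(start:(start + dlen - 1L))]
    }
  }
  paste(ch, collapse = "")
}

# Draw ACR lengths and within-window offsets for one gene's upstream
# window; returns data.table(offset, len) or errors when the window
# cannot hold them.
place_acrs <- function(cfg, n_acr) {
  lens <- sample_range(cfg$acr_len_range[1L], cfg$acr_len_range[2L], n_acr)
  while (sum(lens) + n_acr * 10L > cfg$acr_window && length(lens) > 1L) {
    lens <- lens[-length(lens)]
  }
  if (sum(lens) + length(lens) * 10L > cfg$acr_window) {
    stop("ACRs cannot fit in the configured upstream window")
  }
  slack <- cfg$acr_window - sum(lens)
  gaps <- floor(slack / (length(lens) + 1L))
  offsets <- cumsum(c(gaps, utils::head(lens + gaps, -1L)))
  data.table::data.table(offset = as.integer(offsets), len = as.integer(lens))
}

locus_len <- function(cfg) {
  cfg$neighbor_len + cfg$up_gap + cfg$acr_window + cfg$gene_len +
    cfg$down_gap + cfg$neighbor_len
}

# Gene/neighbor coordinates for the locus starting at `base` (0-based).
locus_coords <- function(cfg, base) {
  upn <- c(base, base + cfg$neighbor_len)
  win <- c(upn[2L] + cfg$up_gap, upn[2L] + cfg$up_gap + cfg$acr_window)
  gene <- c(win[2L], win[2L] + cfg$gene_len)
  dnn <- c(gene[2L] + cfg$down_gap, gene[2L] + cfg$down_gap + cfg$neighbor_len)
  list(upn = upn, window = win, gene = gene, dnn = dnn)
}

#' Generate a duplicated genome with planted ACR divergence
#'
#' Builds one chromosome per duplicate pair (two loci, each a gene with
#' flanking neighbor genes and ACRs within 2 kb upstream of the TSS) and
#' one per 4-gene set (four loci from two successive duplication events
#' with per-branch substitution, so recent copies diverge less than
#' ancestral ones). Pair ACR copies are substituted at \code{sub_rate},
#' truncated by \code{del_frac}, lost with \code{p_acr_loss}; de novo
#' ACRs appear with \code{p_de_novo}. Quad ACR presence follows the
#' planted conservation state (unique / two_copy / multi_copy).
#'
#' @param cfg A [synth_config()].
#' @return List: \code{genome} (named \code{DNAStringSet}),
#'   \code{chrom_lengths}, \code{genes}, \code{acrs}, \code{pairs},
#'   \code{quads}, \code{trees} (\code{multiPhylo}, one per quad, true
#'   topology \code{((A,B),(C,D))}), and \code{truth} with per-ACR planted
#'   records for pairs (\code{pair_acrs}) and quads (\code{quad_acrs}).
#' @export
gen_duplicated_genome <- function(cfg) {
  genes <- list(); acrs <- list(); seqs <- character(0)
  pair_truth <- list(); quad_truth <- list()
  L <- locus_len(cfg)

  for (i in seq_len(cfg$n_pairs)) {
    chrom <- sprintf("chrP%03d", i)
    clen <- 2L * L + cfg$spacer
    chseq <- random_dna(clen)
    bases <- c(0L, L + cfg$spacer)
    ids <- c(sprintf("P%03dA", i), sprintf("P%03dB", i))
    lc <- lapply(bases, locus_coords, cfg = cfg)
    for (k in 1:2) {
      genes[[length(genes) + 1L]] <- data.table::data.table(
        gene_id = c(paste0(ids[k], ".up"), ids[k], paste0(ids[k], ".dn")),
        chrom = chrom,
        start = c(lc[[k]]$upn[1L], lc[[k]]$gene[1L], lc[[k]]$dnn[1L]),
        end = c(lc[[k]]$upn[2L], lc[[k]]$gene[2L], lc[[k]]$dnn[2L]),
        strand = "+")
    }
    src <- place_acrs(cfg, sample_range(cfg$acrs_per_gene[1L],
                                        cfg$acrs_per_gene[2L]))
    # source ACRs are read off the random chromosome; partner copies are
    # mutated versions spliced into the partner window
    cursor <- 0L
    for (j in seq_len(nrow(src))) {
      s1 <- lc[[1L]]$window[1L] + src$offset[j]
      e1 <- s1 + src$len[j]
      a1 <- sprintf("P%03dA.acr%d", i, j)
      acrs[[length(acrs) + 1L]] <- data.table::data.table(
        acr_id = a1, chrom = chrom, start = s1, end = e1,
        tissue = NA_character_, ct_label = NA_character_)
      lost <- stats::runif(1L) < cfg$p_acr_loss
      if (!lost) {
        cp <- mutate_seq(substr(chseq, s1 + 1L, e1), cfg$sub_rate, cfg$del_frac)
        s2 <- lc[[2L]]$window[1L] + cursor + 10L
        e2 <- s2 + nchar(cp)
        if (e2 > lc[[2L]]$window[2L]) stop("partner ACR overflow in window")
        substr(chseq, s2 + 1L, e2) <- cp
        cursor <- cursor + nchar(cp) + 20L
        acrs[[length(acrs) + 1L]] <- data.table::data.table(
          acr_id = sprintf("P%03dB.acr%d", i, j), chrom = chrom,
          start = s2, end = e2, tissue = NA_character_,
          ct_label = NA_character_)
      }
      pair_truth[[length(pair_truth) + 1L]] <- data.table::data.table(
        acr_id = a1, pair_id = sprintf("P%03d", i), source_gene = ids[1L],
        partner_state = if (lost) "lost" else "retained",
        mu = cfg$sub_rate, del_frac = cfg$del_frac)
    }
    if (stats::runif(1L) < cfg$p_de_novo) {
      # de novo ACR at the partner locus: plain random sequence, no
      # counterpart near the source gene
      dlen <- sample_range(cfg$acr_len_range[1L], cfg$acr_len_range[2L])
      s2 <- lc[[2L]]$window[2L] - dlen
      acrs[[length(acrs) + 1L]] <- data.table::data.table(
        acr_id = sprintf("P%03dB.denovo", i), chrom = chrom, start = s2,
        end = s2 + dlen, tissue = NA_character_, ct_label = NA_character_)
    }
    seqs[chrom] <- chseq
  }

  trees <- vector("list", cfg$n_quads)
  for (i in seq_len(cfg$n_quads)) {
    chrom <- sprintf("chrQ%03d", i)
    clen <- 4L * L + 3L * cfg$spacer
    chseq <- random_dna(clen)
    gl <- c("A", "B", "C", "D")
    ids <- sprintf("Q%03d%s", i, gl)
    bases <- (0:3) * (L + cfg$spacer)
    lc <- lapply(bases, locus_coords, cfg = cfg)
    for (k in 1:4) {
      genes[[length(genes) + 1L]] <- data.table::data.table(
        gene_id = c(paste0(ids[k], ".up"), ids[k], paste0(ids[k], ".dn")),
        chrom = chrom,
        start = c(lc[[k]]$upn[1L], lc[[k]]$gene[1L], lc[[k]]$dnn[1L]),
        end = c(lc[[k]]$upn[2L], lc[[k]]$gene[2L], lc[[k]]$dnn[2L]),
        strand = "+")
    }
    anc <- place_acrs(cfg, sample_range(cfg$acrs_per_gene[1L],
                                        cfg$acrs_per_gene[2L]))
    cursors <- rep(0L, 4L)
    for (j in seq_len(nrow(anc))) {
      state <- sample(names(cfg$state_mix), 1L, prob = cfg$state_mix)
      carriers <- switch(state,
        multi_copy = 1:4,
        two_copy = if (stats::runif(1L) < 0.5) 1:2 else 3:4,
        unique = sample.int(4L, 1L))
      aseq <- random_dna(anc$len[j])
      # two rounds of duplication: per-branch substitutions accumulate
      e1 <- mutate_seq(aseq, cfg$sub_rate)
      e2 <- mutate_seq(aseq, cfg$sub_rate)
      leaf <- list(mutate_seq(e1, cfg$sub_rate), mutate_seq(e1, cfg$sub_rate),
                   mutate_seq(e2, cfg$sub_rate), mutate_seq(e2, cfg$sub_rate))
      cnt <- length(carriers) - 1L
      for (k in carriers) {
        s <- lc[[k]]$window[1L] + cursors[k] + 10L
        e <- s + nchar(leaf[[k]])
        if (e > lc[[k]]$window[2L]) stop("quad ACR overflow in window")
        substr(chseq, s + 1L, e) <- leaf[[k]]
        cursors[k] <- cursors[k] + nchar(leaf[[k]]) + 20L
        aid <- sprintf("Q%03d.anc%d.%s", i, j, gl[k])
        acrs[[length(acrs) + 1L]] <- data.table::data.table(
          acr_id = aid, chrom = chrom, start = s, end = e,
          tissue = NA_character_, ct_label = NA_character_)
        quad_truth[[length(quad_truth) + 1L]] <- data.table::data.table(
          acr_id = aid, set_id = sprintf("Q%03d", i), gene = ids[k],
          planted_state = state, planted_count = cnt,
          origin = if (state == "multi_copy") "ancestral" else
            if (state == "two_copy") "recent" else "none")
      }
    }
    trees[[i]] <- ape::read.tree(text = sprintf(
      "((%s:1,%s:1):1,(%s:1,%s:1):1);", ids[1L], ids[2L], ids[3L], ids[4L]))
    seqs[chrom] <- chseq
  }

  genes <- data.table::rbindlist(genes)
  data.table::setkey(genes, chrom, start)
  pairs <- data.table::data.table(
    pair_id = sprintf("P%03d", seq_len(cfg$n_pairs)),
    gene1 = sprintf("P%03dA", seq_len(cfg$n_pairs)),
    gene2 = sprintf("P%03dB", seq_len(cfg$n_pairs)),
    mechanism = sample(names(cfg$mech_mix), cfg$n_pairs, replace = TRUE,
                       prob = cfg$mech_mix))
  quads <- data.table::data.table(
    set_id = sprintf("Q%03d", seq_len(cfg$n_quads)),
    gene1 = sprintf("Q%03dA", seq_len(cfg$n_quads)),
    gene2 = sprintf("Q%03dB", seq_len(cfg$n_quads)),
    gene3 = sprintf("Q%03dC", seq_len(cfg$n_quads)),
    gene4 = sprintf("Q%03dD", seq_len(cfg$n_quads)))
  genome <- Biostrings::DNAStringSet(seqs)
  class(trees) <- "multiPhylo"
  list(genome = genome,
       chrom_lengths = stats::setNames(Biostrings::width(genome), names(genome)),
       genes = genes,
       acrs = if (length(acrs)) data.table::rbindlist(acrs) else NULL,
       pairs = pairs, quads = quads, trees = trees,
       truth = list(
         pair_acrs = if (length(pair_truth)) data.table::rbindlist(pair_truth) else NULL,
         quad_acrs = if (length(quad_truth)) data.table::rbindlist(quad_truth) else NULL))
}

# Latent log2-mean profiles for one pair under a planted pattern.
# Base profile: per-cell-type log2 means ~ N(7, 2.5) truncated to [1, 13].
# Differential offsets amplify the base profile's highest cell types so
# the latent coexpression stays high where the pattern demands it;
# rejection sampling enforces each pattern's rule inequalities with
# margin, which guarantees exact recovery in the zero-noise limit.
planted_profiles <- function(pattern, n_ct) {
  stopifnot(n_ct >= 3L)
  rbase <- function() pmin(pmax(stats::rnorm(n_ct, 7, 2.5), 1), 13)
  stats_of <- function(l1, l2) {
    fc <- l1 - l2
    list(r = suppressWarnings(stats::cor(l1, l2)),
         m = abs(mean(fc)), s = stats::sd(fc))
  }
  for (try in 1:200) {
    b <- rbase()
    swap <- stats::runif(1L) < 0.5
    if (pattern == "non_expressed") return(list(l1 = NULL, l2 = NULL))
    if (pattern == "mono_expressed") {
      out <- list(l1 = b, l2 = NULL)
      if (swap) out <- list(l1 = NULL, l2 = b)
      return(out)
    }
    if (pattern == "dosage_balanced") return(list(l1 = b, l2 = b))
    if (pattern == "paralogue_dominance") {
      l1 <- b + 2; l2 <- b
      if (swap) { t <- l1; l1 <- l2; l2 <- t }
      return(list(l1 = l1, l2 = l2))
    }
    if (pattern == "specialization") {
      k <- max(1L, round(n_ct / 4))
      fc <- rep(0.55, n_ct)
      fc[order(b, decreasing = TRUE)[seq_len(k)]] <- 3.6
      l1 <- b + fc; l2 <- b
      st <- stats_of(l1, l2)
      if (is.na(st$r) || st$r < 0.93 || st$m < 1.25 || st$s < 1.25) next
      if (swap) { t <- l1; l1 <- l2; l2 <- t }
      return(list(l1 = l1, l2 = l2))
    }
    if (pattern == "divergence") {
      l1 <- b; l2 <- rbase()
      st <- stats_of(l1, l2)
      if (is.na(st$r) || st$r > 0.35 || st$m < 1.25 || st$s < 1.25) next
      return(list(l1 = l1, l2 = l2))
    }
    if (pattern == "others") {
      # amplified dynamic range: same shape, balanced up/down offsets ->
      # high coexpression, near-zero mean fold change, large SD; no rule
      # covers it
      fc <- rep(-2.2, n_ct)
      fc[order(b, decreasing = TRUE)[seq_len(floor(n_ct / 2))]] <- 2.2
      l1 <- b + fc; l2 <- b
      st <- stats_of(l1, l2)
      if (is.na(st$r) || st$r < 0.93 || st$m > 0.6 || st$s < 1.4) next
      if (swap) { t <- l1; l1 <- l2; l2 <- t }
      return(list(l1 = l1, l2 = l2))
    }
    stop("unknown pattern: ", pattern)
  }
  stop("could not construct latent profiles for pattern ", pattern)
}

draw_counts <- function(mean, cfg) {
  switch(cfg$noise,
         nb = stats::rnbinom(length(mean), mu = mean, size = 1 / cfg$nb_dispersion),
         poisson = stats::rpois(length(mean), mean),
         none = round(mean))
}

#' Generate pseudobulk expression with planted pair patterns
#'
#' For every tissue and pair, a pattern is drawn from
#' \code{cfg$pattern_mix}, latent per-cell-type mean profiles are
#' constructed to satisfy the pattern's defining inequalities with margin
#' (see [planted_profiles()]), and counts are drawn per replicate under
#' the configured noise model.
#'
#' @param cfg A [synth_config()].
#' @param pairs Pair table (\code{gene1}, \code{gene2}).
#' @return List: \code{counts} (named list of counts objects, one per
#'   tissue) and \code{truth} (\code{data.table} pair x tissue with the
#'   planted pattern).
#' @export
gen_expression <- function(cfg, pairs) {
  if (cfg$cell_types < 3L) stop("need >= 3 cell types")
  cts <- sprintf("ct%02d", seq_len(cfg$cell_types))
  samples <- as.vector(outer(cts, sprintf("r%d", seq_len(cfg$replicates)),
                             paste, sep = "."))
  ct_of <- sub("\\.[^.]*$", "", samples)
  gene_ids <- as.vector(rbind(pairs$gene1, pairs$gene2))
  out_counts <- list(); truth <- list()
  for (tis in cfg$tissues) {
    m <- matrix(0L, length(gene_ids), length(samples),
                dimnames = list(gene_ids, samples))
    pat <- sample(names(cfg$pattern_mix), nrow(pairs), replace = TRUE,
                  prob = cfg$pattern_mix)
    for (p in seq_len(nrow(pairs))) {
      prof <- planted_profiles(pat[p], cfg$cell_types)
      for (g in 1:2) {
        lat <- prof[[g]]
        if (is.null(lat)) next
        mu <- 2^lat
        row <- if (g == 1) pairs$gene1[p] else pairs$gene2[p]
        for (s in seq_along(samples)) {
          ct_i <- match(ct_of[s], cts)
          m[row, s] <- draw_counts(mu[ct_i], cfg)
        }
      }
    }
    out_counts[[tis]] <- list(counts = m, cell_type = ct_of,
                              replicate = sub(".*\\.", "", samples))
    truth[[tis]] <- data.table::data.table(
      pair_id = if ("pair_id" %in% names(pairs)) pairs$pair_id else
        paste(pairs$gene1, pairs$gene2, sep = "|"),
      gene1 = pairs$gene1, gene2 = pairs$gene2,
      tissue = tis, pattern = pat)
  }
  list(counts = out_counts, truth = data.table::rbindlist(truth))
}

#' Planted binary specificity vectors for one quad scenario
#'
#' Cell types are split into 4 equal blocks and each scenario's four
#' vectors are built from block unions, so between-group Jaccard
#' distances are large by construction while within-group vectors agree
#' exactly. Rows are ordered (A, B, C, D) with (A,B) and (C,D) the
#' recent pairs.
#'
#' @param scenario Integer 1..5.
#' @param n_ct Number of cell types (multiple of 4, >= 8).
#' @return Binary 4 x \code{n_ct} matrix.
#' @export
scenario_vectors <- function(scenario, n_ct) {
  stopifnot(n_ct >= 8L, n_ct %% 4L == 0L)
  b <- split(seq_len(n_ct), rep(1:4, each = n_ct / 4))
  vec <- function(blocks) {
    v <- integer(n_ct); v[unlist(b[blocks])] <- 1L; v
  }
  switch(as.character(scenario),
    "1" = rbind(vec(1:2), vec(1:2), vec(1:2), vec(1:2)),
    "2" = rbind(vec(1:2), vec(1:2), vec(3:4), vec(3:4)),
    "3" = {
      # one gene (random) diverged after the second duplication
      base <- vec(1:2); novel <- vec(3:4)
      m <- rbind(base, base, base, base)
      m[sample.int(4L, 1L), ] <- novel
      m
    },
    "4" = {
      # one recent pair keeps a shared profile; the other pair's genes
      # each carry a novel block plus a partial echo of the shared one,
      # so the singletons are closer to the pair than to each other and
      # the 1:2:1 structure is the unambiguous silhouette optimum
      bs <- n_ct / 4
      ov <- max(1L, round(0.75 * bs))
      vC <- vec(3); vC[b[[1L]][seq_len(ov)]] <- 1L
      vD <- vec(4); vD[b[[2L]][seq_len(ov)]] <- 1L
      rbind(vec(1:2), vec(1:2), vC, vD)
    },
    "5" = rbind(vec(1), vec(2), vec(3), vec(4)),
    stop("scenario must be 1..5"))
}

#' Generate planted cell-type-specificity trajectories for quads
#'
#' Per quad a scenario 1-5 is drawn; planted binary specificity vectors
#' agree across exactly the gene groups the scenario dictates (1: all 4
#' identical; 2: identical within recent pairs only; 3: one gene differs
#' from the other three; 4: a 1:2:1 split; 5: all four distinct). Counts
#' supporting the vectors (8-fold elevation in the specific cell types)
#' and matching cell-type labels on each gene's first ACR are also
#' produced.
#'
#' @param cfg A [synth_config()].
#' @param quads Quad table.
#' @param acrs Optional ACR table from [gen_duplicated_genome()]; when
#'   given, each quad gene's first associated ACR is labeled with one of
#'   its planted specific cell types (a ctACR).
#' @return List: \code{truth} (per quad: scenario, per-gene vectors as a
#'   list of matrices), \code{specificity} (stacked binary matrix),
#'   \code{counts} (counts object over the trajectory cell types),
#'   \code{ctacrs} (labeled ACR table or NULL).
#' @export
gen_trajectories <- function(cfg, quads, acrs = NULL) {
  n_ct <- cfg$traj_cell_types
  cts <- sprintf("tct%02d", seq_len(n_ct))
  scen <- sample(1:5, nrow(quads), replace = TRUE, prob = cfg$scenario_mix)
  mats <- vector("list", nrow(quads))
  samples <- as.vector(outer(cts, sprintf("r%d", seq_len(cfg$replicates)),
                             paste, sep = "."))
  ct_of <- sub("\\.[^.]*$", "", samples)
  gene_ids <- as.vector(t(as.matrix(quads[, c("gene1", "gene2", "gene3", "gene4")])))
  m <- matrix(0L, length(gene_ids), length(samples),
              dimnames = list(gene_ids, samples))
  ctacr <- list()
  for (q in seq_len(nrow(quads))) {
    v <- scenario_vectors(scen[q], n_ct)
    g <- unlist(quads[q, c("gene1", "gene2", "gene3", "gene4")], use.names = FALSE)
    rownames(v) <- g
    colnames(v) <- cts
    mats[[q]] <- v
    base <- 2^6
    for (k in 1:4) {
      mu <- base * ifelse(v[k, ] == 1L, 8, 1)
      for (s in seq_along(samples)) {
        ct_i <- match(ct_of[s], cts)
        m[g[k], s] <- draw_counts(mu[ct_i], cfg)
      }
      if (!is.null(acrs)) {
        mine <- acrs[grepl(paste0("\\.", substr(g[k], nchar(g[k]), nchar(g[k])), "$"),
                           acrs$acr_id) & grepl(substr(g[k], 1L, 4L), acrs$acr_id)]
        if (nrow(mine) && any(v[k, ] == 1L)) {
          row <- acrs[acrs$acr_id == mine$acr_id[1L]]
          spec_cts <- which(v[k, ] == 1L)
          row$ct_label <- cts[spec_cts[sample.int(length(spec_cts), 1L)]]
          ctacr[[length(ctacr) + 1L]] <- row
        }
      }
    }
  }
  truth <- data.table::data.table(set_id = quads$set_id, scenario = scen)
  list(truth = truth, specificity = mats,
       counts = list(counts = m, cell_type = ct_of,
                     replicate = sub(".*\\.", "", samples)),
       ctacrs = if (length(ctacr)) data.table::rbindlist(ctacr) else NULL)
}

#' Generate per-condition ACR accessibility profiles
#'
#' Every ACR starts accessible in all conditions; each (ACR, condition)
#' entry is then silenced with probability \code{turnover}, the knob
#' controlling cross-condition accessibility divergence.
#'
#' @param cfg A [synth_config()] (supplies \code{turnover} and the
#'   condition names via \code{tissues}).
#' @param acr_ids Character vector of ACR ids.
#' @param conditions Condition names (default: the first four tissues).
#' @param turnover Override for \code{cfg$turnover}.
#' @return Binary matrix ACR x condition.
#' @export
gen_accessibility <- function(cfg, acr_ids, conditions = cfg$tissues[1:4],
                              turnover = cfg$turnover) {
  m <- matrix(1L, length(acr_ids), length(conditions),
              dimnames = list(acr_ids, conditions))
  off <- matrix(stats::runif(length(m)) < turnover, nrow(m))
  m[off] <- 0L
  m
}

#' Flip a fraction of bits in a binary matrix
#'
#' Exactly \code{round(rate * length(m))} entries, sampled without
#' replacement, are inverted — the controlled perturbation used in
#' robustness checks.
#'
#' @param m Binary matrix.
#' @param rate Fraction of entries to flip.
#' @return The perturbed matrix.
#' @export
flip_bits <- function(m, rate) {
  k <- round(rate * length(m))
  if (k > 0) {
    at <- sample.int(length(m), k)
    m[at] <- 1L - m[at]
  }
  m
}
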