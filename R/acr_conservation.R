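# ACR-to-gene association, reference regions, short-match local alignment
# and conservation metrics (BLASTed ratio B, mismatch rate M, conservation
# counts across 4-gene sets).

#' Karlin-Altschul parameters for a +1/-1 match/mismatch scheme
#'
#' \code{lambda} solves \eqn{\sum p_i p_j e^{\lambda s_{ij}} = 1}
#' numerically; \code{K} uses the closed form \eqn{(q-p)^2/q} for the
#' two-valued +1/-1 score lattice (p = match probability), which equals
#' 1/3 at uniform base composition. Ungapped parameters are applied to
#' gapped HSPs: under +1/-1 scoring with gap cost 5 + 2k, gaps are rare
#' enough that the ungapped statistics remain a close, slightly liberal
#' approximation.
#'
#' @param match Match reward (default +1).
#' @param mismatch Mismatch penalty (default -1).
#' @param p_match Probability two random bases match (0.25 uniform).
#' @return List with \code{lambda} and \code{K}.
#' @export
ka_params <- function(match = 1, mismatch = -1, p_match = 0.25) {
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  K <- (1 - 2 * p_match)^2 / (1 - p_match)
  list(lambda = lambda, K = K)
}

empty_hsps <- function() {
  data.table::data.table(
    q_start = integer(), q_end = integer(), r_start = integer(),
    r_end = integer(), aln_len = integer(), mismatches = integer(),
    gap_opens = integer(), score = integer(), strand = character(),
    evalue = numeric())
}

#' Short-match local alignment of an ACR against a reference region
#'
#' Seed-and-extend local alignment tuned like \code{blastn-short}: exact
#' 7-mer seeds on both strands, gapped extension with reward +1, penalty
#' -1, gap open 5, gap extend 2, and an E-value cutoff of 1e-3 under
#' Karlin-Altschul statistics. Seeds are clustered by diagonal and each
#' cluster is resolved with a full local dynamic program inside a padded
#' window, so reported scores never exceed the unrestricted
#' Smith-Waterman score for the same sequences.
#'
#' @param query Query (ACR) sequence, character scalar over A/C/G/T/N.
#' @param reference Reference region sequence.
#' @param evalue_max Keep HSPs with E-value at or below this (1e-3).
#' @param word_size Exact seed length (7).
#' @param gap_open,gap_extend Gap costs (5, 2); a gap of length k costs
#'   \code{gap_open + k * gap_extend}.
#' @param pad Window padding around each candidate extension, bp.
#' @param diag_band Candidate extensions within this diagonal distance
#'   are resolved in one gapped window.
#' @param trigger Minimum ungapped X-drop extension score that promotes
#'   a seed to gapped resolution (and minimum reported HSP score).
#' @param xdrop Ungapped extension termination threshold.
#' @return \code{data.table} of HSPs: query/reference offsets (0-based
#'   half-open, query coordinates always on the forward query), alignment
#'   length, mismatches, gap opens, score, strand, E-value; sorted by
#'   score, best first.
#' @export
local_align <- function(query, reference, evalue_max = 1e-3, word_size = 7,
                        gap_open = 5, gap_extend = 2, pad = 50,
                        diag_band = 32, trigger = 11, xdrop = 16) {
  if (!nzchar(query)) stop("empty query sequence")
  if (!nzchar(reference)) stop("empty reference sequence")
  qlen <- nchar(query)
  fw <- cpp_local_align(query, reference, word_size, gap_open, gap_extend,
                        pad, diag_band, trigger, xdrop)
  fw <- data.table::as.data.table(fw)
  if (nrow(fw)) fw[, strand := "+"]
  rcq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  rv <- data.table::as.data.table(
    cpp_local_align(rcq, reference, word_size, gap_open, gap_extend,
                    pad, diag_band, trigger, xdrop))
  if (nrow(rv)) {
    rv[, strand := "-"]
    # map reverse-strand hits back to forward-query offsets
    qs <- qlen - rv$q_end
    rv[, q_end := qlen - q_start]
    rv[, q_start := qs]
  }
  hsps <- data.table::rbindlist(list(fw, rv), use.names = TRUE, fill = TRUE)
  if (nrow(hsps) == 0L) return(empty_hsps())
  ka <- ka_params()
  # search space: query on both strands against the reference
  hsps[, evalue := 2 * ka$K * qlen * nchar(reference) * exp(-ka$lambda * score)]
  hsps <- hsps[evalue <= evalue_max]
  data.table::setorder(hsps, -score)
  hsps[]
}

#' Parse external tabular alignment hits (12-column "outfmt 6")
#'
#' Adapter so conservation metrics can be computed from hits produced by
#' an external aligner instead of the built-in one. Columns: qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore (1-based closed coordinates, converted here).
#'
#' @param path Path to the tabular hit file.
#' @return \code{data.table} with one row per HSP including \code{qseqid}
#'   and \code{sseqid}, coordinates 0-based half-open.
#' @export
read_tabular_hits <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("qseqid", "sseqid", "pident", "aln_len",
                                        "mismatches", "gap_opens", "qstart", "qend",
                                        "sstart", "send", "evalue", "bitscore"))
  strand <- ifelse(dt$sstart <= dt$send, "+", "-")
  r_start <- ifelse(strand == "+", dt$sstart, dt$send) - 1L
  r_end <- ifelse(strand == "+", dt$send, dt$sstart)
  data.table::data.table(
    qseqid = dt$qseqid, sseqid = dt$sseqid,
    q_start = dt$qstart - 1L, q_end = dt$qend,
    r_start = as.integer(r_start), r_end = as.integer(r_end),
    aln_len = dt$aln_len, mismatches = dt$mismatches,
    gap_opens = dt$gap_opens, score = as.integer(round(dt$bitscore)),
    strand = strand, evalue = dt$evalue)
}

#' Conservation metrics from a set of HSPs
#'
#' HSPs are reduced, greedily by score, to a subset with non-overlapping
#' query coverage. The BLASTed ratio B is the summed query span of that
#' subset divided by the query length; the mismatch rate M is total
#' mismatches over total aligned length of the same subset. An ACR is
#' conserved when B exceeds \code{b_threshold}; with no HSPs it is
#' "unBLASTed" (B = 0, M = NA).
#'
#' @param hsps HSP table from [local_align()].
#' @param query_len Length of the query ACR, bp.
#' @param b_threshold Conservation threshold on B (default 0.1; stricter
#'   values such as 0.2/0.4/0.6/0.8 can be passed for sensitivity checks).
#' @return List with \code{B}, \code{M}, \code{conserved}, \code{n_hsps}.
#' @export
conservation_metrics <- function(hsps, query_len, b_threshold = 0.1) {
  stopifnot(query_len > 0)
  if (is.null(hsps) || nrow(hsps) == 0L) {
    return(list(B = 0, M = NA_real_, conserved = FALSE, n_hsps = 0L))
  }
  o <- order(-hsps$score)
  sel_s <- integer(0); sel_e <- integer(0); keep <- integer(0)
  for (i in o) {
    qs <- hsps$q_start[i]; qe <- hsps$q_end[i]
    if (!any(qs < sel_e & qe > sel_s)) {
      sel_s <- c(sel_s, qs); sel_e <- c(sel_e, qe); keep <- c(keep, i)
    }
  }
  covered <- sum(sel_e - sel_s)
  B <- covered / query_len
  M <- sum(hsps$mismatches[keep]) / sum(hsps$aln_len[keep])
  list(B = B, M = M, conserved = B > b_threshold, n_hsps = length(keep))
}

#' Associate each ACR with its closest gene
#'
#' Distance is 0 for overlapping intervals, otherwise the gap between the
#' closest interval ends; ties are broken lexicographically by gene id.
#' ACRs on chromosomes without genes are left unassigned with a warning.
#'
#' @param acrs ACR table ([read_bed()]).
#' @param genes Gene-model table ([read_gff3()]).
#' @return \code{data.table}: \code{acr_id}, \code{gene_id} (NA when
#'   unassigned), \code{distance}.
#' @export
associate_acrs <- function(acrs, genes) {
  if (nrow(acrs) == 0L) {
    return(data.table::data.table(acr_id = character(), gene_id = character(),
                                  distance = integer()))
  }
  gr_a <- as_granges0(acrs)
  gr_g <- as_granges0(genes)
  hits <- GenomicRanges::distanceToNearest(gr_a, gr_g, select = "all")
  dt <- data.table::data.table(
    acr = S4Vectors::queryHits(hits),
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    distance = S4Vectors::mcols(hits)$distance)
  data.table::setorder(dt, acr, distance, gene_id)
  dt <- dt[!duplicated(acr)]
  out <- data.table::data.table(acr_id = acrs$acr_id,
                                gene_id = NA_character_,
                                distance = NA_integer_)
  out$gene_id[dt$acr] <- dt$gene_id
  out$distance[dt$acr] <- as.integer(dt$distance)
  if (anyNA(out$gene_id)) {
    warning(sum(is.na(out$gene_id)),
            " ACR(s) on chromosomes without genes left unassigned")
  }
  out[]
}

#' Reference region of a duplicated gene
#'
#' The genomic span from the start of the nearest upstream neighbor gene
#' to the end of the nearest downstream neighbor gene, inclusive of the
#' gene's own body; clipped to chromosome bounds for terminal genes.
#'
#' @param gene_id Gene of interest.
#' @param genes Gene-model table (all annotated genes).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return List with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open).
#' @export
reference_region <- function(gene_id, genes, chrom_lengths) {
  sel <- which(genes$gene_id == gene_id)
  if (length(sel) != 1L) stop("gene not found in annotation: ", gene_id)
  g <- genes[sel]
  same <- genes[which(genes$chrom == g$chrom)]
  data.table::setorder(same, start)
  i <- which(same$gene_id == gene_id)
  start <- if (i > 1L) same$start[i - 1L] else 0L
  end <- if (i < nrow(same)) same$end[i + 1L] else
    as.integer(chrom_lengths[[g$chrom]])
  list(chrom = g$chrom, start = start, end = end)
}

# Extract a region's sequence from a named DNAStringSet genome.
region_seq <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

# ACR sequences from the genome, named by acr_id.
acr_seqs <- function(genome, acrs) {
  stats::setNames(
    vapply(seq_len(nrow(acrs)), function(i) {
      region_seq(genome, acrs$chrom[i], acrs$start[i], acrs$end[i])
    }, character(1)),
    acrs$acr_id)
}

#' Score one ACR against one partner gene's reference region
#'
#' @param acr_seq Query ACR sequence.
#' @param ref_seq Partner reference-region sequence.
#' @param b_threshold Conservation threshold on B.
#' @param ... Passed to [local_align()].
#' @return List as from [conservation_metrics()].
#' @export
acr_vs_region <- function(acr_seq, ref_seq, b_threshold = 0.1, ...) {
  hsps <- local_align(acr_seq, ref_seq, ...)
  conservation_metrics(hsps, nchar(acr_seq), b_threshold = b_threshold)
}

#' Per-pair ACR conservation
#'
#' For each ACR associated with either gene of a duplicated pair, aligns
#' the ACR against the partner gene's reference region and computes
#' conservation metrics.
#'
#' @param pair One-row pair record (\code{gene1}, \code{gene2}).
#' @param acrs ACR table.
#' @param assoc ACR-to-gene association ([associate_acrs()]).
#' @param genes Gene-model table.
#' @param genome Named \code{DNAStringSet}.
#' @param chrom_lengths Named chromosome lengths.
#' @param b_threshold Conservation threshold on B.
#' @return \code{data.table}, one row per ACR: \code{acr_id},
#'   \code{source_gene}, \code{target_gene}, \code{B}, \code{M},
#'   \code{conserved}.
#' @export
pair_acr_conservation <- function(pair, acrs, assoc, genes, genome,
                                  chrom_lengths, b_threshold = 0.1) {
  partner <- c(pair$gene1, pair$gene2)
  rows <- list()
  for (k in 1:2) {
    src <- partner[k]; tgt <- partner[3 - k]
    my_acrs <- acrs[acrs$acr_id %in% assoc$acr_id[assoc$gene_id %in% src]]
    if (nrow(my_acrs) == 0L) next
    reg <- reference_region(tgt, genes, chrom_lengths)
    ref_seq <- region_seq(genome, reg$chrom, reg$start, reg$end)
    for (i in seq_len(nrow(my_acrs))) {
      qseq <- region_seq(genome, my_acrs$chrom[i], my_acrs$start[i],
                         my_acrs$end[i])
      met <- acr_vs_region(qseq, ref_seq, b_threshold = b_threshold)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        acr_id = my_acrs$acr_id[i], source_gene = src, target_gene = tgt,
        B = met$B, M = met$M, conserved = met$conserved)
    }
  }
  if (length(rows) == 0L) {
    return(data.table::data.table(acr_id = character(),
                                  source_gene = character(),
                                  target_gene = character(), B = numeric(),
                                  M = numeric(), conserved = logical()))
  }
  data.table::rbindlist(rows)
}

#' Per-pair summary of ACR conservation
#'
#' The pair-level statistics: fraction of conserved ACRs, mean B and M
#' over conserved ACRs, fraction of unBLASTed ACRs, and the ACR counts of
#' the two genes split into large/small count groups.
#'
#' @param pair One-row pair record.
#' @param conservation Per-ACR table from [pair_acr_conservation()].
#' @return One-row \code{data.table}; all-NA fields for pairs with no
#'   associated ACRs.
#' @export
pair_acr_summary <- function(pair, conservation) {
  n1 <- sum(conservation$source_gene == pair$gene1)
  n2 <- sum(conservation$source_gene == pair$gene2)
  if (nrow(conservation) == 0L) {
    return(data.table::data.table(
      gene1 = pair$gene1, gene2 = pair$gene2, n_acrs = 0L,
      frac_conserved = NA_real_, mean_B_conserved = NA_real_,
      mean_M_conserved = NA_real_, frac_unblasted = NA_real_,
      large_count = NA_integer_, small_count = NA_integer_))
  }
  cons <- conservation[conservation$conserved == TRUE]
  data.table::data.table(
    gene1 = pair$gene1, gene2 = pair$gene2, n_acrs = nrow(conservation),
    frac_conserved = nrow(cons) / nrow(conservation),
    mean_B_conserved = if (nrow(cons)) mean(cons$B) else NA_real_,
    mean_M_conserved = if (nrow(cons)) mean(cons$M) else NA_real_,
    frac_unblasted = mean(conservation$B == 0),
    large_count = max(n1, n2), small_count = min(n1, n2))
}

#' Conservation counts and states across a 4-gene set
#'
#' Each ACR associated with one gene of the set is aligned against the
#' reference regions of the other 3 genes; the conservation count is the
#' number of those 3 alignments with B above threshold. States follow the
#' count: 0 = unique, 1 = two-copy conserved, 2 or 3 = multi-copy
#' conserved.
#'
#' @param quad One-row quad record (\code{gene1}..\code{gene4}).
#' @param acrs,assoc,genes,genome,chrom_lengths As in
#'   [pair_acr_conservation()].
#' @param b_threshold Conservation threshold on B.
#' @param max_targets Cap on reference regions scanned per query (kept for
#'   symmetry with short-match alignment conventions; 3 partners here).
#' @return \code{data.table}, one row per (ACR, partner) with B/M, plus
#'   columns \code{conservation_count} and \code{state} repeated per ACR.
#' @export
quad_conservation <- function(quad, acrs, assoc, genes, genome,
                              chrom_lengths, b_threshold = 0.1,
                              max_targets = 4L) {
  gene_ids <- unlist(quad[, c("gene1", "gene2", "gene3", "gene4")],
                     use.names = FALSE)
  regs <- lapply(gene_ids, function(g) {
    reg <- reference_region(g, genes, chrom_lengths)
    region_seq(genome, reg$chrom, reg$start, reg$end)
  })
  names(regs) <- gene_ids
  rows <- list()
  for (g in gene_ids) {
    my_acrs <- acrs[acrs$acr_id %in% assoc$acr_id[assoc$gene_id %in% g]]
    if (nrow(my_acrs) == 0L) next
    partners <- utils::head(setdiff(gene_ids, g), max_targets)
    for (i in seq_len(nrow(my_acrs))) {
      qseq <- region_seq(genome, my_acrs$chrom[i], my_acrs$start[i],
                         my_acrs$end[i])
      per <- lapply(partners, function(p) {
        acr_vs_region(qseq, regs[[p]], b_threshold = b_threshold)
      })
      cnt <- sum(vapply(per, `[[`, logical(1), "conserved"))
      state <- conservation_state(cnt)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        acr_id = my_acrs$acr_id[i], source_gene = g, target_gene = partners,
        B = vapply(per, `[[`, numeric(1), "B"),
        M = vapply(per, `[[`, numeric(1), "M"),
        conserved = vapply(per, `[[`, logical(1), "conserved"),
        conservation_count = cnt, state = state)
    }
  }
  if (length(rows) == 0L) {
    return(data.table::data.table(
      acr_id = character(), source_gene = character(),
      target_gene = character(), B = numeric(), M = numeric(),
      conserved = logical(), conservation_count = integer(),
      state = character()))
  }
  data.table::rbindlist(rows)
}

#' Map a conservation count to its state
#'
#' @param count Integer count in 0..3.
#' @return "unique", "two_copy" or "multi_copy".
#' @export
conservation_state <- function(count) {
  stopifnot(all(count %in% 0:3))
  c("unique", "two_copy", "multi_copy", "multi_copy")[count + 1L]
}
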