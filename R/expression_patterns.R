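# Per-tissue QC, CPM normalization, pair statistics, the 6+1 expression
# pattern classifier and cross-tissue consolidation for duplicated gene
# pairs, plus the pseudobulk cell-type-specificity test.

PATTERN_LEVELS <- c("non_expressed", "mono_expressed", "dosage_balanced",
                    "paralogue_dominance", "specialization", "divergence",
                    "others")

#' Replicate-concordance QC on cell types
#'
#' Computes the Spearman correlation between the two replicate count
#' vectors of every cell type and removes cell types whose correlation is
#' 0.75 or below.
#'
#' @param counts Counts object from [read_counts()] (list with
#'   \code{counts}, \code{cell_type}, \code{replicate}).
#' @param rho_min Cell types with replicate correlation <= this fail QC.
#' @return The counts object restricted to passing cell types, with
#'   attributes \code{removed} (failed cell types) and \code{rho} (named
#'   correlations).
#' @export
qc_cell_types <- function(counts, rho_min = 0.75) {
  cts <- unique(counts$cell_type)
  rho <- vapply(cts, function(ct) {
    cols <- which(counts$cell_type == ct)
    if (length(cols) < 2L) stop("cell type ", ct, " has fewer than 2 replicates")
    stats::cor(counts$counts[, cols[1L]], counts$counts[, cols[2L]],
               method = "spearman")
  }, numeric(1))
  keep_ct <- cts[!is.na(rho) & rho > rho_min]
  if (length(keep_ct) == 0L) stop("no cell types pass QC")
  keep <- counts$cell_type %in% keep_ct
  out <- list(counts = counts$counts[, keep, drop = FALSE],
              cell_type = counts$cell_type[keep],
              replicate = counts$replicate[keep])
  attr(out, "removed") <- setdiff(cts, keep_ct)
  attr(out, "rho") <- rho
  out
}

#' Counts-per-million normalization
#'
#' \code{value = count / library size * 1e6} per sample; column sums of
#' the result equal 1e6.
#'
#' @param counts Counts object or bare counts matrix.
#' @return Numeric CPM matrix with the input's dimnames.
#' @export
cpm_normalize <- function(counts) {
  m <- if (is.list(counts)) counts$counts else counts
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("zero library size in sample: ", colnames(m)[lib == 0][1L])
  }
  sweep(m, 2L, lib, "/") * 1e6
}

#' Low-expression filter
#'
#' A gene is retained when its CPM is at least 1 in at least
#' \code{min_samples} samples. Genes with zero counts in every sample are
#' additionally labeled non-expressed.
#'
#' @param cpm CPM matrix from [cpm_normalize()].
#' @param counts Matching counts matrix (for the all-zero flag).
#' @param min_cpm,min_samples Filter thresholds.
#' @return List with \code{retained}, \code{dropped} and
#'   \code{non_expressed} gene-id vectors.
#' @export
filter_low_expression <- function(cpm, counts, min_cpm = 1, min_samples = 2L) {
  m <- if (is.list(counts)) counts$counts else counts
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  allzero <- rowSums(m) == 0
  list(retained = rownames(cpm)[keep],
       dropped = rownames(cpm)[!keep],
       non_expressed = rownames(cpm)[allzero])
}

#' Pair expression statistics
#'
#' Per cell type, replicate-mean CPM values are computed for both genes;
#' the per-cell-type log2 fold change is \code{log2((c1+1)/(c2+1))}.
#' \code{m} is the absolute mean and \code{s} the sample SD of those fold
#' changes across cell types. The coexpression value \code{r} is the
#' Pearson correlation of the genes' \code{log2(CPM+1)} replicate-mean
#' profiles across cell types, NA when either gene is non-expressed or
#' has zero profile variance.
#'
#' @param cpm CPM matrix.
#' @param cell_type Per-sample cell-type labels (matching \code{cpm}
#'   columns).
#' @param gene1,gene2 The pair's gene ids.
#' @param expressed Optional named logical vector of expressed flags; by
#'   default the low-expression rule (CPM >= 1 in >= 2 samples) is applied.
#' @param method Correlation flavor, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return List: \code{r}, \code{m}, \code{s}, \code{expressed1},
#'   \code{expressed2}.
#' @export
pair_stats <- function(cpm, cell_type, gene1, gene2, expressed = NULL,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cts <- unique(cell_type)
  if (length(cts) < 3L) stop("need >= 3 cell types for pair statistics")
  if (is.null(expressed)) {
    sub <- cpm[c(gene1, gene2), , drop = FALSE]
    expressed <- rowSums(sub >= 1) >= 2L
    names(expressed) <- c(gene1, gene2)
  }
  e1 <- isTRUE(unname(expressed[gene1])); e2 <- isTRUE(unname(expressed[gene2]))
  prof <- function(g) {
    vapply(cts, function(ct) mean(cpm[g, cell_type == ct]), numeric(1))
  }
  c1 <- prof(gene1); c2 <- prof(gene2)
  if (!e1 || !e2) {
    return(list(r = NA_real_, m = NA_real_, s = NA_real_,
                expressed1 = e1, expressed2 = e2))
  }
  fc <- log2((c1 + 1) / (c2 + 1))
  m <- abs(mean(fc))
  s <- stats::sd(fc)
  l1 <- log2(c1 + 1); l2 <- log2(c2 + 1)
  r <- if (stats::sd(l1) == 0 || stats::sd(l2) == 0) NA_real_ else
    stats::cor(l1, l2, method = method)
  list(r = r, m = m, s = s, expressed1 = TRUE, expressed2 = TRUE)
}

#' Classify one duplicated pair in one tissue
#'
#' Rules, applied in order: both genes non-expressed -> non_expressed;
#' exactly one expressed -> mono_expressed; then with coexpression r,
#' absolute mean m and SD s of per-cell-type log2 fold change:
#' r > 0.9 & m < 1 & s < 1 -> dosage_balanced;
#' r > 0.9 & m >= 1 & s < 1 -> paralogue_dominance;
#' r > 0.9 & m >= 1 & s >= 1 -> specialization;
#' r < 0.5 & m >= 1 & s >= 1 -> divergence; anything else -> others.
#'
#' @param stats List from [pair_stats()].
#' @param coexpr_high,coexpr_low,fc_threshold,sd_threshold Rule
#'   thresholds (0.9, 0.5, 1, 1).
#' @return List with \code{pattern} and its \code{simplified} category.
#' @export
classify_pair <- function(stats, coexpr_high = 0.9, coexpr_low = 0.5,
                          fc_threshold = 1, sd_threshold = 1) {
  e1 <- stats$expressed1; e2 <- stats$expressed2
  pattern <- if (!e1 && !e2) {
    "non_expressed"
  } else if (xor(e1, e2)) {
    "mono_expressed"
  } else {
    r <- stats$r; m <- stats$m; s <- stats$s
    if (is.na(r)) {
      "others"
    } else if (r > coexpr_high && m < fc_threshold && s < sd_threshold) {
      "dosage_balanced"
    } else if (r > coexpr_high && m >= fc_threshold && s < sd_threshold) {
      "paralogue_dominance"
    } else if (r > coexpr_high && m >= fc_threshold && s >= sd_threshold) {
      "specialization"
    } else if (r < coexpr_low && m >= fc_threshold && s >= sd_threshold) {
      "divergence"
    } else {
      "others"
    }
  }
  list(pattern = pattern, simplified = simplify_pattern(pattern))
}

#' Consolidate a pattern into its simplified category
#'
#' dosage_balanced / paralogue_dominance / specialization -> correlated;
#' divergence / others -> uncorrelated; non_expressed -> non;
#' mono_expressed -> mono.
#'
#' @param pattern Pattern label(s).
#' @return Simplified category label(s).
#' @export
simplify_pattern <- function(pattern) {
  map <- c(non_expressed = "non", mono_expressed = "mono",
           dosage_balanced = "correlated", paralogue_dominance = "correlated",
           specialization = "correlated", divergence = "uncorrelated",
           others = "uncorrelated")
  bad <- setdiff(pattern, names(map))
  if (length(bad)) stop("unknown pattern: ", bad[1L])
  unname(map[pattern])
}

#' Classify every pair of a table in one tissue
#'
#' Convenience driver: QC, CPM normalization, low-expression filtering,
#' pair statistics and classification for each pair.
#'
#' @param counts Counts object for one tissue.
#' @param pairs Pair table ([read_pairs()]).
#' @param tissue Tissue name recorded in the output.
#' @param qc_rho Replicate-correlation QC cutoff.
#' @param ... Threshold overrides passed to [classify_pair()].
#' @return \code{data.table}: one row per pair with r, m, s, pattern and
#'   simplified category.
#' @export
classify_pairs <- function(counts, pairs, tissue = NA_character_,
                           qc_rho = 0.75, ...) {
  qc <- qc_cell_types(counts, rho_min = qc_rho)
  cpm <- cpm_normalize(qc)
  filt <- filter_low_expression(cpm, qc)
  expressed <- stats::setNames(rownames(cpm) %in% filt$retained, rownames(cpm))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    if (!g1 %in% rownames(cpm) || !g2 %in% rownames(cpm)) {
      stop("pair gene absent from counts: ", if (g1 %in% rownames(cpm)) g2 else g1)
    }
    st <- pair_stats(cpm, qc$cell_type, g1, g2, expressed = expressed)
    cl <- classify_pair(st, ...)
    out[[i]] <- data.table::data.table(
      gene1 = g1, gene2 = g2, tissue = tissue, r = st$r, m = st$m, s = st$s,
      pattern = cl$pattern, simplified = cl$simplified)
  }
  data.table::rbindlist(out)
}

#' Count shared simplified categories across conditions
#'
#' Collects the simplified categories of one pair over several conditions
#' (e.g. 4 seed stages or 4 organs). Non-expression is a distinct case:
#' it is dropped from the multiset when any expressed category co-occurs,
#' and counts as the single shared category only when the pair is
#' non-expressed in every condition.
#'
#' @param simplified Character vector of simplified categories, one per
#'   condition.
#' @return Integer count of distinct shared categories.
#' @export
shared_categories <- function(simplified) {
  if (length(simplified) == 0L || anyNA(simplified)) {
    stop("one simplified category required per condition")
  }
  cats <- unique(simplified)
  if (length(cats) > 1L) cats <- setdiff(cats, "non")
  length(cats)
}

#' Cell-type-specific genes from pseudobulk counts
#'
#' For every cell type, its replicate pseudobulk columns are tested
#' against an equal number of replicate columns drawn at random from the
#' other cell types of the same tissue, with edgeR's negative-binomial
#' exact test under a common dispersion; P-values are Benjamini-Hochberg
#' adjusted across genes within each cell type. A gene is called specific
#' to a cell type when log2 fold change > \code{lfc} and adjusted
#' P < \code{alpha}, and cell-type specific overall when that holds for
#' at least one cell type.
#'
#' Randomness (the reference-column draw) uses the session RNG; seed it
#' for reproducibility.
#'
#' @param counts Counts object (list with \code{counts},
#'   \code{cell_type}).
#' @param lfc log2-fold-change threshold (default 1).
#' @param alpha Adjusted-P threshold (default 0.05).
#' @return List: \code{specific} binary gene x cell-type matrix,
#'   \code{is_specific} per-gene logical, \code{pvalue} and \code{logfc}
#'   matrices.
#' @export
celltype_specific_genes <- function(counts, lfc = 1, alpha = 0.05) {
  m <- counts$counts
  cell_type <- counts$cell_type
  cts <- unique(cell_type)
  if (length(cts) < 2L) stop("need >= 2 cell types for specificity testing")
  spec <- matrix(0L, nrow(m), length(cts), dimnames = list(rownames(m), cts))
  pmat <- matrix(NA_real_, nrow(m), length(cts), dimnames = list(rownames(m), cts))
  fmat <- pmat
  for (ct in cts) {
    tgt <- which(cell_type == ct)
    other <- which(cell_type != ct)
    ref <- sample(other, length(tgt), replace = length(other) < length(tgt))
    y <- m[, c(tgt, ref), drop = FALSE]
    colnames(y) <- make.unique(colnames(y))
    group <- factor(rep(c("target", "ref"), c(length(tgt), length(ref))),
                    levels = c("ref", "target"))
    dge <- edgeR::DGEList(counts = y, group = group)
    dge <- edgeR::estimateCommonDisp(dge)
    et <- edgeR::exactTest(dge, pair = c("ref", "target"))
    padj <- stats::p.adjust(et$table$PValue, method = "BH")
    pmat[, ct] <- et$table$PValue
    fmat[, ct] <- et$table$logFC
    spec[, ct] <- as.integer(et$table$logFC > lfc & padj < alpha)
  }
  list(specific = spec, is_specific = rowSums(spec) > 0,
       pvalue = pmat, logfc = fmat)
}
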