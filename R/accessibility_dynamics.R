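# Overlap of ACR accessibility profiles across conditions (stages or
# organs) and matching of cell-type-specific ACRs to cell-type-specific
# genes.

#' Jaccard distance of an accessibility profile
#'
#' The profile is a binary ACR x condition matrix (presence = accessible
#' in that condition). For every unordered condition pair the Jaccard
#' distance of the present-ACR sets is \eqn{1 - |A \cap B|/|A \cup B|};
#' the returned value is the mean over all condition pairs. A condition
#' pair with both sets empty contributes 0 (identical sets); an entity
#' whose profile is all-zero yields NA. The pooled variant uses
#' shared-in-all over present-in-any instead of the pairwise mean.
#'
#' @param profile Binary matrix ACR x condition (>= 2 conditions).
#' @param pooled Use the pooled all-condition overlap instead of the
#'   pairwise average.
#' @return Distance in [0, 1], or NA for an empty profile.
#' @export
jaccard_distance <- function(profile, pooled = FALSE) {
  stopifnot(is.matrix(profile), ncol(profile) >= 2L)
  if (all(profile == 0)) return(NA_real_)
  sets <- lapply(seq_len(ncol(profile)), function(j) which(profile[, j] != 0))
  if (pooled) {
    shared <- Reduce(intersect, sets)
    total <- Reduce(union, sets)
    return(1 - length(shared) / length(total))
  }
  pairs <- utils::combn(length(sets), 2L)
  d <- apply(pairs, 2L, function(p) {
    a <- sets[[p[1L]]]; b <- sets[[p[2L]]]
    u <- union(a, b)
    if (length(u) == 0L) return(0)
    1 - length(intersect(a, b)) / length(u)
  })
  mean(d)
}

#' Accessibility profile of an entity's associated ACRs
#'
#' @param acr_ids ACR ids associated with the entity (pair or quad).
#' @param accessibility Binary ACR x condition matrix for the universe of
#'   ACRs (rownames = ACR ids).
#' @return The profile submatrix for the entity.
#' @export
accessibility_profile <- function(acr_ids, accessibility) {
  miss <- setdiff(acr_ids, rownames(accessibility))
  if (length(miss)) stop("ACR ids missing from accessibility matrix: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  accessibility[acr_ids, , drop = FALSE]
}

#' Match cell-type-specific ACRs to cell-type-specific genes
#'
#' Emits one (gene, ACR, cell type) triple for every ctACR whose
#' cell-type label names a cell type where its associated gene is
#' specifically expressed.
#'
#' @param gene_specificity Binary gene x cell-type matrix.
#' @param ctacrs ACR table with non-NA \code{ct_label}.
#' @param assoc ACR-to-gene association ([associate_acrs()]).
#' @return \code{data.table} of matched triples.
#' @export
match_ctacrs <- function(gene_specificity, ctacrs, assoc) {
  ctacrs <- ctacrs[!is.na(ctacrs$ct_label)]
  vocab <- colnames(gene_specificity)
  bad <- setdiff(unique(ctacrs$ct_label), vocab)
  if (length(bad)) {
    stop("unknown cell-type label(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(vocab, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(ctacrs))) {
    gid <- assoc$gene_id[assoc$acr_id == ctacrs$acr_id[i]]
    if (length(gid) != 1L || is.na(gid)) next
    if (!gid %in% rownames(gene_specificity)) next
    if (gene_specificity[gid, ctacrs$ct_label[i]] == 1) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene_id = gid, acr_id = ctacrs$acr_id[i],
        cell_type = ctacrs$ct_label[i])
    }
  }
  if (length(rows) == 0L) {
    return(data.table::data.table(gene_id = character(),
                                  acr_id = character(),
                                  cell_type = character()))
  }
  data.table::rbindlist(rows)
}
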