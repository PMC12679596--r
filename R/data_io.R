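#' @useDynLib dupdiverge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# All genomic intervals are carried internally as 0-based half-open
# [start, end); conversion from 1-based closed GFF3 happens exactly once,
# in read_gff3().

#' Read gene models from a GFF3 file
#'
#' Parses features of type \code{gene} into a gene-model table. GFF3
#' 1-based closed coordinates are converted to the package-wide 0-based
#' half-open convention on read.
#'
#' @param path Path to a GFF3 file.
#' @return A \code{data.table} with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and \code{strand},
#'   sorted by (\code{chrom}, \code{start}).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_genes())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1L]]
    stop("malformed GFF3 line ", bad, ": expected 9 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  is_gene <- m[, 3L] == "gene"
  if (!any(is_gene)) return(empty_genes())
  m <- m[is_gene, , drop = FALSE]
  gidx <- idx[is_gene]
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- gidx[which(is.na(start1) | is.na(end1))[1L]]
    stop("malformed GFF3 line ", bad, ": non-integer coordinate")
  }
  if (any(start1 > end1)) {
    bad <- gidx[which(start1 > end1)[1L]]
    stop("malformed GFF3 line ", bad, ": start > end")
  }
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9L])
  no_id <- !grepl("ID=", m[, 9L])
  if (any(no_id)) {
    bad <- gidx[which(no_id)[1L]]
    stop("malformed GFF3 line ", bad, ": gene feature without ID attribute")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in GFF3: ", ids[duplicated(ids)][1L])
  }
  out <- data.table(
    gene_id = ids, chrom = m[, 1L],
    start = start1 - 1L, end = end1, strand = m[, 7L]
  )
  setkey(out, chrom, start)
  out[]
}

empty_genes <- function() {
  data.table(gene_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character())
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]; internal 0-based half-open coordinates are
#' converted back to 1-based closed.
#'
#' @param genes Gene-model table as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start + 1L, genes$end,
                       genes$strand, genes$gene_id), con)
  }
  invisible(path)
}

#' Read ACR intervals from a BED file
#'
#' BED3+ with optional name (column 4), tissue (column 5) and cell-type
#' label (column 6). Coordinates are kept 0-based half-open. Missing names
#' are synthesized as \code{"chrom:start-end"}.
#'
#' @param path Path to a BED file.
#' @return \code{data.table} with columns \code{acr_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{tissue}, \code{ct_label}.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.table(acr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      tissue = character(), ct_label = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop("malformed BED line ", bad, ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop("malformed BED line ", bad, ": non-integer coordinate")
  }
  if (any(start >= end)) {
    bad <- idx[which(start >= end)[1L]]
    stop("malformed BED line ", bad, ": start >= end")
  }
  col_or_na <- function(k) {
    v <- vapply(fields, function(f) if (length(f) >= k) f[[k]] else NA_character_, "")
    v[v == "."] <- NA_character_
    v
  }
  name <- col_or_na(4L)
  name[is.na(name)] <- sprintf("%s:%d-%d", chrom, start, end)[is.na(name)]
  out <- data.table(acr_id = name, chrom = chrom, start = start, end = end,
                    tissue = col_or_na(5L), ct_label = col_or_na(6L))
  out[]
}

#' Write ACR intervals to BED
#'
#' @param acrs ACR table as returned by [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(acrs, path) {
  dot <- function(x) ifelse(is.na(x), ".", x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", acrs$chrom, acrs$start,
                   acrs$end, acrs$acr_id, dot(acrs$tissue), dot(acrs$ct_label))
  # trim trailing all-dot columns for plain BED4 inputs
  if (all(is.na(acrs$tissue)) && all(is.na(acrs$ct_label))) {
    lines <- sprintf("%s\t%d\t%d\t%s", acrs$chrom, acrs$start, acrs$end, acrs$acr_id)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene family tree in Newick format
#'
#' @param path Path to a Newick file (one tree).
#' @return An \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label in tree: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  tree
}

#' Read a pseudobulk counts table
#'
#' Accepts a TSV of genes x samples (first column gene ids) whose column
#' labels encode cell type and replicate as \code{"celltype.rep"} (the part
#' after the last dot is the replicate tag), or a MatrixMarket triplet file
#' accompanied by \code{<path>.genes} and \code{<path>.samples} label files.
#'
#' @param path Path to the counts TSV or \code{.mtx} file.
#' @return A list with \code{counts} (integer matrix, genes x samples),
#'   \code{cell_type} and \code{replicate} (per-sample character vectors).
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".genes"))
    samples <- readLines(paste0(path, ".samples"))
    dimnames(m) <- list(genes, samples)
    storage.mode(m) <- "integer"
  } else {
    dt <- fread(path, sep = "\t", header = TRUE)
    genes <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- genes
  }
  if (any(m < 0)) stop("negative count entry")
  if (anyDuplicated(colnames(m))) stop("duplicate sample label")
  parsed <- parse_sample_labels(colnames(m))
  list(counts = m, cell_type = parsed$cell_type, replicate = parsed$replicate)
}

#' Write a pseudobulk counts table as TSV
#'
#' @param counts Integer matrix (genes x samples) with "celltype.rep"
#'   column names.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table(gene_id = rownames(counts))
  dt <- cbind(dt, as.data.table(counts))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

# "celltype.rep": replicate tag after the last dot; cell type may itself
# contain dots.
parse_sample_labels <- function(labels) {
  if (!all(grepl("\\.", labels))) {
    stop("sample labels must encode cell type and replicate as 'celltype.rep'")
  }
  cell_type <- sub("\\.[^.]*$", "", labels)
  replicate <- sub(".*\\.", "", labels)
  list(cell_type = cell_type, replicate = replicate)
}

#' Read a duplicated-pair table
#'
#' TSV with columns \code{gene1}, \code{gene2}, \code{mechanism}; the
#' mechanism label is one of WGD, TD, PD, TRD, DSD (consumed as produced
#' by an upstream duplication-mode classifier, not computed here).
#'
#' @param path Path to the TSV.
#' @return \code{data.table} with one row per pair.
#' @export
read_pairs <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("gene1", "gene2", "mechanism")
  if (!all(need %in% names(dt))) {
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  }
  ok <- dt$mechanism %in% c("WGD", "TD", "PD", "TRD", "DSD")
  if (!all(ok)) stop("unknown duplication mechanism: ", dt$mechanism[!ok][1L])
  dt[]
}

#' Read a 4-gene-set (quad) table
#'
#' TSV with columns \code{set_id}, \code{gene1}..\code{gene4} and
#' optionally \code{tree} (path or id of the family tree).
#'
#' @param path Path to the TSV.
#' @return \code{data.table} with one row per 4-gene set.
#' @export
read_quads <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("set_id", "gene1", "gene2", "gene3", "gene4")
  if (!all(need %in% names(dt))) {
    stop("quad table must have columns: ", paste(need, collapse = ", "))
  }
  dt[]
}

#' Convert an interval table to GRanges
#'
#' Internal 0-based half-open coordinates become 1-based closed GRanges.
#' @param x Table with \code{chrom}, \code{start}, \code{end}.
#' @param names Optional names for the ranges.
#' @return A \code{GRanges}.
#' @export
as_granges0 <- function(x, names = NULL) {
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end))
  if (!is.null(names)) names(gr) <- names
  gr
}
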