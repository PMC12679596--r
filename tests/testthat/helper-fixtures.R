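# Small in-code fixtures shared across tests.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# counts object from a bare matrix with "celltype.rep" column names
make_counts <- function(m) {
  list(counts = m,
       cell_type = sub("\\.[^.]*$", "", colnames(m)),
       replicate = sub(".*\\.", "", colnames(m)))
}

# counts matrix with given per-cell-type means, identical across
# replicates (zero-noise)
counts_from_means <- function(means, n_rep = 2) {
  # means: genes x cell types
  cts <- colnames(means)
  cols <- as.vector(t(outer(cts, paste0("r", seq_len(n_rep)), paste, sep = ".")))
  m <- means[, rep(seq_along(cts), each = n_rep), drop = FALSE]
  colnames(m) <- cols
  storage.mode(m) <- "integer"
  make_counts(m)
}

scen_names <- c("before_first_wgd", "before_second_wgd", "after_second_wgd",
                "combination", "complex")
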