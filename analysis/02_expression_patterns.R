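#!/usr/bin/env Rscript
# Stage 2 — classify every duplicate pair's within-tissue expression
# pattern (6 + 1 categories) from the pseudobulk counts, consolidate to
# simplified categories and count shared categories across the four
# seed stages and the four organs.

library(dupdiverge)

ind <- "results/01_simulate"
out <- "results/02_patterns"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20240902)

pairs <- read_pairs(file.path(ind, "pairs.tsv"))
tissues <- c("globular", "heart", "cotyledon", "early_maturation",
             "hypocotyl", "root", "nodule")
calls <- data.table::rbindlist(lapply(tissues, function(tis) {
  cc <- read_counts(file.path(ind, sprintf("counts_%s.tsv", tis)))
  classify_pairs(cc, pairs, tissue = tis)
}))
data.table::fwrite(calls, file.path(out, "pattern_calls.tsv"), sep = "\t")

truth <- data.table::fread(file.path(ind, "truth_patterns.tsv"))
m <- merge(calls, truth[, c("gene1", "gene2", "tissue", "pattern")],
           by = c("gene1", "gene2", "tissue"), suffixes = c("", "_true"))
cat(sprintf("pattern calls: %d; planted-pattern recovery %.1f%%\n",
            nrow(calls), 100 * mean(m$pattern == m$pattern_true)))
print(table(calls$tissue, calls$simplified))

stages <- tissues[1:4]
organs <- tissues[c(5, 6, 7, 2)]
shared <- calls[, list(
  shared_stages = shared_categories(simplified[match(stages, tissue)]),
  shared_organs = shared_categories(simplified[match(organs, tissue)])),
  by = c("gene1", "gene2")]
data.table::fwrite(shared, file.path(out, "shared_categories.tsv"), sep = "\t")
cat(sprintf("single shared category across stages: %.1f%%, across organs: %.1f%%\n",
            100 * mean(shared$shared_stages == 1),
            100 * mean(shared$shared_organs == 1)))
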