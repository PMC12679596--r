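# End-to-end synthetic study: simulate -> patterns -> acr -> dynamics ->
# trajectories, with a manifest and summary tabulations. Identical
# config + seed gives byte-identical outputs.

#' Pipeline run configuration
#'
#' Aggregates the analysis thresholds, the synthetic-study configuration
#' and the run flags.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; all stage randomness derives from it.
#' @param synth A [synth_config()].
#' @param coexpr_high,coexpr_low,fc,sd_thr Expression-pattern rule
#'   thresholds.
#' @param conserved_B Conservation threshold on the BLASTed ratio, plus
#'   \code{strict_B} stricter alternatives reported alongside.
#' @param qc_rho Replicate-correlation QC cutoff.
#' @param de_lfc,de_alpha Cell-type-specificity test thresholds.
#' @param k1_distance,s_min Trajectory clustering parameters.
#' @param mask_self Reserved flag for excluding self-hits of tandem
#'   duplicates (off: faithful default).
#' @param pooled_jaccard Use the pooled Jaccard variant.
#' @param strict_recent_split Require 2:2 splits to match recent pairs.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, synth = synth_config(),
                       coexpr_high = 0.9, coexpr_low = 0.5, fc = 1,
                       sd_thr = 1, conserved_B = 0.1,
                       strict_B = c(0.2, 0.4, 0.6, 0.8), qc_rho = 0.75,
                       de_lfc = 1, de_alpha = 0.05, k1_distance = 0.35,
                       s_min = 0.25, mask_self = FALSE,
                       pooled_jaccard = FALSE, strict_recent_split = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(seed, stage) {
  # deterministic child seeds, kept within 32-bit integer range
  (seed * 7919L + stage * 104729L) %% 2147483562L + 1L
}

#' Run the full synthetic pipeline
#'
#' Runs all stages in dependency order and writes per-stage TSVs, a
#' manifest echoing the resolved configuration, and summary tabulations
#' (pattern counts per tissue, mechanism x simplified-category
#' cross-table, conservation-state proportions, accessibility distances,
#' scenario counts and recovery rates against the planted truth).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, ...)
  log_msg <- function(...) message("[dupdiverge] ", sprintf(...))

  ## stage 1: simulate ----
  set.seed(stage_seed(config$seed, 1L))
  cfg <- config$synth
  sim <- gen_duplicated_genome(cfg)
  expr <- gen_expression(cfg, sim$pairs)
  traj <- gen_trajectories(cfg, sim$quads, acrs = sim$acrs)
  Biostrings::writeXStringSet(sim$genome, outfile("genome.fa"))
  write_gff3(sim$genes, outfile("genes.gff3"))
  write_bed(sim$acrs, outfile("acrs.bed"))
  data.table::fwrite(sim$pairs, outfile("pairs.tsv"), sep = "\t")
  data.table::fwrite(sim$quads, outfile("quads.tsv"), sep = "\t")
  ape::write.tree(sim$trees, outfile("trees.nwk"))
  for (tis in names(expr$counts)) {
    write_counts(expr$counts[[tis]]$counts,
                 outfile(sprintf("counts_%s.tsv", tis)))
  }
  data.table::fwrite(expr$truth, outfile("truth_patterns.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$pair_acrs, outfile("truth_pair_acrs.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$truth$quad_acrs, outfile("truth_quad_acrs.tsv"),
                     sep = "\t")
  data.table::fwrite(traj$truth, outfile("truth_trajectories.tsv"), sep = "\t")
  log_msg("simulate: %d pairs, %d quads, %d ACRs, %d tissues",
          nrow(sim$pairs), nrow(sim$quads), nrow(sim$acrs),
          length(expr$counts))

  ## stage 2: expression patterns ----
  set.seed(stage_seed(config$seed, 2L))
  calls <- data.table::rbindlist(lapply(names(expr$counts), function(tis) {
    classify_pairs(expr$counts[[tis]], sim$pairs, tissue = tis,
                   qc_rho = config$qc_rho,
                   coexpr_high = config$coexpr_high,
                   coexpr_low = config$coexpr_low,
                   fc_threshold = config$fc, sd_threshold = config$sd_thr)
  }))
  calls <- merge(calls, expr$truth[, c("gene1", "gene2", "tissue", "pattern")],
                 by = c("gene1", "gene2", "tissue"), suffixes = c("", "_true"))
  data.table::setorder(calls, tissue, gene1)
  stages <- cfg$tissues[1:4]
  organs <- cfg$tissues[c(5, 6, 7, 2)]
  shared <- calls[, {
    sc_st <- shared_categories(simplified[match(stages, tissue)])
    sc_or <- shared_categories(simplified[match(organs, tissue)])
    list(shared_stages = sc_st, shared_organs = sc_or)
  }, by = c("gene1", "gene2")]
  data.table::fwrite(calls, outfile("pattern_calls.tsv"), sep = "\t")
  data.table::fwrite(shared, outfile("shared_categories.tsv"), sep = "\t")
  log_msg("patterns: %d calls, recovery %.3f", nrow(calls),
          mean(calls$pattern == calls$pattern_true))

  ## stage 3: ACR conservation ----
  set.seed(stage_seed(config$seed, 3L))
  assoc <- suppressWarnings(associate_acrs(sim$acrs, sim$genes))
  pair_rows <- list(); pair_sums <- list()
  for (i in seq_len(nrow(sim$pairs))) {
    pr <- sim$pairs[i]
    cons <- pair_acr_conservation(pr, sim$acrs, assoc, sim$genes, sim$genome,
                                  sim$chrom_lengths,
                                  b_threshold = config$conserved_B)
    if (nrow(cons)) cons$pair_id <- pr$pair_id
    pair_rows[[i]] <- cons
    pair_sums[[i]] <- pair_acr_summary(pr, cons)
  }
  pair_cons <- data.table::rbindlist(pair_rows, fill = TRUE)
  pair_sum <- data.table::rbindlist(pair_sums)
  quad_rows <- list()
  for (i in seq_len(nrow(sim$quads))) {
    qc <- quad_conservation(sim$quads[i], sim$acrs, assoc, sim$genes,
                            sim$genome, sim$chrom_lengths,
                            b_threshold = config$conserved_B)
    if (nrow(qc)) qc$set_id <- sim$quads$set_id[i]
    quad_rows[[i]] <- qc
  }
  quad_cons <- data.table::rbindlist(quad_rows, fill = TRUE)
  data.table::fwrite(pair_cons, outfile("pair_acr_conservation.tsv"), sep = "\t")
  data.table::fwrite(pair_sum, outfile("pair_acr_summary.tsv"), sep = "\t")
  data.table::fwrite(quad_cons, outfile("quad_acr_conservation.tsv"), sep = "\t")
  log_msg("acr: %d pair-ACR alignments, %d quad-ACR alignments",
          nrow(pair_cons), nrow(quad_cons))

  ## stage 4: accessibility dynamics ----
  set.seed(stage_seed(config$seed, 4L))
  acc_stage <- gen_accessibility(cfg, sim$acrs$acr_id, conditions = stages)
  acc_organ <- gen_accessibility(cfg, sim$acrs$acr_id, conditions = organs)
  ent_dist <- function(acr_ids) {
    if (length(acr_ids) == 0L) return(c(NA_real_, NA_real_))
    c(jaccard_distance(accessibility_profile(acr_ids, acc_stage),
                       pooled = config$pooled_jaccard),
      jaccard_distance(accessibility_profile(acr_ids, acc_organ),
                       pooled = config$pooled_jaccard))
  }
  dyn <- data.table::rbindlist(lapply(seq_len(nrow(sim$pairs)), function(i) {
    ids <- assoc$acr_id[assoc$gene_id %in%
                          c(sim$pairs$gene1[i], sim$pairs$gene2[i])]
    d <- ent_dist(ids)
    data.table::data.table(entity = sim$pairs$pair_id[i], type = "pair",
                           n_acrs = length(ids), distance_stages = d[1L],
                           distance_organs = d[2L])
  }))
  dynq <- data.table::rbindlist(lapply(seq_len(nrow(sim$quads)), function(i) {
    g <- unlist(sim$quads[i, c("gene1", "gene2", "gene3", "gene4")],
                use.names = FALSE)
    ids <- assoc$acr_id[assoc$gene_id %in% g]
    d <- ent_dist(ids)
    data.table::data.table(entity = sim$quads$set_id[i], type = "quad",
                           n_acrs = length(ids), distance_stages = d[1L],
                           distance_organs = d[2L])
  }))
  dyn <- rbind(dyn, dynq)
  data.table::fwrite(dyn, outfile("accessibility_distances.tsv"), sep = "\t")
  log_msg("dynamics: %d entities", nrow(dyn))

  ## stage 5: trajectories ----
  set.seed(stage_seed(config$seed, 5L))
  de <- celltype_specific_genes(traj$counts, lfc = config$de_lfc,
                                alpha = config$de_alpha)
  traj_calls <- data.table::rbindlist(lapply(seq_len(nrow(sim$quads)), function(i) {
    g <- unlist(sim$quads[i, c("gene1", "gene2", "gene3", "gene4")],
                use.names = FALSE)
    rp <- recent_pair_partition(sim$trees[[i]], g)
    flags <- de$specific[g, , drop = FALSE]
    res <- if (all(rowSums(flags) == 0)) {
      list(scenario = "unresolved", k = NA_integer_, sizes = integer(0))
    } else {
      infer_trajectory(flags, rp, k1_distance = config$k1_distance,
                       s_min = config$s_min,
                       strict = config$strict_recent_split)
    }
    data.table::data.table(set_id = sim$quads$set_id[i], k = res$k,
                           sizes = paste(res$sizes, collapse = ":"),
                           scenario = res$scenario)
  }))
  scen_names <- TRAJ_SCENARIOS[1:5]
  traj_calls <- merge(traj_calls, traj$truth, by = "set_id")
  traj_calls[, scenario_true := scen_names[scenario.y]]
  data.table::setnames(traj_calls, "scenario.x", "scenario")
  traj_calls[, scenario.y := NULL]
  data.table::fwrite(traj_calls, outfile("trajectory_calls.tsv"), sep = "\t")
  log_msg("trajectories: %d quads, recovery %.3f", nrow(traj_calls),
          mean(traj_calls$scenario == traj_calls$scenario_true))

  ## summary + manifest ----
  summary <- list(
    pattern_counts = as.list(table(calls$tissue, calls$pattern)),
    pattern_recovery = mean(calls$pattern == calls$pattern_true),
    mechanism_by_category = as.list(table(
      sim$pairs$mechanism[match(calls$gene1, sim$pairs$gene1)],
      calls$simplified)),
    shared_single_stages = mean(shared$shared_stages == 1),
    shared_single_organs = mean(shared$shared_organs == 1),
    conservation_states = as.list(table(
      unique(quad_cons, by = "acr_id")$state)),
    mean_distance_stages = mean(dyn$distance_stages, na.rm = TRUE),
    mean_distance_organs = mean(dyn$distance_organs, na.rm = TRUE),
    scenario_counts = as.list(table(traj_calls$scenario)),
    trajectory_recovery = mean(traj_calls$scenario == traj_calls$scenario_true))
  manifest <- list(seed = config$seed,
                   config = config[setdiff(names(config), c("synth", "out_dir"))],
                   synth = unclass(config$synth),
                   outputs = sort(list.files(config$out_dir)))
  jsonlite::write_json(summary, outfile("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(sim = sim, expr = expr, traj = traj, calls = calls,
                 shared = shared, pair_cons = pair_cons, pair_sum = pair_sum,
                 quad_cons = quad_cons, dynamics = dyn,
                 trajectory_calls = traj_calls, summary = summary))
}
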