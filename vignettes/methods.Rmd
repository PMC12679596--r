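---
title: "Methods: measuring expression and cis-regulatory divergence of duplicated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring expression and cis-regulatory divergence of duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dupdiverge` studies what happens to the two (or four) copies of a
duplicated gene: whether they keep the same expression program across
cell types, and whether the accessible chromatin regions (ACRs) around
them — the carriers of cis-regulatory information — remain recognizable
between copies. This vignette explains the models and procedures, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the analysis was
genuinely open.

## Coordinates and inputs

All intervals are handled internally as 0-based half-open; GFF3 input is
converted once, on read. Duplicate-pair tables (with duplication-
mechanism labels WGD/TD/PD/TRD/DSD) and 4-gene-set tables are consumed
as inputs: classifying duplication mechanisms is upstream of this
package, as is peak calling and nucleus-level processing — only
pseudobulk counts (cell type × replicate) enter here.

## Expression patterns of duplicate pairs

Within one tissue, cell types are kept only when their two pseudobulk
replicates agree (Spearman correlation above 0.75; a correlation exactly
at the threshold fails). Counts are normalized to CPM; genes with
CPM ≥ 1 in at least 2 samples are treated as expressed — a deterministic
surrogate for the usual count-based expression filter, chosen so that
the expressed/non-expressed boundary is exactly reproducible. Genes with
zero counts everywhere are non-expressed.

For a pair, per-cell-type replicate-mean CPM values $c_1, c_2$ give a
fold-change profile $f = \log_2((c_1+1)/(c_2+1))$; the pseudocount
bounds the ratio when one copy is silent in a cell type. Three
statistics summarize the pair: $r$, the Pearson correlation of
$\log_2(\mathrm{CPM}+1)$ profiles across cell types; $m = |\bar f|$; and
$s = \mathrm{sd}(f)$ (sample SD). Two decisions deserve note:

* **Coexpression measure.** $r$ is Pearson on log-CPM profiles
  (Spearman available as an option). This is the simplest statistic
  compatible with the 0.9/0.5 rule thresholds; a network-derived
  coexpression score would add machinery without changing the rule
  structure.
* **$m$ as the absolute mean, not the mean absolute.** With
  $m = |\mathrm{mean}(f)|$, paralogue dominance demands a *consistent
  direction* of differential expression across cell types, which is what
  dominance means; mean-of-absolute would conflate dominance with
  specialization.

The rules are applied in order: both silent → non-expressed; exactly one
expressed → mono-expressed; then (r, m, s) thresholds define dosage
balanced, paralogue dominance, specialization and divergence, with
everything else "others". The printed rules leave the cell
(r > 0.9, m < 1, s ≥ 1) and the band 0.5 ≤ r ≤ 0.9 uncovered; both fall
to "others" by rule exhaustion, and the classifier is deliberately a
total function. Patterns consolidate to four simplified categories;
when sharing is counted across four stages or four organs,
non-expression is dropped whenever any expressed category co-occurs, so
"one shared category" means one shared *expressed* behavior unless the
pair is silent everywhere.

## Cell-type-specific genes

Per cell type, the replicate pseudobulk columns are compared against an
equal number of reference columns drawn uniformly at random from the
other cell types of the tissue, using the negative-binomial exact test
with common dispersion (edgeR) and BH adjustment across genes;
log2FC > 1 and adjusted P < 0.05 flag the gene as highly expressed
there. The reference draw uses whole replicate columns rather than a
multinomial pool of all other cell types: pooling would shrink the
reference group's biological variance below the target group's and
distort the exact test's calibration, whereas sampled columns keep both
groups exchangeable under the null. One draw is performed per cell type
(no repetition), under the pipeline RNG.

## ACR conservation between duplicates

The gene closest to each ACR (distance 0 when overlapping, ties broken
lexicographically by gene id, and documented as such) is its associated
gene. The alignment target for a duplicate is its *reference region*:
from the start of the nearest upstream neighbor gene to the end of the
nearest downstream neighbor gene, clipped at chromosome ends. The
inclusive span (neighbor bodies included) is used; for tandem
duplicates these regions overlap and an ACR can hit its own locus —
the faithful default keeps such hits, with self-masking available as an
option.

The aligner is a seed-and-extend local aligner parameterized like a
short-sequence nucleotide search: exact 7-mer seeds on both strands,
reward +1, penalty −1, gap of length $k$ costing $5 + 2k$. Seeds are
clustered by diagonal (band 32) and each cluster is resolved by a full
affine-gap Smith–Waterman with traceback inside a window padded 50 bp
around the cluster — so a reported score can never exceed the
unrestricted Smith–Waterman score, and in practice equals it whenever a
seed survives (tests require ≥ 95% exact score agreement on planted
cases and never-over-scoring). HSPs pass at E ≤ 1e−3 with
$E = 2 K m n e^{-\lambda S}$: $\lambda$ is solved numerically from the
score moment equation ($\ln 3$ at equal base composition) and $K$ uses
the closed form $(q-p)^2/q$ of the ±1 score lattice (1/3), matching the
tabulated value for this scheme. Ungapped parameters are applied to
gapped HSPs; under ±1 scoring with these gap costs, gaps are rare and
the approximation is mildly liberal. A Monte-Carlo null (random 300 bp
vs 5 kb) shows the realized E-values are, if anything, conservative.

Per ACR, accepted HSPs are reduced greedily by score to a set with
non-overlapping query coverage; the BLASTed ratio is
$B = \text{covered query length}/\text{ACR length}$ (bounded by 1 by
construction — the summed-HSP union is used rather than the best HSP
alone, both being defensible readings of "length of the BLASTed
sequence") and the mismatch rate is
$M = \sum \text{mismatches} / \sum \text{aligned length}$ over the same
set. B > 0.1 (≈ 50 bp for a typical ACR) defines conservation; stricter
thresholds (0.2–0.8) are exposed for sensitivity analyses. With no HSP
the ACR is unBLASTed (B = 0, M undefined). Across a 4-gene set, each
ACR is aligned against the other three reference regions; the number of
alignments with B > 0.1 is its conservation count, mapped 0 → unique,
1 → two-copy, 2–3 → multi-copy. On synthetic sets with per-branch
mutation, multi-copy ACRs (retained since the first duplication) show a
higher mean M than two-copy ACRs (recent retention only), reproducing
the expected gradual accumulation of variation.

## Accessibility dynamics

For an entity (pair or quad) with ACR set $A_c$ accessible in condition
$c$, the distance between conditions $a, b$ is
$1 - |A_a \cap A_b| / |A_a \cup A_b|$ and the reported value is the mean
over the 6 unordered pairs of 4 conditions. The sentence defining the
statistic admits a pooled reading (shared-in-all over present-in-any);
both are implemented, pairwise-average being the default as the standard
reading of cross-condition overlap. A condition pair with both sets
empty contributes 0 (identical sets); an entity with no accessible ACR
anywhere is NA.

## Trajectories of cell-type-specific expression

Quads where all four genes are expressed and at least one is cell-type
specific are clustered on their binary specificity vectors: Jaccard
distances, Ward.D2 linkage for the dendrogram, and — because a quad has
at most 4 informative rows — the partition at each candidate $k$ is
taken as the exact minimizer of the Ward objective over all partitions
(at most 15), which removes the occasional greedy suboptimality of
agglomeration while agreeing with it whenever the structure is clear.
All-zero rows are removed before clustering and rejoin as one implicit
"no specificity" group when cluster sizes are read off.

Choice of $k$: the average silhouette width over $k \in \{2..n\}$,
with three guards that the source procedure leaves open and that are
fixed here as package policy:

* **Single-cluster rule.** Silhouette is undefined at $k=1$; a quad is
  a single cluster when all pairwise distances are ≤ 0.35. The
  threshold is configurable; 0.35 rather than a stricter 0.2 because
  Jaccard distances on realistic specificity vectors (8–16 cell types)
  are coarse-grained — two discordant bits between two 8-bit profiles
  already exceed 0.2, so a stricter rule would shatter genuinely
  uniform quads at moderate noise.
* **No-structure rule.** When no $k$ reaches an average silhouette of
  0.25, the genes are called all-distinct ($k = n$): silhouette near
  zero everywhere is evidence of no grouping, not of one group.
* **Ties break toward larger k.** A coarse and a fine partition with
  identical silhouette (a structural tie for 1:2:1 layouts) resolve to
  the finer one, which carries the information; the within-cluster sum
  of squares (elbow curve) is reported alongside.

Scenario mapping: $k=1$ → specificity predates the first WGD; $k=2$
with a 2:2 split → before the second WGD, where strict mode (default)
additionally requires the split to coincide with the recent-pair
partition from the gene tree — a 2:2 split across recent pairs is a
different event and is left unresolved (the literal rule is available
with strict mode off); 1:3 → after the second WGD; 1:2:1 → combination;
four singletons → complex. Recent pairs are the two cherries of the
quad's gene tree; topologies without two cherries (caterpillar,
polytomy) leave the quad unresolved.

## The synthetic-data generator

The generator is the package's study design, not a test fixture. It
emulates:

* **Genomes.** One chromosome per pair (two loci) or quad (four loci);
  each locus is neighbor gene — gap — 2 kb ACR window — gene — gap —
  neighbor gene, with the neighbor placed farther from the ACR window
  than the window is deep, so nearest-gene association is unambiguous
  by construction (collisions can be built explicitly for tie tests).
  ACR copies at partner loci are substituted per base (always to a
  different base, so the planted rate equals the expected mismatch
  rate), optionally truncated by one contiguous block (the simplest
  model producing partial BLASTed ratios), lost entirely, or
  complemented by de novo ACRs. Quads apply substitutions per branch of
  ((A,B),(C,D)), so recent copies diverge less than ancestral ones, and
  plant conservation states by copy presence (multi-copy in all four,
  two-copy within one recent pair, unique in one gene).
* **Counts.** Latent per-cell-type log2 means (base profile N(7, 2.5)
  truncated to [1, 13]) with pattern-specific offsets: dominance adds a
  constant 2.0 (twice the rule threshold); specialization boosts a
  minority of cell types — the highest-expression ones, so the latent
  coexpression stays high, as amplification of an existing program;
  "others" is planted as the uncovered rule cell (high r, near-zero
  mean, high SD): balanced ±2.2 offsets amplifying the dynamic range.
  Rejection sampling enforces every pattern's inequalities with margin
  (e.g. r ≥ 0.93 vs the 0.9 rule, m and s at least 0.25 from their
  thresholds), which is what guarantees 100% classifier recovery in the
  zero-noise limit. Counts are negative-binomial around the latent
  means (dispersion 0.05 by default); Poisson is the dispersion → 0
  limit, and `noise = "none"` gives deterministic rounded means — the
  regime "zero noise" refers to, since a Poisson draw cannot guarantee
  exact recovery.
* **Trajectories.** Specificity vectors are block-unions over cell
  types (16 by default), giving large between-group and zero
  within-group distances; the 1:2:1 scenario places its two singletons
  nearer to the shared pair than to each other so that the 3-cluster
  solution is the silhouette optimum with margin rather than a tie.
  Perturbation experiments flip an exact fraction of matrix bits.
* **Accessibility.** Every ACR starts accessible in all conditions and
  is silenced per condition with a turnover probability (0.15 default);
  higher turnover yields strictly higher mean Jaccard distance.

What it does **not** emulate: read-level or nucleus-level data (no
FASTQ, no barcodes), selection or drift, trans-acting divergence,
correlated ACR–expression losses, or the mixture complexity of real
tissues. Pattern labels are drawn independently per tissue, so
cross-tissue shared-category fractions on synthetic data are low by
construction and exercise the counting logic, not the biological
persistence of patterns. Recovery rates on this generator therefore validate the
*machinery* — rule logic, alignment scoring, clustering, calibration —
not the biological effect sizes of any real dataset.

## Numerical choices and problem sizes

Determinism is a contract: a single seed drives each pipeline run, with
per-stage child seeds derived arithmetically; identical config + seed
reproduces every output byte for byte. Degenerate inputs are defined,
not special-cased: empty HSP tables give B = 0 with M = NA; profiles
with zero variance give r = NA; both-empty condition pairs contribute
distance 0; ties in nearest-gene association and in partition
enumeration break deterministically (lexicographic, first-minimizer).

The validation suite runs at sizes chosen to exercise the statistics
while staying desk-sized: 500 pairs × 4 tissues for pattern recovery,
200 planted alignments against full dynamic programming, ~100 ACRs per
substitution-rate level for mismatch calibration, 20–25 quads for
conservation-state recovery, 200 quads for trajectory recovery, and a
200-gene × 50-replicate null for test calibration. The analysis
drivers default to 150 pairs and 40 quads.

## Known limitations

* The aligner's E-values use ungapped Karlin–Altschul parameters; for
  heavily gapped homologies at other scoring schemes they would need
  recalibration.
* The exact-Ward partition search is only feasible because quads have
  ≤ 4 informative rows; larger gene sets would need the greedy path.
* The specificity test assumes 2 replicates per cell type and inherits
  edgeR's small-sample behavior; with more replicates the reference
  draw generalizes but calibration should be rechecked.
* Scenario calling reads cluster *structure* only; it does not model
  the probability of convergent specificity gains, which would confound
  a 2:2 split matching the recent pairs with independent parallel
  gains.
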