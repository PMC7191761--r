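---
title: "Methods: CYP mining, classification and pan-CYPome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CYP mining, classification and pan-CYPome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypome)
```

# Overview

Cytochrome P450 monooxygenases (CYPs, P450s) form one of the largest
protein superfamilies, found in every kingdom, and a genome's full CYP
complement (its CYPome) is a compact functional fingerprint of its
metabolic capabilities. `cypome` analyses CYPomes at the level of a
*genome population*: given one protein FASTA per genome and a named
reference CYP set, it identifies and classifies every CYP, tabulates
them in a Genome-CYP Matrix (GCM: CYP names in rows, genomes in
columns, sequence counts as elements), and derives four
population-level views from the GCM — pan/core-CYPome rarefaction
curves with a power-law fit, a CYP co-occurrence network, hierarchical
genome clustering, and CYP frequency clouds.

The pipeline has four stages:

1. **Redundancy reduction.** All proteomes are pooled (headers tagged
   `genome|id`) and clustered greedily at 55% identity; only cluster
   centroids move forward, which keeps the expensive scanning and
   classification steps proportional to the number of distinct protein
   shapes rather than to the number of sequences.
2. **CYP identification.** Centroids are scanned against one or more
   position-specific scoring matrices (PSSMs) of the conserved P450
   domain; a centroid is a CYP when its best hit reaches an E-value of
   at most 1e-5.
3. **CYP classification.** CYP centroids are searched against the named
   reference set and named by the standard nomenclature identity rules
   (≥ 40% identity: same family; ≥ 55%: same subfamily; otherwise new
   groups). Labels propagate from centroids to their cluster members.
4. **GCM analyses** at family and subfamily level.

# Sequence identity

One identity definition is used everywhere (clustering, classification,
fixture verification): sequences are aligned globally
(Needleman–Wunsch, BLOSUM62, affine gap penalties of 10 to open and 1
per extended position, end gaps penalised) and identity is the number
of identical columns divided by the number of alignment columns
*excluding terminal-gap columns*. Excluding terminal gaps follows
common protein-clustering practice: a perfect domain contained in a
longer protein should not be diluted by the unaligned tails.
`pairwise_identity(..., definition = "all-columns")` divides by the
full alignment length instead, for sensitivity analyses; results near
the 55% clustering cutoff can differ between the two conventions, which
is why the definition is a visible, configurable parameter rather than
an internal detail.

The alignment itself is delegated to `Biostrings::pairwiseAlignment()`;
the identity computation on the aligned strings is this package's, and
the test suite checks it against an independent pure-R
dynamic-programming oracle.

# Greedy centroid clustering

Clustering follows the classic greedy incremental discipline: records
are sorted by decreasing length (ties broken lexicographically by
tagged id, so runs are fully deterministic), and each record joins the
*first* existing centroid it matches at the threshold (default 0.55) or
founds a new cluster. First-match (rather than best-match) mirrors the
default behaviour of the widely used greedy clustering tools this stage
emulates; `best_match = TRUE` is available. Two consequences worth
knowing:

* every member is ≥ 55% identical to its centroid, and
* centroids are pairwise < 55% identical (each later centroid was
  rejected by all earlier ones).

A k-mer prefilter (length-5 amino-acid words; centroids sharing no word
with the query are skipped) accelerates the scan. The filter can only
*miss* low-identity matches near the threshold, never invent them;
`exact = TRUE` disables it, and the correctness tests always run
exactly. Word length 5 makes a false skip at ≥ 55% identity essentially
impossible for real protein lengths (a 55%-identical pair of 200-residue
proteins shares dozens of 5-mers).

# Domain identification and E-values

The PSSM is built from an alignment of reference CYP domain sequences:
columns with more than 50% gaps are dropped, and each surviving column
scores residue *a* as `2·log2(f_a / b_a)` in half-bits, with `f_a` the
+1-pseudocount column frequency and `b_a` the background (uniform 0.05
by default). `X` scores 0 — exactly its background expectation — so
ambiguity neither helps nor hurts a hit. The scan is ungapped: every
window of profile width is scored and the best window is reported. An
ungapped scan is a deliberate simplification; the conserved P450 core
is compact, and the fixtures (below) model domain divergence as
substitutions, which an ungapped scan handles at full power. Indel-rich
domains would lose score, which is a known limitation; an adapter
around `identify_cyps()` can substitute any external domain-search
engine without touching the rest of the pipeline.

Significance uses the Karlin–Altschul form `E = K·m·n·exp(−λS)` (m =
query residues, n = profile-database residues) with λ and K fitted
*empirically per profile*: 500 decoys drawn from the background are
scanned, and a Gumbel distribution is fitted to their maximum window
scores by maximum likelihood (`calibrate_profile()`, fixed seed). This
gives honestly calibrated tail probabilities for exactly the statistic
the pipeline thresholds on — the best window score — without assuming
the asymptotic theory applies to short profiles. The default cutoff
(1e-5) is deliberately harsh; on the synthetic fixtures true CYPs and
decoys are separated by more than three orders of magnitude in E-value,
so the precise cutoff is not delicate there.

# Classification rules

`best_hit_classify()` takes the best-identity reference (ties broken by
the lexicographically smallest reference name, so reference file order
never matters) and applies the inclusive nomenclature thresholds:

| best identity | family | subfamily |
|---|---|---|
| ≥ 0.55 | best hit's | best hit's |
| 0.40 – < 0.55 | best hit's | new |
| < 0.40 | new | new |

Sequences falling into "new" groups are clustered among themselves with
the same thresholds (deterministic order by tagged id) and given
run-scoped working names: `NF<k>` / `NF<k>.<j>` for new families and
their subfamilies, `<family>-NS<j>` for new subfamilies inside known
families. These are *not* nomenclature-committee assignments — real CYP
names are allocated by the International P450 Nomenclature Committee —
and the run log says so whenever novel groups are emitted.

Cluster members inherit their centroid's labels. This is implied by
building the GCM from cluster membership plus centroid classification,
and it is the one place where a member's own best reference identity is
never computed; a member sitting within 5 percentage points of a rule
boundary (relative to its centroid) is flagged in the `near_boundary`
column of `C_classification.tsv` so downstream users can audit the
risky inheritances.

# GCM analyses

**Pan/core curves.** For each subset size *n* from 1 to *N* genomes, up
to 300 *distinct* genome subsets are drawn (exhaustive enumeration when
`choose(N, n) ≤ 300`, so small populations are computed exactly and
deterministically); the pan size of a subset counts GCM rows present in
at least one subset genome, the core size counts rows present in all of
them. Both means and medians are reported per *n*. The power law
`n = σN^γ` is fitted by ordinary least squares on the log-log scale.
The fit targets the mean curve by default with the median available
(`fit_target = "median"`) — the two summaries are both in common use
and practically indistinguishable on saturated sampling; no model is
fitted to the core curve. γ ≈ 0 indicates a closed (saturating)
pan-CYPome; substantially positive γ, an open one.

**Co-occurrence.** With `B = indicator(M > 0)`, the weighted matrix is
`B·Bᵀ` with zeroed diagonal (entries = genomes sharing the pair) and
the unweighted adjacency replaces non-zeros by 1. Exports are plain
edge lists and node tables (occurrence counts *and* total sequence
counts per node, since either can be meant by "node size"), importable
into Gephi or Cytoscape; no interactive visualisation is bundled.

**Genome clustering.** `stats::hclust` on the count matrix, Euclidean
distance and average linkage by default (both configurable; defaults
chosen as the most common heatmap-clustering pairing). Leaf orders and
the merge tree are always written as text; the heatmap image needs the
`pheatmap` package and a working graphics device, and the pipeline
degrades gracefully (a warning, tables intact) without them.

**CYP cloud.** Row totals ranked in decreasing frequency, ties broken
by name; the image (a deterministic spiral text cloud) is decorative,
the table is the interface.

# Synthetic data generator

`write_synth_dataset()` emits everything the pipeline consumes —
reference FASTA, domain alignment, genome FASTAs — plus a ground-truth
manifest, fully determined by one seed (byte-identical reruns). Its
defaults define the package's standard test conditions: 6 genomes, 4
reference families × 2 subfamilies, 8 CYPs and 6 decoys per genome,
protein lengths 280–340, a 60-residue conserved core present in every
CYP and (verified, at 10-mer resolution) in no decoy.

The mutation model is substitution-only: positions are drawn uniformly,
replacements from a BLOSUM62-conditional distribution (never the
original residue). Substitution-only evolution keeps the
identity-vs-mutation-count mapping essentially deterministic, which is
what lets the generator *engineer* identities into bands that stay ≥ 5
percentage points clear of both rule boundaries: members ≥ 0.70
mutual identity within a subfamily (0.85–0.95 to their reference),
subfamily references at 0.45–0.54 within a family (disjoint mutation
sets of a shared ancestor), families ≤ 0.30 apart. All realized
identities are *verified* by alignment after generation, with bounded
retries, rather than trusted.

What passing the end-to-end fixture tests shows, therefore, is that the
pipeline recovers a truth that is recoverable by construction:
sensitivity/specificity 1.0 and exact GCM recovery on fixtures say the
machinery is correct, not that real proteomes — with indels, promiscuous
domains, fragmented gene models and identities *on* the boundaries —
would be called perfectly. The near-boundary flags and configurable
thresholds exist precisely because real data is not this clean.

# Numerical and design choices

* **Determinism.** Every stochastic step (subset sampling, decoy
  calibration, fixture generation) takes an explicit seed; pipeline
  reruns with the same config and seed produce byte-identical tables.
* **Tie-breaks** are all lexicographic (record ids for processing
  order, reference names for best hits, CYP names for cloud ranks) —
  arbitrary but fixed.
* **Problem sizes.** The bundled test conditions (84 pooled sequences,
  6 genomes) were chosen so the full suite, including two extra
  population runs for the inclusion–exclusion check, completes in a few
  minutes on one CPU while still exercising every code path;
  the algorithms themselves have no small-N assumptions.
* **Command-line surface.** The CLI (`inst/cli/cypome.R`) exposes two
  commands, `synth` and `run`; the intermediate stages are exported R
  functions, and since `run` persists every intermediate file, a
  partial re-run is a function call on an existing output rather than a
  separate subcommand. This keeps one orchestration path under test
  instead of eight.
* **Degenerate inputs.** Empty FASTA files error; records with
  non-amino-acid characters are skipped with a warning (terminal `*`
  stripped silently); an empty CYP set yields 0-row GCMs and analyses
  that report empty tables rather than failing; single-genome runs skip
  genome clustering with a warning.

# Known limitations

* Ungapped domain scan (above): indel-rich domain variants score low.
* Whether the 55% clustering convention of upstream greedy tools counts
  terminal gaps is not documented by those tools; near-threshold
  memberships can differ between the two identity definitions offered.
* Greedy first-match clustering is order-dependent by design; the fixed
  length/lexicographic ordering makes it reproducible but not
  order-free.
* NF/NS working names are stable only within one run (and across runs
  on identical input); merging GCMs from separate runs is only sound
  for rows named from the shared reference set, which is exactly the
  scope of the inclusion–exclusion consistency check in the test suite.
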