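---
title: "Detecting bipartite TCF binding-site clusters and scoring defecation rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bipartite TCF binding-site clusters and scoring defecation rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrescan)
```

## The biological problem

TCF transcription factors are the nuclear endpoint of Wnt/ß-catenin
signaling. Most invertebrate TCFs — including *C. elegans* POP-1 — carry
two DNA-binding domains: the High Mobility Group (HMG) domain, which
recognizes the classical HMG site (high-affinity consensus `SCTTTGATS`,
S = G/C), and the C-clamp, which recognizes a second, shorter motif called
the Helper site (worm consensus `GCCRAnW`; R = A/G, W = A/T). Functional
Wnt response elements (WREs) in worms and flies typically pair one HMG
site with one or more nearby Helper sites, and the Helper sites are
essential for signal-dependent activation.

This package turns that observation into a reusable genome scanner. The
search criterion is deliberately simple and matches the one used to find
new POP-1 targets: a region scores positive when some **50-bp window**
contains **at least two Helper sites and one HMG site** above their score
cutoffs, scanning the **500 bp upstream** of every annotated translational
(TlSS) or transcriptional (TSS) start on **both strands**. Candidates are
then stratified by topology — whether an HMG site lies *between* two
Helper sites, the arrangement observed in validated WREs — by the number
of Helper sites within 50 bp of the HMG site, and by the presence of an
HMG–Helper pair in a consistent relative orientation.

A companion module reproduces the behavioral arithmetic used to describe
the defecation phenotype of *pop-1*-compromised animals: per-animal mean
pBoc cycle lengths, group summaries over those means, percent change
versus control, missed-expulsion rates, and Student's two-tailed t tests.

## The score model

Motif models are additive position weight matrices. Built from an aligned
set of $N$ functional sites with pseudocount $p$ and background
frequencies $q_b$, the weight of base $b$ at position $i$ is

$$ w_{ib} \;=\; \log_2 \frac{(n_{ib} + p\,q_b)/(N + p)}{q_b}, $$

and a window scores as $\sum_i w_{i,b_i}$, with the reverse complement
scored on the minus strand. A window "fires" when its score reaches the
matrix cutoff. Windows containing `N` score $-\infty$ and never fire — a
deliberately conservative choice that avoids imputing scores in gaps.

Matrices can also be loaded verbatim from a tab-delimited file
(`load_matrix()`), in which case the scores are applied exactly as
printed and round-trip bit-exactly through `write_matrix()`.

### The built-in matrices and their cutoffs

The original search matrices were distributed only as formatted
supplementary material, and the underlying functional site alignments
only as figure panels; neither is available as machine-readable data.
The package therefore ships *synthetic stand-in* site alignments
(`helper_sites_synthetic()`, `hmg_sites_synthetic()`, and matching
`inst/extdata/*_synthetic.*` files), designed once to the published
summary features rather than to any test outcome:

* the eight-site Helper alignment reproduces the published worm Helper
  consensus `GCCRAnW` under the default degeneracy rule (a base counts
  toward the consensus if observed at all; more than two qualifying bases
  collapse to `n`);
* the HMG alignment is centered on the published high-affinity consensus
  `SCTTTGATS`;
* each build set includes the optimal synthetic-reporter site embedded in
  the printed 27-bp HMG–Helper repeat unit (`GCCGCCA` on the plus strand,
  `CCTTTGATC` on the minus strand), since the original matrices also
  included the optimal sites.

The published cutoffs — 5.51 for Helper, 6.69 for HMG — are applied to
these matrices on the package's log2 log-odds scale (pseudocount 1,
uniform background). The normalization behind the original cutoffs was
never stated, so identical numeric cutoffs on a rebuilt matrix cannot be
assumed comparable to the original scanner; all genome-wide counts
obtained with the stand-in matrices should be read as properties of this
package's models, not as reproductions of the original hit list. Users
with access to the original matrices can load them verbatim and keep the
printed cutoffs, which removes that unknown entirely.

## Cluster detection

`find_clusters()` enumerates every 50-bp window position over a region's
hits; a window qualifies when it holds at least `min_helpers` *distinct*
Helper sites and `min_hmg` HMG sites (membership by hit start position;
full containment is available via `scan_config(membership =
"containment")`). Maximal runs of overlapping qualifying windows merge
into one reported cluster per locus, so a dense site neighborhood is one
candidate rather than dozens of window-shifted duplicates. Two further
rules keep counting honest:

* Helper hits that overlap on opposite strands by more than half the
  motif width collapse to one site, so a single palindromic locus cannot
  satisfy the two-Helper minimum by itself.
* Hit strand never constrains membership — candidate sequences may be
  functional in either orientation.

Topology (`classify_topology()`) is `HMG_BETWEEN_HELPERS` exactly when
some HMG hit has a Helper hit strictly before and strictly after it
within the cluster. `count_proximal_helpers()` reports the maximum number
of distinct Helper sites within ±50 bp of any single HMG hit, and
`detect_oriented_pair()` tests for an HMG–Helper pair in a configured
relative arrangement, evaluated in the reading direction of the HMG hit
so the predicate is invariant under reverse complementation. The ranked
report sorts between-Helpers topology first, then proximal-Helper count,
then aggregate score — a deterministic order chosen for diffability.

## Worked examples built into the package

`pophhop_repeat()` returns the printed 27-bp repeat unit of the
concatemerized synthetic reporter; six repeats carry exactly six HMG hits
(minus strand) and six Helper hits (plus strand), i.e. six HMG–Helper
pairs:

```{r pophhop}
pw <- default_pwms()
cc <- pophhop_concatemer(6)
nrow(scan_pwm(pw$hmg, cc))
nrow(scan_pwm(pw$helper, cc))
```

`synthetic_k08d12_region()` reconstructs the *described* arrangement of
the cluster found upstream of K08D12.3 — three Helper sites and one HMG
site, HMG between Helpers, all Helper starts within 50 bp of the HMG
start — in a fixed low-complexity spacer free of motif cores. It is a
synthetic stand-in for a genomic sequence that is not available as text,
and is labelled as such everywhere.

```{r k08}
res <- run_scan_pipeline(synthetic_k08d12_region(), pw$hmg, pw$helper)
res$report[, c("topology", "n_helpers", "n_hmg", "n_proximal_helpers")]
```

## The synthetic-data generator

`plant_genome()` produces regions of i.i.d. background DNA (uniform
composition by default; no Markov structure, matching the null model the
search itself assumes) and plants, in a configurable fraction of regions,
`helper_count` Helper words and one HMG word sampled from the matrices by
rejection until they rescore at `cutoff + margin`. Sites are laid out
left to right with gaps drawn from a spacing range (default 5–15 bp,
comfortably inside one 50-bp window and comparable to the tight spacing
of validated clusters), Helpers split around the HMG site for the
between-Helpers topology, and never overlap. Truth records carry the
exact coordinates, strands and words; identical specs are byte-identical
across runs.

What the generator deliberately does **not** emulate: genomic base
composition and repeat structure, chromatin or conservation signal,
overlapping or antisense sites, and degenerate borderline-scoring sites.
Passing recovery tests on planted genomes therefore demonstrates the
correctness of the scanning and clustering machinery — not genome-wide
sensitivity or precision on real promoters, which depend on the true
score distribution of functional sites.

`simulate_defecation()` draws per-animal cycle lengths from a normal
distribution truncated at zero (resampling non-positive draws — periods
are durations) and flags missed expulsions per cycle by a Bernoulli draw.
`table1_sim_spec()` packages the published per-genotype design: group
sizes of 12–26 animals, eight cycles per animal, the printed means and
SDs, and missed-expulsion probabilities. Truncation makes the realized
mean of a heavily dispersed group (e.g. mean 92.4 s, SD 49.5 s) sit a few
seconds above the nominal mean; at the published group sizes this bias is
well inside three standard errors, and the summaries recover every
nominal group mean at that tolerance.

## Statistics conventions

Group summaries average animals first — each animal contributes one mean
cycle length, and the group mean, sample SD ($n-1$), median and quartiles
are taken over those per-animal means. Whether the published SD was taken
over animal means or over all raw intervals is ambiguous; per-animal
means is the reading most consistent with the stated protocol and is what
`summarize_group()` implements (raw pooling is a one-line change on the
input frame). Quartiles use linear interpolation (R type 7); at n = 26
the difference from Tukey hinges is negligible, and the choice is
recorded here because no quartile rule was ever stated. Percent changes
are rounded half away from zero to one decimal, matching how such
percentages are conventionally reported. The t test is the classical
pooled-variance Student's test (the test named in the source material),
with Welch's variant behind `var_equal = FALSE`; zero pooled variance
with equal means returns p = 1 by convention, with unequal means it is an
error rather than a silent infinity.

## Numerical and design choices

* **Coordinates.** Region-local positions are 1-based, position 1 being
  −500 from the anchor and position 500 being −1. BED output converts to
  0-based half-open only at the file boundary.
* **Anchors.** TlSS is the first CDS codon per transcript; TSS the
  transcript 5′ end; both are emitted because the published anchor count
  (24,841) exceeds any single-anchor gene count, implying the union was
  searched. Upstream coding overlap is not masked. The exact annotation
  release behind the published funnel (24,841 regions → 115 clusters →
  19 after the topology filter) is unknown, so those counts are treated
  as order-of-magnitude context, not as reproducible targets; the
  package's funnel is instead validated for internal consistency and on
  planted synthetic genomes.
* **Tie-breaks.** Hits sort by start, then `+` before `−`, then score
  descending; PWM consensus ties resolve to the alphabetically first
  base. Everything downstream is deterministic given the inputs.
* **Merged loci.** The cluster count reported by the pipeline counts
  merged loci, not raw qualifying windows — the interpretation under
  which one dense candidate region is one cluster.
* **Problem sizes in tests.** Oracle-equivalence and recovery properties
  run on 200 random 500-bp regions, 100-region planted and background
  genomes, and the full published behavioral design (152 animals, 1,216
  cycles) — sizes chosen to exercise every code path while keeping the
  default check fast.

## Limitations

The stand-in matrices make absolute hit lists package-specific (see
above); the generator's planted sites are stronger than many real sites
near cutoff, so measured sensitivity is an upper bound; no statistical
enrichment p-value is computed for clusters (none was used in the
original search); and the interval simulator draws independent normal
periods, which cannot reproduce the strong arrhythmia of mutant animals —
only the group-level mean/SD/missed-expulsion structure that the
statistics module consumes.
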