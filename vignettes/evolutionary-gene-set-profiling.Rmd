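---
title: "Evolutionary profiling of disease gene sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary profiling of disease gene sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoprofiler)
```

# Overview

`evoprofiler` asks two evolutionary questions about a curated disease gene
set — *how old are its genes?* and *how constrained are they?* — and
answers both relative to the whole-proteome background. Four analysis
stages feed one another:

1. **Gene-set accounting**: normalized symbol lists, Venn partitions,
   annotation fractions.
2. **Phylostratigraphy**: a per-gene *phylostratigraphic age index* (PAI)
   from ortholog presence across a 16-level taxon ladder.
3. **Divergence**: per-gene *divergence index* (DI) from Nei–Gojobori
   (NG86) dN/dS over Hominidae ortholog pairs.
4. **Enrichment and networks**: binned set-vs-background chi-square tests
   with Benjamini–Hochberg adjustment, and hub extraction from
   confidence-filtered protein-interaction networks.

A fifth component, the seeded synthetic-data generators, produces inputs
with known ground truth for every stage and carries a ledger sufficient to
predict each downstream result exactly; it is how the package validates
itself.

# Gene-set handling

Symbols are normalized by trimming and uppercasing only. Alias or
symbol-history resolution is deliberately **not** applied: published gene
lists are intersected exactly as published, and any remapping would change
intersection counts in ways the list authors never intended. Venn
partitions are computed over all $2^k - 1$ membership regions (2–5 sets)
and are checked against brute-force membership enumeration in the test
suite. Annotation fractions are reported as one-decimal percents, the
rounding convention of the literature this style of accounting appears in;
whole-percent rounding is applied by the caller where a source reports
whole percents.

A combined disease set built from two source lists is the deduplicated
union; because published combined denominators are not always
reconstructible from the source lists alone, `unionSet()` accepts an
`expectedSize` and warns on mismatch instead of silently adopting either
number.

# Phylostratigraphy

The ladder runs from *Cellular Organisms* (stratum 1) through *Eukaryota*,
*Metazoa*, ... to *Homo sapiens* (stratum 16); smaller PAI = older gene.
Every reference species is mapped in advance to the stratum at which its
lineage diverges from the human lineage (`split_index`), and a gene's PAI
is simply the minimum split index over the species that carry an ortholog
of it. Precomputing the species-to-stratum map keeps the assignment pure
and order-invariant; an optional helper maps NCBI-style lineage strings
onto the ladder by deepest shared taxon name. Genes with no ortholog row
are excluded from distributions rather than imputed — an absence from the
orthology resource is not evidence of age.

Ortholog inference itself (clustering, BLAST thresholds, treatment of
multi-copy groups) is out of scope: presence is taken as given input,
because those choices belong to the orthology resource, not to the age
index.

# NG86 divergence and the DI

The dN/dS machinery is classic Nei–Gojobori (1986) counting:

* **Sites.** For each codon position, the synonymous fraction is
  (synonymous non-stop neighbors) / (non-stop neighbors); neighbors that
  would create a stop codon are excluded from numerator *and* denominator,
  so each position contributes one full site and $s + n = 3$ per sense
  codon. Pair totals average the two sequences. (Implementations differ in
  this stop-neighbor convention; one widely used library shrinks the
  denominator instead. The pathway-averaged difference counts below agree
  exactly between the two conventions, and at low divergence the resulting
  $\omega$ values differ by a few percent; the package's convention keeps
  the site total an invariant of the alignment length.)
* **Differences.** For codons differing at $k$ positions, every one of the
  $k!$ substitution orderings is classified step by step; orderings passing
  through a stop codon are discarded and counts averaged over the rest,
  with equal pathway weighting. If no stop-free pathway exists, the raw
  difference count is attributed to the nonsynonymous class, with a
  warning.
* **Distances.** $p_S = S_d/S$ and $p_N = N_d/N$ are Jukes–Cantor
  corrected, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; a proportion at or
  beyond $3/4$ is saturated and the distance undefined.

Codon pairs containing a gap, an ambiguous base or a stop codon in either
sequence are dropped pairwise before counting, with a skip count retained.
Boundary cases are made explicit rather than numeric accidents: identical
sequences report $\omega = 0$ flagged `no-substitutions`; $d_N = 0$ with
$d_S > 0$ reports $\omega = 0$; $d_S = 0$ with $d_N > 0$ is flagged
`undefined-infinite` and **excluded** from DI averaging, because mapping it
to any finite number would fabricate a divergence value.

The per-gene DI combines the defined pairwise $\omega$ over the available
Hominidae partners (chimpanzee, gorilla, orangutan in the motivating
design). The combination rule behind published DI values is a convention
rather than a derivation, so the package makes it a parameter: the default
is the arithmetic mean — the simplest order-independent combiner — with a
median alternative behind `combiner = "median"`. DI $< 1$ is labeled
stabilizing selection, DI $> 1$ positive, DI $\approx 1$ neutral.

# Enrichment testing

PAI uses one bin per stratum. DI uses a dedicated bin for exactly 0, then
$(0, 0.2)$, four width-0.2 interior bins and an open $[1, \infty)$ bin.
The 0, 0.2 and 1 edges are the thresholds used in selection-regime
reporting; the interior 0.2-width edges are a declared convention (a
histogram's exact interior edges are rarely printed, and nothing
downstream depends on them). The zero bin is kept separate because "no
nonsynonymous change in any pair" is a qualitatively different statement
than "small $\omega$".

Each bin is tested by a one-sample Pearson goodness-of-fit chi-square
(df = 1) of the set's (in-bin, out-of-bin) split against the background
proportions — *not* a 2×2 set-vs-rest test — because the design treats the
set as a draw from the background universe and computes expected counts
from the whole-proteome distribution. No continuity correction is applied
by default (expected counts in tested bins are large; a Yates switch
exists). Raw p-values are Benjamini–Hochberg adjusted across the testable
bins of one panel (one set × one scheme); bins with zero expected count
are reported untestable and excluded from the family. Stars are `*`
p_adj < 0.05, `**` < 0.01, `***` < 0.001; the middle threshold is included
for completeness even where a source only defines the outer two.

Set-level summaries report mean PAI and mean DI to two decimals over
covered genes, with coverage counts, so partial index coverage is always
visible.

# Network analysis

Edge tables are canonicalized on load (symbol normalization, undirected
deduplication, self-loop removal, range checks). The filter keeps edges
with confidence **strictly** greater than 0.9 — the verbatim reading of
"more than 0.9", switchable to ≥ — that carry the experimental evidence
channel; a channel is present when its per-channel score is positive, or
when its label appears in a `channels` column (edge-table dialects differ).
Hubs are nodes of degree ≥ 5 in the filtered graph. Hub comparison across
two networks labels origin (first / second / both) and the mTOR relation
with precedence *pathway member > mTOR-sensitive > neither*, so each hub
receives exactly one class. Graph primitives are delegated to `igraph`;
reproducing any specific published network requires the archived database
snapshot it was built from, which is why the package's network tests
operate on synthetic tables with planted structure.

# Synthetic data: what it emulates, and what it does not

The generators define the package's validation conditions:

* `simPresence()` — ortholog presence for a planted PAI distribution
  (default: a proteome-like profile with modes at strata 1 and 3 and a
  thin recent tail) over a synthetic 31-species panel covering all 16
  strata. Construction guarantees at least one species at exactly the
  planted stratum and none below it, so recovery must be exact; this
  validates the assignment logic, not the biology of orthology resources
  (patchy detection, contamination and multi-copy groups are not
  modeled).
* `simCodonPair()` — a random sense-codon ancestor evolved along two
  branches; substitution proposals are uniform over sites and alternative
  bases (expected `t` per site per branch; default study condition
  t = 0.05, 2000 codons), stop-creating proposals rejected, nonsynonymous
  proposals accepted with probability min(1, ω). Acceptance/rejection by
  amino-acid effect was chosen over rate-matrix exponentiation: it is
  transparent, seeded, independent of the counting code it validates, and
  adequate at low divergence. It does not model transition/transversion
  bias, codon usage or rate variation — so estimator validation, not
  phylogenetic realism.
* `simGeneSet()` — sampling without replacement from a background
  universe with the planted bin's expected proportion raised by `delta`
  (study conditions: set size 1000 against a 19 478-gene universe, +15
  points for power checks, 0 for null calibration).
* `simEdgeTable()` — qualifying edges (confidence in (0.9, 1],
  experimental channel) realize a prescribed degree sequence by stub
  matching with rejection of self/parallel edges; noise edges carry
  sub-threshold confidence or non-experimental channels. The ledger's
  planted hubs and edge counts must be recovered exactly through the
  read-filter-degree path.

Every generator uses one explicitly seeded stream and restores the
caller's RNG state; identical (config, seed) gives byte-identical output.
Passing tests on these data demonstrate correctness of the computational
chain under the stated generative assumptions — they cannot certify
behavior on real curated databases, whose identifier noise, coverage gaps
and annotation biases are outside the generators' scope.

# Numerical and design choices

* Chi-square statistics use the direct $\sum (O-E)^2/E$ formula with
  `pchisq`; the BH step is `p.adjust`. Both are cross-checked in the test
  suite against independent routes (`chisq.test`, a longhand step-up).
* `ng86` precomputes per-codon site counts and pairwise pathway-averaged
  difference matrices once per session, making whole-alignment scoring a
  table lookup; the test oracle recomputes everything by direct
  enumeration.
* A difference proportion above 1 (possible in tiny samples when almost
  all differences fall in a site class with few sites) is stored as NA:
  it is saturated and not a proportion.
* Tie-breaks and orderings are deterministic everywhere (lexicographic
  members in Venn regions, degree-then-name hub ordering) so that file
  outputs are byte-stable and checksummable; `runProfile()` writes an MD5
  manifest and is idempotent.
* Problem sizes used in validation (500 oracle pairs of ≤ 50 codons, 100
  replicates per ω level, 200 null and 100 power replicates, 2000-gene
  presence matrices) were chosen to make sampling error small relative to
  the tolerances being checked while keeping the default validation run
  in the tens of seconds.

# Known limitations

* Exact reproduction of database-derived published numbers (specific
  network node/edge counts, per-gene index values) requires the archived
  snapshots of the source databases; with the package alone, those code
  paths are exercised against planted synthetic supplements instead.
* The DI combination rule is a documented convention (mean by default);
  results for genes with heterogeneous pairwise ω depend on it.
* NG86 is a counting method: no maximum-likelihood codon model, no
  transition/transversion weighting, no rate variation. For closely
  related Hominidae pairs this is standard practice, but ω estimates at
  deeper divergences would need model-based methods.
* Identifier normalization is intentionally minimal; lists using retired
  or aliased symbols will intersect as written, not as a curator would
  remap them.
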