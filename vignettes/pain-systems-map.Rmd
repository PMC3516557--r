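---
title: "Building a cross-species nociception systems map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a cross-species nociception systems map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmap)
```

## The problem

Genome-wide RNAi screening in *Drosophila* can flag hundreds of genes whose
knockdown blunts avoidance of noxious heat, but a fly hit list by itself says
little about mammalian pain biology. `painmap` implements the in-silico half
of that research program as a reusable pipeline: project the fly hits onto
mouse and human orthologs, grow the set by first-degree physical binding
partners, ask which pathways and curated gene sets are over-represented,
pool the significant sets into functional classes to form a bipartite
class–gene "systems map", and finally ask whether the map is enriched for
genes already annotated to pain (an OMIM-style disease list and a
microarray-style differential-expression list) relative to random gene
lists.

Every stage is an exported function; `run_pipeline()` chains them with one
run-level seed and a manifest, and the synthetic-data generators let the
whole pipeline run and be calibrated with no external downloads.

## The statistic

Over-representation is tested with the hypergeometric upper tail: drawing a
query of $n$ genes from a universe of $N$ of which $K$ belong to a set, the
p-value for an observed overlap $k$ is

$$P(X \ge k) \;=\; \sum_{j\ge k} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}.$$

Only over-representation is tested (one-sided); depletion is not of
interest here. Significance is declared per collection at fixed raw
alphas — 0.1 for KEGG-style pathways and GO-style terms, 0.01 for
C2-style curated sets — with no multiple-testing correction by default.
This fixed-alpha convention follows classical over-representation
reports; `enrich_collection(adjust = TRUE)` adds a Benjamini–Hochberg
column for users who want it, but the significance flag always uses the
raw p-value. GO-style results additionally pass through
`prune_go_results()`: terms larger than 500 genes are discarded
(uninformatively broad), and when several significant terms lie on one
ancestor–descendant chain of the (transitively closed) parent–child
relation, only the term with the largest query overlap is retained, ties
broken by smaller p and then name.

The background universe $N$ drives every p-value and is deliberately
explicit: the pipeline default is the union of the collection's member
genes and the species' ortholog targets, and every function takes
`background` directly.

## Orthology and counting conventions

Ortholog predictions from several pre-computed sources (Compara-,
Homologene-, Inparanoid- and OrthoMCL-style tables) are pooled by **set
union**, keeping per-mapping provenance; union maximizes recall and
naturally yields the mixed one-to-one / many-to-many topology such tables
exhibit. `map_genes()` expands many-to-many mappings but all downstream
counts are over **de-duplicated target genes**, never mapping edges —
otherwise per-category totals and percentages would be ill-defined.
Identifiers are opaque, case-sensitive strings; a gene ID attached to two
species anywhere in a merge is an integrity error.

Partner expansion happens in fly space (neighbors of hits in the binary
interaction table, minus the hits) and the expanded set is then projected;
a flag on the enrichment stage (`go_query`) lets GO-style collections be
queried with direct-hit orthologs only, since hit-only and hit-plus-partner
query modes are both legitimate analyses.

Node categories are total and follow the precedence
`pain > lethal > binding_partner`: a screen hit is always a pain node even
when it is also someone's binding partner; a developmental-lethal gene is
displayed as its own class of node but is never used as an enrichment query
seed.

## The systems map and its diagnostics

`pool_into_classes()` unions the member genes of significant sets into
functional classes. Class assignment is an explicit input table — in the
real analysis that grouping is a manual curation step, and no clustering
heuristic should silently stand in for it; the synthetic pipeline generates
a random assignment purely as plumbing. Mouse and human members collapse
onto their fly anchor gene where the ortholog table provides one (one node
per gene across species), with anchors restricted to the screen universe so
a many-to-many co-ortholog outside the screen cannot enter the map through
the back door.

Two structural diagnostics mirror the claims such a map must support:

* `class_hit_representation()` — per class, the fraction of member genes
  that are direct hits. The comparison is strict: exactly 50% does *not*
  count as majority-hit.
* `connectivity_without_partners()` — components before and after deleting
  all binding-partner nodes. "Intact" means the pruned map has no more
  components and no class lost all its members. In a bipartite class–gene
  map a class with at least one pain member provably cannot be isolated by
  partner removal; the test suite asserts this property on random maps.

## Overlap validation and the random-list null

`overlap_report()` reproduces the published-table arithmetic: per category
(pain, binding partner), counts against annotation source A (OMIM-style)
and B (microarray-style; multiple microarray sub-lists are unioned by
default), their intersection, and the union by inclusion–exclusion.
Percentages are rounded **half-up to two decimals** — the only convention
consistent with printed values such as 24.10 (40/166) and 42.31 (33/78).

`random_list_null()` draws R (default 100) gene lists, size-matched to the
category under test, uniformly without replacement from the background,
and pushes each through the *same* overlap code path. The empirical
p-value uses the standard +1 correction, $(1 + \#\{null \ge obs\})/(R+1)$.

## What the synthetic generator emulates — and what it does not

```{r generator, message = FALSE}
u <- generate_universe(universe_spec(n_fly = 1000, n_mouse = 1600,
                                     n_human = 1700, seed = 7))
screen <- generate_screen(u, n_hits = 40, n_lethal = 10, seed = 8)
head(merge_tables(u$tables), 3)
```

* **Universe and orthology.** Three namespaced gene universes; fly genes
  split into one-to-one (default 60%), many-to-many (10%, blocks of 2–3
  fully connected to blocks of 2–3), unmapped (30%) and one-to-many (the
  remainder). Every mapping is carried by at least one of four simulated
  prediction sources and independently by each other source with
  probability 0.4, so sources overlap but none is complete. The 14,000-gene
  fly default approximates a genome-wide protein-coding RNAi screen; it is
  a convention, not a measured value.
* **Interactions.** Erdős–Rényi $G(n, p)$ with $p = d/(n-1)$ for a target
  mean degree $d$; expected edge count $nd/2$. The default $d = 1$ reflects
  how sparse curated yeast-two-hybrid binary interactomes of the BIND era
  are. No hubs, no degree heterogeneity — adequate for testing expansion
  logic, not a model of real interactome topology.
* **Planted enrichment.** For a planted set of size $s$ the number of hit
  members is drawn $\mathrm{Binomial}(s, \min(1, f \cdot H/N))$ for
  enrichment factor $f$, $H$ hits in a background of $N$; hits and
  non-hits are then sampled uniformly without replacement. The expected
  hit overlap is therefore exactly $s f H/N$, which makes the generator's
  calibration checkable in closed form. At $f = 1$ the scheme reduces to
  (binomially approximated) uniform sampling.
* **Annotations.** Each source marks map genes with probability
  `annotation_hit_rate` (default 0.38) and background genes with
  `annotation_base_rate` (default 0.03), independently per source, so the
  expected union coverage of map genes is $1-(1-0.38)^2 = 61.6\%$.
* **Seeds.** One run-level seed fans out through `derive_seed()` with fixed
  per-stage offsets. Reusing one literal seed across two generators would
  make them consume the same RNG stream prefix and correlate their output
  (e.g. a screen that preferentially samples mappable genes), which is why
  the fan-out is part of the package contract.

What it does **not** emulate: real pathway topology or sizes, interactome
hubs and study bias, gene-symbol aliasing, correlated annotation sources,
or the manual curation behind functional classes. Passing the suite
therefore demonstrates that the pipeline's arithmetic, contracts and
statistical calibration are correct under a known generative process — not
that any particular biological conclusion transfers to real inputs.

## Numerical choices and degenerate inputs

* Character ordering uses radix (C-locale) sorting everywhere, so outputs
  are byte-identical across machines and locales; re-running a pipeline
  with the same config reproduces identical file checksums.
* Half-up rounding is implemented as `floor(100 * p + 0.5) / 100` on the
  percentage scale; exact halves are exactly representable here because
  the numerator is an integer multiple of a power of two over the total.
* `percent(count, 0)` is undefined and returns `NA` rather than 0 or an
  error; empty categories produce zero rows, empty queries produce
  all-`k = 0`, all-`p = 1` enrichment tables.
* The hypergeometric p-value is a lattice statistic, so under a uniform
  null the fraction of sets with $p < \alpha$ is the *achievable level*
  $\alpha^* \le \alpha$, not $\alpha$ itself — with 30–80-gene sets and a
  580-of-14,000 query, $\alpha^*$ at nominal 0.1 is roughly 0.06. The
  suite therefore checks conservatism (rate $\le \alpha$) and agreement
  with the exactly computed $\alpha^*$; expecting the nominal rate from a
  discrete test would be a false alarm by construction.
* Pruning ties (equal overlap) break by smaller p, then lexicographic
  name; the pruning log records every removal and its winner, so curation
  can be audited.

## Problem sizes used for validation

The shipped checks run the screen-scale configuration (580 hits of a
14,000-gene fly universe, gene-set sizes 30–80): 200 replicates for the
null-calibration measurement, 50 replicates for planted-effect recovery
(10 sets at factor 5, recovered at $\alpha = 0.01$), 50 × 100 random lists
for the overlap null, and an exhaustive hypergeometric sweep over all
parameter combinations with $N \le 60$. These sizes were chosen so each
measurement's Monte-Carlo error is well inside the tolerance it is checked
against.

## Known limitations

* The interaction model is a single-parameter random graph; degree-targeted
  or rewired nulls are out of scope.
* Ontology handling is ancestor–descendant pruning only — no term
  similarity, no DAG reasoning beyond the transitive closure, cycles are
  rejected rather than repaired.
* Cross-species unification assumes the ortholog table is the arbiter of
  identity; no sequence-level reconciliation is attempted.
* The pipeline treats annotation membership as given; it neither queries
  live databases nor re-analyzes expression data.
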