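# painmap

Cross-species systems mapping of nociception screen hits.

A genome-wide *Drosophila* RNAi screen for defective heat nociception
yields hundreds of candidate "pain" genes; the interesting question is
what they say about mammalian pain biology. `painmap` implements that
translation as a tested, deterministic pipeline:

1. **Ortholog projection** — pool several pre-computed orthology
   prediction tables (Compara-, Homologene-, Inparanoid-, OrthoMCL-style)
   by set union with provenance, and project the fly hit list onto mouse
   and human genes, honoring one-to-one and many-to-many mappings.
2. **Binding-partner expansion** — grow the hit set by first-degree
   physical interactors from a binary (yeast-two-hybrid-style)
   interaction table; categorize every node as `pain`, `binding_partner`
   or `lethal` with precedence `pain > lethal > binding_partner`.
3. **Enrichment** — hypergeometric upper-tail over-representation tests
   of the expanded gene set against KEGG-, C2- and GO-style collections,
   with per-collection significance levels (0.1 / 0.01 / 0.1) and
   GO-style ancestor–descendant pruning (max-overlap term wins, terms
   above 500 genes dropped). The statistic is
   P(X ≥ k) for X ~ Hypergeometric(N, K, n).
4. **Systems map** — pool significant sets into functional classes
   (explicit class-map input) and assemble the bipartite class–gene
   network, with two structural diagnostics: per-class direct-hit
   representation (strict > 50%) and connectivity after removing all
   binding partners.
5. **Overlap validation** — a per-category report of overlap with an
   OMIM-style and a microarray-style annotation list (union by
   inclusion–exclusion, percentages rounded half-up to two decimals),
   judged against a size-matched 100-random-gene-list null with an
   empirical p-value.

A synthetic-data module generates all inputs with controlled statistical
structure (mixed orthology topology, sparse random interactome, planted
gene-set enrichment, planted annotation overlap), so the entire pipeline
runs and is calibrated without downloads. See the methods vignette
(`vignettes/pain-systems-map.Rmd`) for the model, parameter and design
discussion.

## Worked example

Reconstructing a published-style overlap table from its counts — 166
direct hits of which 40 carry the OMIM-style annotation, 34 the
microarray-style annotation and 10 both; 78 binding partners with
20/23/10:

```r
library(painmap)
pain <- sprintf("P%03d", 1:166); bp <- sprintf("B%03d", 1:78)
cats <- data.frame(gene_id = c(pain, bp),
                   category = rep(c("pain", "binding_partner"), c(166, 78)))
omim  <- c(pain[1:40], bp[1:20])
array <- c(pain[c(1:10, 41:64)], bp[c(1:10, 21:33)])
overlap_report(cats, omim, array)
#> Overlap of systems-map genes with annotation sources A and B
#>         category total share_pct a_count a_pct b_count b_pct both_count
#>             pain   166     68.03      40 24.10      34 20.48         10
#>  binding_partner    78     31.97      20 25.64      23 29.49         10
#>  union_count union_pct
#>           64     38.55
#>           33     42.31
```

Reading: 64 of the 166 direct hits (38.55%) and 33 of the 78 partners
(42.31%) carry at least one known pain annotation — the
inclusion–exclusion union of the two sources.

An end-to-end synthetic run (scaled down; the defaults are screen-scale):

```r
cfg <- painmap_config(seed = 42, outdir = "readme_run",
  universe = universe_spec(n_fly = 2000, n_mouse = 2600, n_human = 2800),
  n_hits = 120, n_lethal = 25,
  effects = planted_effects(n_sets = 60, set_size_range = c(15, 40),
                            n_planted = 6),
  n_random_lists = 100, n_classes = 6)
res <- run_pipeline(cfg)
res$hit_maps$human
#> ortholog projection to human: 85/120 query genes mapped, 108 distinct targets
res$nulls$pain
#> random-list null: R=100 lists of 80 genes; overlap % min=3.75 mean=10.31 max=17.50
#> observed 70.00% -> empirical p = 0.009901
res$connectivity$intact
#> [1] TRUE
```

The 120 synthetic hits project to 108 human genes (85 have at least one
ortholog, matching the universe's 70% mappable fraction); the map's pain
genes overlap their annotations far above anything 100 size-matched
random lists achieve (empirical p ≈ 0.01, the resolution limit of R =
100); and deleting every binding-partner node leaves the map's
connectivity intact. The run directory contains every table with a
provenance header, GraphML/SIF exports of the map, `config.yaml` and a
`manifest.json` with per-stage counts and file checksums; identical
configs reproduce identical checksums.

A thin command-line wrapper ships in `inst/scripts/painmap`
(`painmap {simulate, map-orthologs, expand, enrich, build-map, validate, all}`).

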