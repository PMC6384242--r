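# immunoscreen

Predicting whether a chemical or food substance is likely to disturb —
or support — immune health is hard to do from first principles.
`immunoscreen` implements a knowledge-base screening approach for four
immune health endpoints: **hypersensitivity**, **autoimmunity**,
**resistance to infection** and **resistance to cancer**. It is aimed at
immunotoxicologists and nutrition researchers who want a desk-scale,
fully reproducible triage step before committing to assays.

The pipeline:

1. **Endpoint gene sets.** Each endpoint is anchored by MeSH disease
   roots (hypersensitivity D006967; autoimmune diseases D001327;
   parasitic D010272 + bacterial/mycoses D001423 + virus diseases
   D014777 merged as infection; neoplasms D009369). Curated disease–gene
   associations in the CTD flat-file dialect are filtered to direct
   evidence, and every gene attached to a root or any MeSH descendant
   term enters the endpoint's set *E_k*.
2. **GO cross-reference.** Biological processes matching per-endpoint
   keyword lists are selected from an OBO ontology; their annotated
   genes (GAF, with `is_a` propagation, `NOT` rows excluded) give a
   coverage diagnostic |G ∩ E_k| / |G| against the disease-derived sets.
3. **Overlap structure.** The union of the four sets is decomposed into
   the Venn partition: each gene gets a membership signature
   S(g) = {k : g ∈ E_k}, giving ≤ 2⁴ − 1 disjoint regions, and a
   bipartite gene–endpoint network exportable as GraphML, node/edge TSV
   or a graph-database statement script.
4. **Secretome refinement.** Genes whose UniProt-style annotation marks
   the product as secreted (keyword token or subcellular location) are
   plausible circulating biomarkers; composite molecules such as
   HLA-DQA2/HLA-DQA1 count through either member.
5. **Biomarker ranking.** Candidates are ordered lexicographically by
   (|S(g)| desc, secreted desc, curated interaction references desc,
   symbol asc).
6. **Chemical screening.** For a chemical, the top *n* = 10 curated
   interacting genes (interaction count, then reference count, then
   symbol) are crossed against each endpoint set; an endpoint is flagged
   when at least one top gene falls in its set, optionally with a
   hypergeometric tail probability P(X ≥ hits).

A synthetic-fixture generator (`generate_fixture()`) emulates every
input dialect with planted ground truth, so the whole pipeline is
testable end-to-end without external downloads.

## Worked example

The worked-example fixture plants the 15-molecule four-way overlap core
(ALB, HLA-DPB1, HLA-DQA2/HLA-DQA1, HLA-DRB1, ICAM1, IFNG, IL1B, IL4,
IL6, IL10, IL12B, IL18, MPO, CCL2, TNF) plus 5 unique decoys per
endpoint, with two screening profiles:

```r
library(immunoscreen)
m    <- worked_example_fixture("fixture")
cfg  <- fixture_pipeline_config(m)
res  <- run_pipeline(cfg, "out")
res$partition
#> <venn partition> 4 endpoints, 35 genes, 5 non-empty regions
#>   hypersensitivity                                                 5
#>   autoimmunity                                                     5
#>   infection                                                        5
#>   cancer                                                           5
#>   hypersensitivity+autoimmunity+infection+cancer                  15
res$reports[["Bleomycin-like"]]
#> <screening report> Bleomycin-like: 10 top genes; flagged endpoints: hypersensitivity, autoimmunity, infection, cancer
res$reports[["Bortezomib-like"]]
#> <screening report> Bortezomib-like: 10 top genes; flagged endpoints: infection
head(res$candidates, 3)
#>   rank gene n_endpoints                                      signature secreted
#> 1    1  MPO           4 hypersensitivity+autoimmunity+infection+cancer     TRUE
#> 2    2  IL4           4 hypersensitivity+autoimmunity+infection+cancer     TRUE
#> 3    3  TNF           4 hypersensitivity+autoimmunity+infection+cancer     TRUE
#>   total_interaction_refs
#> 1                      3
#> 2                      1
#> 3                      1
```

The 15-gene all-four region is the shared mechanistic core; the two
chemical profiles reproduce the qualitative screening patterns (an
all-endpoint hitter versus an infection-only hitter); the ranked table
puts four-endpoint secreted molecules on top.

`out/` contains `endpoint_sets.tsv`, `venn_regions.json`, the network
exports, the secreted-network refinement, `ranked_biomarkers.tsv`,
per-chemical screening reports (TSV/markdown/JSON) and a
`run_manifest.json` with MD5 digests of every artifact.

A thin command-line front end is installed at
`inst/cli/immunoscreen.R` (`simulate`, `run-all`, `screen`).

## Scope notes

Endpoint gene counts and GO process counts obtained from live database
snapshots (e.g. 184/564/357/3173 genes, 164/203/187/309 processes)
depend on the database versions mined at the time and are not
regenerated here; the package's guarantees are structural and are
enforced on planted fixtures instead. See the methods vignette
(`vignettes/immunoscreen-methods.Rmd`) for the model, parameter
defaults and known limitations.
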