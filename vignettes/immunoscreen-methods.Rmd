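---
title: "Methods: endpoint gene sets, overlap structure and chemical screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endpoint gene sets, overlap structure and chemical screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoscreen)
```

## The model

`immunoscreen` treats immune health as four outcome axes — hypersensitivity,
autoimmunity, resistance to infection, resistance to cancer — and asks two
questions of curated knowledge bases:

1. *Which genes are mechanistically tied to each endpoint?* An endpoint is
   defined by MeSH disease descriptor roots; a curated disease–gene
   association contributes its gene to endpoint $k$ whenever its disease
   term lies in the transitive closure of the child-of relation under any
   of $k$'s roots. Formally, with $D_k$ the expanded descriptor set and
   $A$ the association table,
   $E_k = \{\,g : (g, d) \in A,\ d \in D_k\,\}$.
2. *Where do those sets overlap, and which shared molecules could be
   monitored in plasma?* The union $U = \bigcup_k E_k$ is decomposed into
   the Venn partition: each gene's membership signature
   $S(g) = \{k : g \in E_k\}$ indexes one of $\le 2^4 - 1$ disjoint
   regions. Genes shared by all four endpoints are the core readout; the
   secretome filter then keeps genes whose product is annotated secreted,
   i.e. plausible circulating biomarkers.

Screening a chemical maps its top-$n$ curated interacting genes onto the
$E_k$ and flags every endpoint containing at least $t$ of them. The
readout is deliberately qualitative (a cross matrix), matching how such
screens are read in practice; a hypergeometric upper tail
$P(X \ge h)$ for $h$ hits out of $n$ draws against a background of $N$
genes with $m$ endpoint genes is available as an optional score.

### Assumptions

- Curated (direct-evidence) associations are trustworthy and sufficient;
  inferred associations are excluded by default rather than weighted.
- Gene identity is the symbol string. Composite molecules written as
  slash-joined pairs (e.g. HLA-DQA2/HLA-DQA1) are kept as one node and
  match through either member; this mirrors how paired loci are reported
  as a single molecule in overlap counts.
- A disease subtree stands for its endpoint: expansion is purely
  hierarchical, with no semantic filtering of descendant terms.
- Secretion annotation (keyword or subcellular location) is a proxy for
  plasma detectability.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `curated_only` | `TRUE` | keep only direct-evidence disease–gene rows |
| `propagate` | `TRUE` | GAF annotations count for all `is_a` ancestors |
| `union_go` | `FALSE` | merge GO-process genes into endpoint sets |
| `top_n` | 10 | screening panel size (top interacting genes) |
| `threshold` | 1 | hits required to flag an endpoint |
| `enrichment` | `FALSE` | add hypergeometric tail probabilities |
| `exclude_endpoints` | none | drop endpoints from the network view |

Defaults and rationale:

- **Evidence filter.** The chemical side of the screen rests on curated
  interactions, so the same curation standard is applied to the disease
  side. Therapeutic-evidence rows are kept alongside marker/mechanism
  rows under the direct filter (`evidence_labels` can restrict further):
  whether therapeutic associations should count is genuinely open, so
  the permissive choice is the default and the restriction is a flag.
- **Top-10 panel, threshold 1.** Screening reports list the ten
  highest-evidence genes per chemical and flag an endpoint on any cross;
  both match the conventional presentation of such screens. The ranking
  key — interaction count desc, then distinct supporting publications
  desc, then symbol — is a determinism choice; a reference-first key is
  exposed via `rank_by` since curated "top interactions" views can be
  ordered either way.
- **GO genes as diagnostic, not union.** On real data the disease-derived
  sets already contain most process-derived genes, so GO coverage is
  reported (`go_coverage()`) and only merged under `union_go = TRUE`.
- **Propagation uses `is_a` only** (not `part_of`/`regulates`): the
  conservative standard closure.
- **Secreted = keyword token OR location substring.** "Secreted" is not
  defined operationally by any single annotation route; the OR rule is
  the permissive, auditable choice. Genes missing from the annotation
  table are dropped from the secreted network and reported in an
  unresolved-symbol side list — silently keeping them would fabricate
  evidence.
- **Biomarker ranking** is lexicographic: endpoint coverage, secretion
  (unknown after annotated-not-secreted), summed interaction references,
  symbol. No weighted score is published for this selection, so an
  explicit, auditable total order was chosen over arbitrary weights.

## The synthetic fixture generator

`generate_fixture()` writes every dialect the pipeline reads — CTD-style
disease–gene and chemical–gene TSVs, a disease vocabulary with parent
links, a UniProt-style annotation table, OBO + GAF — with planted ground
truth recorded in a JSON manifest. What it emulates:

- the flat-file dialects (comment conventions, pipe-separated fields,
  CRLF tolerance, composite symbols written with stray whitespace);
- hierarchy expansion: genes attach to disease terms 1–3 levels below
  the endpoint roots (`mesh_depth = 3`), never only to the root;
- a configurable Venn structure (default: 12 genes per single region,
  4 per pair, 2 per triple, 15 in the four-way core — the core size
  matches the worked example, the rest are realistic desk-scale values);
- a secreted fraction (default 0.4, in the range typical of
  immune-relevant secretome annotations), inferred-only decoy rows that
  the evidence filter must remove, `NOT`-qualified GAF rows that
  propagation must ignore, and namespace/obsolete GO traps;
- chemical profiles realizing intended flag patterns inside the top-10
  panel, plus low-evidence distractor genes outside the pattern that the
  panel cut must truncate away.

Decoy symbols come from a synthetic alphabet (`SYN0001`, …) so fixture
content can never be mistaken for a biological claim.
`worked_example_fixture()` builds the worked example: each endpoint set is
exactly the 15 shared core molecules plus 5 unique decoys (set size 20),
with an all-endpoint chemical profile and an infection-only profile.
Secretion flags for the core follow their actual annotations (cytokines,
ALB and MPO secreted; ICAM1 and HLA molecules membrane-bound); the
composite is written to file as "HLA-DQA2/ HLA-DQA1" to exercise
canonicalization.

What fixtures do *not* emulate: real database scale (tens of thousands
of rows), inference scores, evidence-code heterogeneity, symbol
aliasing/withdrawn symbols, or annotation bias. Passing recovery tests
therefore demonstrates that the machinery is faithful — not that
real-snapshot gene counts would be reproduced. Published snapshot counts
(184/564/357/3173 endpoint genes; 164/203/187/309 processes) depend on
2018-era database versions and are treated as documented references, not
test expectations.

## Numerical and degenerate-input choices

- Venn signatures are canonically ordered (hypersensitivity,
  autoimmunity, infection, cancer; alphabetical for non-standard
  labels), so region keys are invariant to input-set order.
- Empty GO gene sets have coverage 1.0 (vacuous); empty gene sets filter
  to empty; a family containing an empty set has empty intersection.
- `P(X ≥ 0) = 1` exactly; bounds are validated before calling the
  distribution function.
- Ties in every ordering fall through to the gene symbol, giving
  deterministic, byte-identical outputs across reruns (verified by MD5
  in the run manifest).
- All randomness in fixture generation flows from one integer seed
  through a locally scoped RNG (Mersenne-Twister), restoring the
  caller's RNG state.

## Problem sizes used in the test suite

The suite runs entirely on generated fixtures: ~35–90 gene universes,
20 recovery seeds, 200 random set families for partition laws, a
500-genes-per-set brute-force partition check, and exhaustive
hypergeometric enumeration for populations up to 20. These sizes give
full structural coverage while keeping the default test run fast.

## Known limitations

- Symbol-keyed gene identity: no resolution of aliases or numeric IDs
  (a symbol→ID map can be applied upstream).
- Keyword-based GO process selection is a blunt instrument; an explicit
  term-ID list per endpoint is the intended override for serious use.
- No direction-of-effect (increase/decrease), dose, or mixture
  reasoning in screening; a flag means "top interacting genes touch this
  endpoint's gene set", nothing stronger.
- Inference scores on non-curated associations are ignored entirely
  rather than modeled.
- The hypergeometric background defaults to genes present in the
  interaction file, which understates the true genome background;
  enrichment values are comparative, not calibrated p-values.
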