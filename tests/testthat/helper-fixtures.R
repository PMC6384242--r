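# Shared helpers: tiny literal input files plus memoised generated fixtures.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal disease-gene file: 3 direct rows, 2 inferred rows.
tiny_disease_gene_file <- function() {
  write_lines_tmp(c(
    "# synthetic disease-gene rows",
    "# GeneSymbol\tGeneID\tDiseaseName\tDiseaseID\tDirectEvidence\tInferenceScore\tPubMedIDs",
    "Il6\t3569\tasthma\tMESH:D001249\tmarker/mechanism\t\t111|222",
    "TNF\t7124\tasthma\tMESH:D001249\ttherapeutic\t\t333",
    "hla-dqa2/ hla-dqa1\t1\tlupus\tMESH:D008180\tmarker/mechanism\t\t444",
    "CXCL8\t3576\tasthma\tMESH:D001249\t\t12.5\t555",
    "ALB\t213\tlupus\tMESH:D008180\t\t4.2\t666|777"
  ))
}

tiny_vocab_file <- function() {
  write_lines_tmp(c(
    "# DiseaseName\tDiseaseID\tParentIDs",
    "hypersensitivity\tMESH:D006967\t",
    "asthma\tMESH:D001249\tMESH:D006967",
    "autoimmune diseases\tMESH:D001327\t",
    "lupus\tMESH:D008180\tMESH:D001327"
  ))
}

chain_hierarchy <- function() {
  mesh_hierarchy(
    c("MESH:D1", "MESH:D2", "MESH:D3"),
    list(`MESH:D2` = "MESH:D1", `MESH:D3` = "MESH:D2")
  )
}

# Random forest hierarchy: each node's parent is an earlier node or none.
random_hierarchy <- function(n = 50, p_root = 0.2) {
  ids <- sprintf("MESH:D%07d", seq_len(n))
  parents <- list()
  for (i in seq(2L, n)) {
    if (stats::runif(1) > p_root) {
      parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], 1)
    }
  }
  mesh_hierarchy(ids, parents)
}

# Brute-force one-step expansion to fixpoint; the oracle for
# expand_mesh_descendants.
expand_fixpoint_oracle <- function(hierarchy, roots) {
  out <- roots
  repeat {
    step <- out
    for (child in names(hierarchy$parents)) {
      if (any(hierarchy$parents[[child]] %in% out)) step <- union(step, child)
    }
    if (setequal(step, out)) {
      return(sort(unique(out)))
    }
    out <- step
  }
}

# Memoised generated fixtures (one build per R session).
.fixture_cache <- new.env(parent = emptyenv())

cached_core_fixture <- function() {
  if (is.null(.fixture_cache$core)) {
    .fixture_cache$core <- worked_example_fixture(
      file.path(tempdir(), "immunoscreen-core-fixture")
    )
  }
  .fixture_cache$core
}

cached_random_fixture <- function(seed = 7L) {
  key <- paste0("rand", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_fixture(
      fixture_config(seed = seed),
      file.path(tempdir(), paste0("immunoscreen-rand-fixture-", seed))
    )
  }
  .fixture_cache[[key]]
}

# Rebuild endpoint sets from a fixture's files with default options.
recover_sets <- function(manifest) {
  records <- parse_disease_gene_file(manifest$files$disease_genes)
  hierarchy <- parse_disease_vocab(manifest$files$disease_vocab)
  lapply(default_endpoints(), function(e) {
    collect_endpoint_genes(records, e, hierarchy)
  })
}

random_symbol_sets <- function(k = 4, n_each = 50, alphabet = 100) {
  pool <- sprintf("G%03d", seq_len(alphabet))
  n_each <- min(n_each, alphabet)
  sets <- lapply(seq_len(k), function(i) sample(pool, n_each))
  names(sets) <- if (k == 4) {
    c("hypersensitivity", "autoimmunity", "infection", "cancer")
  } else {
    paste0("set", seq_len(k))
  }
  sets
}
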