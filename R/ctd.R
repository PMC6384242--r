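#' Parse a CTD-dialect disease-gene association file
#'
#' Reads the tab-separated flat-file dialect used by curated
#' toxicogenomics databases for gene-disease associations: `#`-prefixed
#' comment/header lines, columns GeneSymbol, GeneID, DiseaseName,
#' DiseaseID (with `MESH:` prefix), DirectEvidence, InferenceScore,
#' PubMedIDs. A row is classed `direct` (curated) when its DirectEvidence
#' label (e.g. "marker/mechanism", "therapeutic") is non-empty, else
#' `inferred`.
#'
#' @param path Path to the TSV file.
#' @param curated_only Keep only rows with direct (curated) evidence.
#'   Default `TRUE`: the screening pipeline is built on curated data.
#' @param evidence_labels Optional character vector restricting direct rows
#'   to specific labels (e.g. `"marker/mechanism"` to drop therapeutic
#'   rows). A row is kept if any of its slash-insensitive labels matches.
#' @return A data frame with columns `gene_symbol` (canonicalized),
#'   `disease_id`, `evidence_class`, `direct_evidence_label`,
#'   `reference_count`.
#' @export
parse_disease_gene_file <- function(path, curated_only = TRUE,
                                    evidence_labels = NULL) {
  cols <- c(
    "GeneSymbol", "GeneID", "DiseaseName", "DiseaseID",
    "DirectEvidence", "InferenceScore", "PubMedIDs"
  )
  raw <- read_flat_tsv(path, 7L, cols, what = "disease-gene file")
  if (nrow(raw) == 0L) {
    return(data.frame(
      gene_symbol = character(), disease_id = character(),
      evidence_class = character(), direct_evidence_label = character(),
      reference_count = integer(), stringsAsFactors = FALSE
    ))
  }
  label <- trimws(raw$DirectEvidence)
  rec <- data.frame(
    gene_symbol = canonicalize_gene(raw$GeneSymbol),
    disease_id = toupper(trimws(raw$DiseaseID)),
    evidence_class = ifelse(nzchar(label), "direct", "inferred"),
    direct_evidence_label = label,
    reference_count = count_pipe_tokens(raw$PubMedIDs),
    stringsAsFactors = FALSE
  )
  if (curated_only) {
    rec <- rec[rec$evidence_class == "direct", , drop = FALSE]
  }
  if (!is.null(evidence_labels)) {
    keep <- vapply(strsplit(rec$direct_evidence_label, "|", fixed = TRUE),
      function(l) any(trimws(l) %in% evidence_labels), logical(1)
    )
    rec <- rec[keep, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Read a MeSH disease hierarchy from a CTD-dialect vocabulary file
#'
#' Columns: DiseaseName, DiseaseID (`MESH:` prefixed), ParentIDs
#' (pipe-separated `MESH:` IDs). Parent links give the disease
#' polyhierarchy used for descendant expansion.
#'
#' @param path Path to the vocabulary TSV.
#' @return An object of class `mesh_hierarchy`: list with `nodes`
#'   (character vector of IDs), `parents` (named list ID -> parent IDs)
#'   and `children` (the inverted relation).
#' @export
parse_disease_vocab <- function(path) {
  raw <- read_flat_tsv(path, 3L, c("DiseaseName", "DiseaseID", "ParentIDs"),
    what = "disease vocabulary"
  )
  ids <- toupper(trimws(raw$DiseaseID))
  parents <- lapply(raw$ParentIDs, function(p) toupper(split_pipe(p)))
  names(parents) <- ids
  mesh_hierarchy(ids, parents, names = stats::setNames(raw$DiseaseName, ids))
}

#' Construct a MeSH hierarchy from nodes and parent links
#'
#' @param nodes Character vector of MeSH descriptor IDs.
#' @param parents Named list mapping a child ID to its parent ID(s); every
#'   name must appear in `nodes`. The relation must be acyclic.
#' @param names Optional named character vector of term labels.
#' @return A `mesh_hierarchy` object.
#' @export
mesh_hierarchy <- function(nodes, parents = list(), names = NULL) {
  nodes <- unique(nodes)
  if (length(parents) && !all(base::names(parents) %in% nodes)) {
    stop("parent_links refer to IDs absent from nodes", call. = FALSE)
  }
  children <- new.env(parent = emptyenv())
  for (child in base::names(parents)) {
    # parent IDs outside the vocabulary (e.g. other MeSH branches) carry
    # no expansion information and are ignored
    for (p in intersect(parents[[child]], nodes)) {
      children[[p]] <- c(children[[p]], child)
    }
  }
  h <- structure(
    list(nodes = nodes, parents = parents, children = children,
         labels = names),
    class = "mesh_hierarchy"
  )
  assert_acyclic(h)
  h
}

assert_acyclic <- function(h) {
  # Kahn-style peel on the child-of relation; leftover nodes mean a cycle.
  indeg <- stats::setNames(integer(length(h$nodes)), h$nodes)
  for (child in names(h$parents)) {
    indeg[child] <- indeg[child] +
      length(intersect(h$parents[[child]], h$nodes))
  }
  queue <- h$nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (c in h$children[[n]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(h$nodes)) {
    stop("cycle detected in MeSH parent links", call. = FALSE)
  }
  invisible(h)
}

#' Expand MeSH roots to all descendant descriptors
#'
#' Returns the transitive closure of the child-of relation starting from
#' `roots`, including the roots themselves, so that an endpoint root such
#' as "bacterial infections and mycoses" covers every descendant disease
#' term.
#'
#' @param hierarchy A [mesh_hierarchy()].
#' @param roots Character vector of MeSH IDs, all present in the hierarchy.
#' @return Character vector of MeSH IDs (sorted, unique).
#' @export
expand_mesh_descendants <- function(hierarchy, roots) {
  stopifnot(inherits(hierarchy, "mesh_hierarchy"))
  roots <- unique(toupper(roots))
  missing <- setdiff(roots, hierarchy$nodes)
  if (length(missing)) {
    stop("configuration error: MeSH root(s) not in hierarchy: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- character(0)
  queue <- roots
  while (length(queue)) {
    n <- queue[[1]]
    queue <- queue[-1]
    if (n %in% out) next
    out <- c(out, n)
    kids <- hierarchy$children[[n]]
    if (!is.null(kids)) queue <- c(queue, setdiff(kids, out))
  }
  sort(unique(out))
}

#' Collect the gene set of one endpoint from disease-gene records
#'
#' Takes the records whose disease term falls inside the expanded subtree
#' of the endpoint's MeSH roots and unions their gene symbols.
#'
#' @param records Data frame from [parse_disease_gene_file()] (the
#'   evidence filter is applied there, not here).
#' @param endpoint An [endpoint_definition()].
#' @param hierarchy A [mesh_hierarchy()].
#' @return An object of class `endpoint_gene_set`: list with `endpoint`,
#'   `genes` (sorted canonical symbols), `provenance` (named list of
#'   source tags per gene) and `disease_terms_used`.
#' @export
collect_endpoint_genes <- function(records, endpoint, hierarchy) {
  stopifnot(inherits(endpoint, "endpoint_definition"))
  terms <- expand_mesh_descendants(hierarchy, endpoint$mesh_root_ids)
  if (length(terms) == 0L) {
    stop("configuration error: empty MeSH expansion for endpoint '",
      endpoint$name, "'",
      call. = FALSE
    )
  }
  hit <- records$disease_id %in% terms
  genes <- sort(unique(records$gene_symbol[hit]))
  structure(
    list(
      endpoint = endpoint$name,
      genes = genes,
      provenance = stats::setNames(rep(list("ctd"), length(genes)), genes),
      disease_terms_used = terms
    ),
    class = "endpoint_gene_set"
  )
}

#' @export
print.endpoint_gene_set <- function(x, ...) {
  cat(sprintf(
    "<endpoint gene set> %s: %d genes over %d disease terms\n",
    x$endpoint, length(x$genes), length(x$disease_terms_used)
  ))
  invisible(x)
}

# Merge GO-derived genes into an endpoint set (used under union_go).
merge_endpoint_genes <- function(set, go_genes) {
  extra <- setdiff(go_genes, set$genes)
  for (g in set$genes) {
    if (g %in% go_genes) {
      set$provenance[[g]] <- union(set$provenance[[g]], "go")
    }
  }
  set$genes <- sort(c(set$genes, extra))
  set$provenance[extra] <- rep(list("go"), length(extra))
  set$provenance <- set$provenance[set$genes]
  set
}
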