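#' Rank candidate biomarkers
#'
#' Orders every gene in the partition universe by the screening tool's
#' implicit priorities: coverage across endpoints first (a molecule shared
#' by all four endpoints is the most informative readout), then secretion
#' status (plasma-detectable candidates before cell-bound ones, unknown
#' last), then total curated chemical-interaction references (evidence
#' volume), then symbol for a deterministic total order.
#'
#' @param partition A [venn_partition()].
#' @param secretome Optional data frame from [parse_uniprot_table()].
#' @param interactions Optional data frame from
#'   [parse_chemical_gene_file()]; reference counts are summed over all
#'   chemicals per gene.
#' @return Data frame with columns `rank`, `gene`, `n_endpoints`,
#'   `signature`, `secreted` (`TRUE`/`FALSE`/`NA`),
#'   `total_interaction_refs`; ranks are `1..N`.
#' @export
rank_candidates <- function(partition, secretome = NULL,
                            interactions = NULL) {
  stopifnot(inherits(partition, "venn_partition"))
  genes <- partition$universe
  if (length(genes) == 0L) {
    return(data.frame(
      rank = integer(), gene = character(), n_endpoints = integer(),
      signature = character(), secreted = logical(),
      total_interaction_refs = integer(), stringsAsFactors = FALSE
    ))
  }
  sig <- character(length(genes))
  names(sig) <- genes
  for (k in names(partition$regions)) {
    sig[partition$regions[[k]]] <- k
  }
  n_ep <- lengths(strsplit(sig, "+", fixed = TRUE))
  secreted <- rep(NA, length(genes))
  if (!is.null(secretome)) {
    res <- filter_secreted(genes, secretome)
    secreted[genes %in% res$secreted] <- TRUE
    secreted[genes %in% res$not_secreted] <- FALSE
  }
  refs <- integer(length(genes))
  if (!is.null(interactions) && nrow(interactions)) {
    per_gene <- tapply(interactions$reference_count,
      interactions$gene_symbol, sum
    )
    atoms <- gene_members(genes)
    refs <- vapply(atoms, function(m) {
      hit <- names(per_gene)[names(per_gene) %in% m |
        vapply(gene_members(names(per_gene)),
          function(a) any(a %in% m), logical(1)
        )]
      as.integer(sum(per_gene[hit]))
    }, integer(1))
  }
  # secreted key: TRUE (0) > FALSE (1) > unknown (2)
  sec_key <- ifelse(is.na(secreted), 2L, ifelse(secreted, 0L, 1L))
  ord <- order(-n_ep, sec_key, -refs, genes)
  data.frame(
    rank = seq_along(genes),
    gene = genes[ord],
    n_endpoints = as.integer(n_ep[ord]),
    signature = unname(sig[ord]),
    secreted = secreted[ord],
    total_interaction_refs = refs[ord],
    stringsAsFactors = FALSE
  )
}

#' Write the ranked-candidate table
#'
#' @param candidates Data frame from [rank_candidates()].
#' @param path Output TSV path.
#' @export
write_ranked_tsv <- function(candidates, path) {
  out <- candidates
  out$secreted <- ifelse(is.na(out$secreted), "unknown",
    ifelse(out$secreted, "true", "false")
  )
  write_tsv_file(out, path)
}
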