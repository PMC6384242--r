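#' Build the bipartite gene-endpoint network
#'
#' One node per endpoint (carrying its set size) and one per gene
#' (carrying its membership signature, degree, and secreted status when a
#' secretome table is supplied), with an edge for every gene-endpoint
#' membership. This is the unique-vs-shared molecule network behind the
#' overlap visualizations.
#'
#' @param partition A [venn_partition()].
#' @param secretome Optional data frame from [parse_uniprot_table()].
#' @param exclude Endpoint labels to drop from the network (the partition
#'   itself is unchanged); the overlap figures omit cancer for clarity and
#'   this reproduces that view.
#' @return An `igraph` graph with vertex attributes `kind`
#'   (`"endpoint"`/`"gene"`), `signature`, `set_size`, `secreted`
#'   (`"true"`, `"false"` or `"unknown"`).
#' @export
build_network <- function(partition, secretome = NULL, exclude = character()) {
  stopifnot(inherits(partition, "venn_partition"))
  labels <- setdiff(partition$endpoint_names, exclude)
  # per-endpoint sizes reconstructed from regions
  sizes <- stats::setNames(integer(length(labels)), labels)
  edges <- character(0)
  gene_sig <- character(0)
  for (k in names(partition$regions)) {
    parts <- strsplit(k, "+", fixed = TRUE)[[1]]
    kept <- intersect(parts, labels)
    for (e in kept) sizes[e] <- sizes[e] + length(partition$regions[[k]])
    if (length(kept) == 0L) next
    for (g in partition$regions[[k]]) {
      gene_sig[g] <- paste(kept, collapse = "+")
      edges <- c(edges, as.vector(rbind(g, kept)))
    }
  }
  genes <- sort(names(gene_sig))
  secflag <- rep("unknown", length(genes))
  if (!is.null(secretome)) {
    res <- filter_secreted(genes, secretome)
    secflag[genes %in% res$secreted] <- "true"
    secflag[genes %in% res$not_secreted] <- "false"
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(labels),
    name = labels, kind = "endpoint",
    signature = "", set_size = as.integer(sizes[labels]),
    secreted = "unknown"
  )
  if (length(genes)) {
    g <- igraph::add_vertices(g, length(genes),
      name = genes, kind = "gene",
      signature = as.character(gene_sig[genes]),
      set_size = 0L, secreted = secflag
    )
    g <- igraph::add_edges(g, match(edges, igraph::V(g)$name))
  }
  g
}

#' Export the gene-endpoint network
#'
#' Three formats: `"graphml"` (round-trippable structure + attributes),
#' `"tsv"` (a `nodes.tsv` / `edges.tsv` pair), and `"statements"` (a
#' plain-text bulk-load script with one node/edge creation statement per
#' element for a property-graph database).
#'
#' @param network Graph from [build_network()].
#' @param path Output path; for `"tsv"` a directory (created if needed),
#'   otherwise a file.
#' @param format One of `"graphml"`, `"tsv"`, `"statements"`.
#' @return Character vector of the file(s) written, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "tsv",
                                                   "statements")) {
  if (length(format) != 1L || !format %in% c("graphml", "tsv", "statements")) {
    stop("usage error: unknown export format: ",
      paste(format, collapse = "/"),
      call. = FALSE
    )
  }
  v <- data.frame(
    id = igraph::V(network)$name,
    kind = igraph::V(network)$kind,
    signature = igraph::V(network)$signature,
    set_size = igraph::V(network)$set_size,
    secreted = igraph::V(network)$secreted,
    stringsAsFactors = FALSE
  )
  el <- igraph::as_edgelist(network)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nodes_path <- file.path(path, "nodes.tsv")
    edges_path <- file.path(path, "edges.tsv")
    write_tsv_file(v, nodes_path)
    write_tsv_file(
      data.frame(source = el[, 1], target = el[, 2],
        stringsAsFactors = FALSE
      ),
      edges_path
    )
    return(invisible(c(nodes_path, edges_path)))
  }
  # statements: one CREATE per node, one per membership edge
  esc <- function(x) gsub("'", "\\\\'", x)
  node_stmt <- sprintf(
    "CREATE (:%s {id: '%s', signature: '%s', set_size: %d, secreted: '%s'});",
    ifelse(v$kind == "endpoint", "Endpoint", "Gene"),
    esc(v$id), esc(v$signature), v$set_size, v$secreted
  )
  edge_stmt <- if (nrow(el)) {
    sprintf(
      paste0(
        "MATCH (g:Gene {id: '%s'}), (e:Endpoint {id: '%s'}) ",
        "CREATE (g)-[:INVOLVED_IN]->(e);"
      ),
      esc(el[, 1]), esc(el[, 2])
    )
  } else {
    character(0)
  }
  writeLines(c(node_stmt, edge_stmt), path)
  invisible(path)
}
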