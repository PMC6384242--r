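#' Parse a CTD-dialect chemical-gene interaction file
#'
#' TSV dialect: `#`-prefixed comments, columns ChemicalName, ChemicalID,
#' GeneSymbol, InteractionActions, InteractionCount, PubMedIDs. Rows are
#' aggregated per (chemical, gene): interaction counts are summed and the
#' reference count is the number of distinct PubMed ids across rows, so
#' screening does not depend on how curation split the records.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `chemical_id`, `chemical_name`,
#'   `gene_symbol` (canonical), `interaction_count`, `reference_count`,
#'   sorted by chemical then gene.
#' @export
parse_chemical_gene_file <- function(path) {
  cols <- c(
    "ChemicalName", "ChemicalID", "GeneSymbol", "InteractionActions",
    "InteractionCount", "PubMedIDs"
  )
  raw <- read_flat_tsv(path, 6L, cols, what = "chemical-gene file")
  if (nrow(raw) == 0L) {
    return(data.frame(
      chemical_id = character(), chemical_name = character(),
      gene_symbol = character(), interaction_count = integer(),
      reference_count = integer(), stringsAsFactors = FALSE
    ))
  }
  n <- suppressWarnings(as.integer(raw$InteractionCount))
  if (anyNA(n) || any(n < 1L)) {
    bad <- which(is.na(n) | n < 1L)[1]
    stop(sprintf(
      "parse error: bad InteractionCount %s in %s (data row %d)",
      raw$InteractionCount[bad], path, bad
    ), call. = FALSE)
  }
  key <- paste(raw$ChemicalID, canonicalize_gene(raw$GeneSymbol), sep = "\r")
  groups <- split(seq_len(nrow(raw)), key)
  agg <- lapply(groups, function(i) {
    refs <- unique(unlist(lapply(raw$PubMedIDs[i], split_pipe)))
    data.frame(
      chemical_id = raw$ChemicalID[i[1]],
      chemical_name = raw$ChemicalName[i[1]],
      gene_symbol = canonicalize_gene(raw$GeneSymbol[i[1]]),
      interaction_count = sum(n[i]),
      reference_count = length(refs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$chemical_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Resolve a chemical by id or (case-insensitive) name; error lists
# near-matches to help against typos.
resolve_chemical <- function(interactions, chemical) {
  hit <- interactions$chemical_id == chemical |
    tolower(interactions$chemical_name) == tolower(chemical)
  if (!any(hit)) {
    pool <- unique(c(interactions$chemical_name, interactions$chemical_id))
    near <- pool[utils::adist(tolower(chemical), tolower(pool)) <= 3]
    stop(
      "lookup error: chemical '", chemical, "' not found",
      if (length(near)) paste0("; did you mean: ",
        paste(near, collapse = ", "), "?"
      ) else "",
      call. = FALSE
    )
  }
  interactions[hit, , drop = FALSE]
}

#' Top curated interacting genes of a chemical
#'
#' Genes ranked by curated evidence volume. The default key is
#' interaction count (descending), then reference count (descending),
#' then symbol (ascending) for a deterministic total order; `rank_by =
#' "reference"` swaps the first two keys.
#'
#' @param interactions Data frame from [parse_chemical_gene_file()].
#' @param chemical Chemical id or name.
#' @param n Number of genes to return (default 10, the standard screening
#'   panel size); fewer are returned when fewer distinct genes exist.
#' @param rank_by `"interaction"` (default) or `"reference"`.
#' @return Data frame of the top rows (gene_symbol, interaction_count,
#'   reference_count) in rank order.
#' @export
top_interacting_genes <- function(interactions, chemical, n = 10,
                                  rank_by = c("interaction", "reference")) {
  rank_by <- match.arg(rank_by)
  stopifnot(n >= 1)
  rows <- resolve_chemical(interactions, chemical)
  ord <- if (rank_by == "interaction") {
    order(-rows$interaction_count, -rows$reference_count, rows$gene_symbol)
  } else {
    order(-rows$reference_count, -rows$interaction_count, rows$gene_symbol)
  }
  rows <- rows[ord, , drop = FALSE]
  rows <- rows[seq_len(min(n, nrow(rows))), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Hypergeometric upper tail for endpoint hit enrichment
#'
#' Probability of observing at least `hits` endpoint genes when drawing
#' `n` genes from a background of `background_size` genes of which
#' `endpoint_set_size` belong to the endpoint: P(X >= hits).
#'
#' @param hits,n,endpoint_set_size,background_size Integers with
#'   `0 <= hits <= n <= background_size` and
#'   `endpoint_set_size <= background_size`.
#' @return Tail probability in (0, 1].
#' @export
enrichment_tail <- function(hits, n, endpoint_set_size, background_size) {
  if (hits < 0 || n < hits || background_size < n ||
    endpoint_set_size < 0 || endpoint_set_size > background_size) {
    stop("usage error: hypergeometric bounds violated", call. = FALSE)
  }
  if (hits == 0) {
    return(1.0)
  }
  stats::phyper(hits - 1, endpoint_set_size,
    background_size - endpoint_set_size, n,
    lower.tail = FALSE
  )
}

#' Screen a chemical against the endpoint gene sets
#'
#' Extracts the chemical's top curated interacting genes and crosses them
#' against each endpoint gene set (composites match through either
#' member). An endpoint is flagged when at least `threshold` of the top
#' genes fall in its set — the qualitative readout of the screening tool.
#'
#' @param interactions Data frame from [parse_chemical_gene_file()].
#' @param chemical Chemical id or name.
#' @param endpoint_sets Named list label -> `endpoint_gene_set` (or plain
#'   character vector of symbols).
#' @param n Top-gene panel size (default 10).
#' @param threshold Minimum hits to flag an endpoint (default 1: any
#'   cross flags).
#' @param enrichment Also compute hypergeometric tail probabilities per
#'   endpoint (off by default; the primary readout is the cross matrix).
#' @param background_size Background gene count for enrichment; defaults
#'   to the number of distinct genes in `interactions`.
#' @param rank_by Ranking key, see [top_interacting_genes()].
#' @return An object of class `screening_report`: list with `chemical`,
#'   `chemical_id`, `top_genes` (data frame), `membership` (logical gene
#'   x endpoint matrix), `hit_counts`, `flagged`, and optional
#'   `enrichment`.
#' @export
screen_chemical <- function(interactions, chemical, endpoint_sets,
                            n = 10, threshold = 1, enrichment = FALSE,
                            background_size = NULL,
                            rank_by = c("interaction", "reference")) {
  rank_by <- match.arg(rank_by)
  sets <- lapply(endpoint_sets, function(s) {
    if (inherits(s, "endpoint_gene_set")) s$genes else s
  })
  top <- top_interacting_genes(interactions, chemical, n, rank_by)
  genes <- top$gene_symbol
  membership <- vapply(sets, function(s) genes_in_set(genes, s),
    logical(length(genes))
  )
  membership <- matrix(membership,
    nrow = length(genes),
    dimnames = list(genes, names(sets))
  )
  hit_counts <- colSums(membership)
  flagged <- hit_counts >= threshold
  enr <- NULL
  if (enrichment) {
    if (is.null(background_size)) {
      background_size <- length(unique(interactions$gene_symbol))
    }
    enr <- vapply(names(sets), function(e) {
      m <- min(length(unique(sets[[e]])), background_size)
      enrichment_tail(hit_counts[[e]], nrow(top), m, background_size)
    }, numeric(1))
  }
  structure(
    list(
      chemical = top$chemical_name[1],
      chemical_id = top$chemical_id[1],
      top_genes = top[, c("gene_symbol", "interaction_count",
        "reference_count"), drop = FALSE],
      membership = membership,
      hit_counts = hit_counts,
      threshold = threshold,
      flagged = flagged,
      enrichment = enr
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  flags <- names(x$flagged)[x$flagged]
  cat(sprintf(
    "<screening report> %s: %d top genes; flagged endpoints: %s\n",
    x$chemical, nrow(x$top_genes),
    if (length(flags)) paste(flags, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Write a screening report to file
#'
#' `tsv` and `json` render booleans; `markdown` renders the cross matrix
#' with the conventional `x` marks, one row per top gene.
#'
#' @param report A [screen_chemical()] result.
#' @param path Output file.
#' @param format One of `"tsv"`, `"markdown"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "markdown", "json")) {
  if (length(format) != 1L || !format %in% c("tsv", "markdown", "json")) {
    stop("usage error: unknown report format: ",
      paste(format, collapse = "/"),
      call. = FALSE
    )
  }
  stopifnot(inherits(report, "screening_report"))
  eps <- colnames(report$membership)
  if (format == "json") {
    x <- list(
      chemical = report$chemical,
      chemical_id = report$chemical_id,
      threshold = report$threshold,
      top_genes = report$top_genes,
      membership = as.data.frame(report$membership),
      hit_counts = as.list(report$hit_counts),
      flagged = as.list(report$flagged)
    )
    if (!is.null(report$enrichment)) {
      x$enrichment <- as.list(report$enrichment)
    }
    return(write_json_file(x, path))
  }
  genes <- rownames(report$membership)
  if (format == "tsv") {
    df <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (e in eps) df[[e]] <- report$membership[, e]
    df <- rbind(
      df,
      c("hit_count", as.list(unname(report$hit_counts))),
      c("flagged", as.list(unname(report$flagged)))
    )
    return(write_tsv_file(df, path))
  }
  # markdown
  hdr <- paste0("| gene | ", paste(eps, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---|", length(eps) + 1L), collapse = ""))
  body <- vapply(seq_along(genes), function(i) {
    marks <- ifelse(report$membership[i, ], "×", "")
    paste0("| ", genes[i], " | ", paste(marks, collapse = " | "), " |")
  }, character(1))
  hits <- paste0(
    "| **hits** | ",
    paste(report$hit_counts, collapse = " | "), " |"
  )
  flg <- paste0(
    "| **flagged** | ",
    paste(ifelse(report$flagged, "yes", "no"), collapse = " | "), " |"
  )
  writeLines(
    c(paste0("### ", report$chemical), "", hdr, sep, body, hits, flg),
    path
  )
  invisible(path)
}
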