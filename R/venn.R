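#' Venn partition of endpoint gene sets
#'
#' Decomposes the union of k gene sets (2 <= k <= 8) into disjoint
#' regions keyed by membership signature: the exact subset of endpoints
#' containing each gene. Signatures are canonically ordered (the fixed
#' global endpoint order when the labels are the four standard endpoints,
#' alphabetical otherwise) so region keys do not depend on input order.
#'
#' @param sets Named list mapping endpoint label to a character vector of
#'   canonical gene symbols.
#' @return An object of class `venn_partition`: list with
#'   `endpoint_names` (canonical order), `regions` (named list, signature
#'   key `"a+b"` -> sorted gene vector; only non-empty regions are kept)
#'   and `universe` (sorted union).
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list", call. = FALSE)
  }
  if (length(sets) < 2L || length(sets) > 8L) {
    stop("usage error: venn_partition needs between 2 and 8 sets",
      call. = FALSE
    )
  }
  labels <- canonical_endpoint_order(names(sets))
  sets <- lapply(sets[labels], unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0L) {
    return(structure(
      list(endpoint_names = labels, regions = list(), universe = character()),
      class = "venn_partition"
    ))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
    dimnames = list(universe, labels)
  )
  sig <- apply(member, 1L, function(row) {
    paste(labels[row], collapse = "+")
  })
  regions <- split(universe, sig)
  regions <- lapply(regions, sort)
  # deterministic region order: by signature length, then canonical position
  key_rank <- function(k) {
    parts <- strsplit(k, "+", fixed = TRUE)[[1]]
    c(length(parts), match(parts, labels), rep(0L, 8 - length(parts)))
  }
  ord <- order(vapply(
    names(regions),
    function(k) paste(sprintf("%02d", key_rank(k)), collapse = ""),
    character(1)
  ))
  structure(
    list(
      endpoint_names = labels,
      regions = regions[ord],
      universe = universe
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf(
    "<venn partition> %d endpoints, %d genes, %d non-empty regions\n",
    length(x$endpoint_names), length(x$universe), length(x$regions)
  ))
  for (k in names(x$regions)) {
    cat(sprintf("  %-60s %5d\n", k, length(x$regions[[k]])))
  }
  invisible(x)
}

#' Genes shared by every set
#'
#' @param sets Named list as in [venn_partition()].
#' @return Sorted character vector: the intersection of all sets.
#' @export
intersect_all <- function(sets) {
  if (length(sets) < 2L || length(sets) > 8L) {
    stop("usage error: intersect_all needs between 2 and 8 sets",
      call. = FALSE
    )
  }
  sort(Reduce(intersect, lapply(sets, unique)))
}

#' Region sizes of a Venn partition
#'
#' @param partition A [venn_partition()].
#' @return Named integer vector signature -> count.
#' @export
region_sizes <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  vapply(partition$regions, length, integer(1))
}

# Membership signature of one gene, or NA if absent from the universe.
gene_signature <- function(partition, gene) {
  for (k in names(partition$regions)) {
    if (gene %in% partition$regions[[k]]) {
      return(k)
    }
  }
  NA_character_
}

#' Write a Venn region-size and contents summary as JSON
#'
#' @param partition A [venn_partition()].
#' @param path Output path.
#' @param contents Include the sorted gene lists per region.
#' @export
write_venn_json <- function(partition, path, contents = TRUE) {
  stopifnot(inherits(partition, "venn_partition"))
  x <- list(
    endpoints = partition$endpoint_names,
    n_genes = length(partition$universe),
    region_sizes = as.list(region_sizes(partition))
  )
  if (contents) {
    x$regions <- partition$regions
  }
  write_json_file(x, path)
}
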