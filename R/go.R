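#' Parse a GO ontology in OBO 1.2 format
#'
#' Reads `[Term]` stanzas, capturing id, name, namespace, `is_a` parents
#' and the obsolete flag. Only the fields needed for process selection and
#' annotation propagation are kept.
#'
#' @param path Path to the OBO file.
#' @return An object of class `go_ontology`: list with `terms` (data frame
#'   id/name/namespace/obsolete) and `parents` (named list id -> is_a
#'   parent ids).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) {
    stop("input error: OBO file not found: ", path, call. = FALSE)
  }
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  starts <- which(lines == "[Term]")
  n <- length(starts)
  ids <- names <- namespaces <- character(n)
  obsolete <- logical(n)
  parents <- vector("list", n)
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_len(n)) {
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    # stanza ends at the next stanza header of any type
    stanza_end <- grep("^\\[", block)
    if (length(stanza_end)) block <- block[seq_len(stanza_end[1] - 1L)]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(hit) == 0L) {
        return(NA_character_)
      }
      trimws(sub(paste0("^", key, ":"), "", hit[1]))
    }
    id <- get1("id")
    if (is.na(id) || !grepl("^GO:[0-9]{7}$", id)) {
      stop(sprintf(
        "parse error: malformed [Term] stanza at line %d of %s",
        starts[i], path
      ), call. = FALSE)
    }
    ids[i] <- id
    names[i] <- get1("name")
    ns <- get1("namespace")
    namespaces[i] <- if (is.na(ns)) "biological_process" else ns
    obsolete[i] <- identical(get1("is_obsolete"), "true")
    isa <- grep("^is_a:", block, value = TRUE)
    parents[[i]] <- trimws(sub("!.*$", "", sub("^is_a:", "", isa)))
  }
  names(parents) <- ids
  structure(
    list(
      terms = data.frame(
        id = ids, name = names, namespace = namespaces,
        obsolete = obsolete, stringsAsFactors = FALSE
      ),
      parents = parents
    ),
    class = "go_ontology"
  )
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf(
    "<GO ontology> %d terms (%d obsolete)\n",
    nrow(x$terms), sum(x$terms$obsolete)
  ))
  invisible(x)
}

#' Parse a GO annotation (GAF 2.x) file
#'
#' `!`-prefixed comment lines are skipped; column 3 is the gene symbol,
#' column 4 the qualifier (may carry `NOT`), column 5 the GO id, column 7
#' the evidence code.
#'
#' @param path Path to the GAF file.
#' @return Data frame with columns `gene_symbol`, `qualifier`, `go_id`,
#'   `evidence_code`.
#' @export
parse_gaf <- function(path) {
  if (!file.exists(path)) {
    stop("input error: GAF file not found: ", path, call. = FALSE)
  }
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !startsWith(lines, "!") & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(
      gene_symbol = character(), qualifier = character(),
      go_id = character(), evidence_code = character(),
      stringsAsFactors = FALSE
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 15L)
  if (length(short)) {
    stop(sprintf(
      "parse error: GAF row %d has %d columns, expected >= 15",
      which(keep)[short[1]], lengths(parts)[short[1]]
    ), call. = FALSE)
  }
  df <- data.frame(
    gene_symbol = canonicalize_gene(vapply(parts, `[[`, "", 3L)),
    qualifier = vapply(parts, `[[`, "", 4L),
    go_id = vapply(parts, `[[`, "", 5L),
    evidence_code = vapply(parts, `[[`, "", 7L),
    stringsAsFactors = FALSE
  )
  bad <- !grepl("^GO:[0-9]{7}$", df$go_id)
  if (any(bad)) {
    stop("parse error: malformed GO id in GAF: ", df$go_id[which(bad)[1]],
      call. = FALSE
    )
  }
  df
}

#' Select biological processes matching endpoint keywords
#'
#' Non-obsolete `biological_process` terms whose name contains any of the
#' keywords (case-insensitive substring match).
#'
#' @param ontology A [parse_obo()] result.
#' @param keywords Non-empty character vector of match strings.
#' @return Character vector of GO ids (sorted).
#' @export
select_processes <- function(ontology, keywords) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (length(keywords) == 0L) {
    stop("configuration error: empty GO keyword list", call. = FALSE)
  }
  t <- ontology$terms
  eligible <- t$namespace == "biological_process" & !t$obsolete
  nm <- tolower(t$name)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k) {
    grepl(k, nm, fixed = TRUE)
  }))
  sort(t$id[eligible & hit])
}

# is_a ancestor closure of one term (including itself), iterative.
go_ancestors <- function(ontology, id) {
  out <- character(0)
  queue <- id
  while (length(queue)) {
    x <- queue[[1]]
    queue <- queue[-1]
    if (x %in% out) next
    out <- c(out, x)
    queue <- c(queue, setdiff(ontology$parents[[x]], out))
  }
  out
}

#' Genes annotated to a set of GO processes
#'
#' With `propagate = TRUE` (the default) an annotation to a term also
#' counts for every `is_a` ancestor of that term, so querying a parent
#' process retrieves genes annotated to its children. Rows whose qualifier
#' contains `NOT` never contribute.
#'
#' @param annotations Data frame from [parse_gaf()].
#' @param ontology A [parse_obo()] result.
#' @param process_ids GO ids to query; all must exist in the ontology.
#' @param propagate Propagate annotations up `is_a` edges.
#' @return Sorted character vector of canonical gene symbols.
#' @export
genes_for_processes <- function(annotations, ontology, process_ids,
                                propagate = TRUE) {
  stopifnot(inherits(ontology, "go_ontology"))
  unknown <- setdiff(process_ids, ontology$terms$id)
  if (length(unknown)) {
    stop("configuration error: unknown GO id(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  ann <- annotations[!grepl("\\bNOT\\b", annotations$qualifier), ,
    drop = FALSE
  ]
  ann <- ann[ann$go_id %in% ontology$terms$id, , drop = FALSE]
  if (propagate) {
    terms <- unique(ann$go_id)
    closure <- lapply(terms, function(t) go_ancestors(ontology, t))
    names(closure) <- terms
    hit <- vapply(ann$go_id, function(t) {
      any(closure[[t]] %in% process_ids)
    }, logical(1))
  } else {
    hit <- ann$go_id %in% process_ids
  }
  sort(unique(ann$gene_symbol[hit]))
}

#' Coverage of a GO-derived gene set by the CTD-derived set
#'
#' Fraction of GO-process genes already present in the disease-association
#' set: `|go ∩ ctd| / |go|`, with empty GO sets covered vacuously (1.0).
#'
#' @param go_genes,ctd_genes Character vectors of canonical symbols.
#' @return Scalar in \[0, 1\].
#' @export
coverage_vs_ctd <- function(go_genes, ctd_genes) {
  go_genes <- unique(go_genes)
  if (length(go_genes) == 0L) {
    return(1.0)
  }
  sum(go_genes %in% ctd_genes) / length(go_genes)
}
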