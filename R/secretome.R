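#' Parse a UniProt-dialect secretome annotation table
#'
#' TSV with a header row and columns `GeneSymbol`, `Keywords`
#' (semicolon-separated) and `SubcellularLocation` (free text). A protein
#' is called secreted when its keywords contain the exact token
#' `Secreted`, or its subcellular location mentions "secreted"
#' (case-insensitive) — the union rule, since either annotation route
#' marks a plausible circulating protein.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `gene_symbol` (canonical), `secreted`
#'   (logical) and `evidence` (the annotation string that triggered the
#'   call, empty when not secreted).
#' @export
parse_uniprot_table <- function(path) {
  if (!file.exists(path)) {
    stop("input error: annotation table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    sep = "\t", header = TRUE, quote = "",
    comment.char = "#", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  need <- c("GeneSymbol", "Keywords", "SubcellularLocation")
  if (!all(need %in% names(df))) {
    stop("parse error: annotation table lacks column(s): ",
      paste(setdiff(need, names(df)), collapse = ", "),
      call. = FALSE
    )
  }
  kw_hit <- vapply(strsplit(df$Keywords, ";", fixed = TRUE), function(k) {
    "Secreted" %in% trimws(k)
  }, logical(1))
  loc_hit <- grepl("secreted", df$SubcellularLocation, ignore.case = TRUE)
  evidence <- ifelse(kw_hit, "keyword:Secreted",
    ifelse(loc_hit, paste0("location:", df$SubcellularLocation), "")
  )
  data.frame(
    gene_symbol = canonicalize_gene(df$GeneSymbol),
    secreted = kw_hit | loc_hit,
    evidence = evidence,
    stringsAsFactors = FALSE
  )
}

#' Filter a gene set to secreted candidates
#'
#' Keeps the genes whose product is annotated as secreted; a composite
#' molecule is kept if any of its members is secreted. Genes absent from
#' the annotation table are dropped and reported separately rather than
#' silently retained, since the secretome refinement is evidence-based.
#'
#' @param genes Character vector of canonical symbols.
#' @param annotations Data frame from [parse_uniprot_table()].
#' @return List with `secreted` (subset of `genes`), `not_secreted`
#'   (annotated but not secreted) and `unresolved` (no annotation); the
#'   three parts partition `genes`.
#' @export
filter_secreted <- function(genes, annotations) {
  genes <- unique(genes)
  sec_symbols <- annotations$gene_symbol[annotations$secreted]
  ann_symbols <- annotations$gene_symbol
  ann_atoms <- unique(unlist(gene_members(ann_symbols), use.names = FALSE))
  members <- gene_members(genes)
  annotated <- vapply(members, function(m) any(m %in% ann_atoms), logical(1))
  secreted <- genes_in_set(genes, sec_symbols)
  list(
    secreted = genes[secreted],
    not_secreted = genes[annotated & !secreted],
    unresolved = genes[!annotated]
  )
}

#' Write the unresolved-symbol side list
#'
#' @param unresolved Character vector of symbols with no annotation.
#' @param path Output path (one-column TSV).
#' @export
write_unresolved <- function(unresolved, path) {
  write_tsv_file(
    data.frame(GeneSymbol = sort(unresolved), stringsAsFactors = FALSE),
    path
  )
}
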