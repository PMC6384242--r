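#' Canonicalize a gene symbol
#'
#' Gene identity throughout the package is by canonical symbol string.
#' Symbols are uppercased and trimmed; composite molecules written as
#' slash-joined pairs (e.g. the HLA-DQA2/HLA-DQA1 dimer partner pair that
#' overlap analyses treat as one molecule) keep the slash but lose any
#' whitespace around it, so `"HLA-DQA2/ HLA-DQA1"` and
#' `"hla-dqa2 / hla-dqa1"` canonicalize identically.
#'
#' @param symbol Character vector of raw gene symbols.
#' @return Character vector of canonical symbols, same length as `symbol`.
#' @examples
#' canonicalize_gene("il6")
#' canonicalize_gene("HLA-DQA2/ HLA-DQA1")
#' @export
canonicalize_gene <- function(symbol) {
  if (!is.character(symbol)) {
    stop("gene symbols must be character", call. = FALSE)
  }
  s <- toupper(trimws(symbol))
  s <- gsub("[[:space:]]*/[[:space:]]*", "/", s)
  if (any(is.na(s)) || any(!nzchar(gsub("/", "", s)))) {
    stop("empty or whitespace-only gene symbol", call. = FALSE)
  }
  s
}

#' Atomic members of (possibly composite) gene symbols
#'
#' @param symbol Character vector of canonical symbols.
#' @return A list, one character vector of atomic symbols per input.
#' @export
gene_members <- function(symbol) {
  strsplit(symbol, "/", fixed = TRUE)
}

# Member-aware membership: a gene matches a set if its symbol is in the set
# or any atomic member matches any atomic member of a set element. Vectorised
# over `symbols`.
genes_in_set <- function(symbols, set) {
  if (length(set) == 0L) {
    return(rep(FALSE, length(symbols)))
  }
  direct <- symbols %in% set
  if (all(direct)) {
    return(direct)
  }
  set_atoms <- unique(unlist(gene_members(set), use.names = FALSE))
  atoms <- gene_members(symbols)
  direct | vapply(atoms, function(a) any(a %in% set_atoms), logical(1))
}
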