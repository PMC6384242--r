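#' Define an immune health endpoint
#'
#' An endpoint is anchored by one or more MeSH disease descriptor roots
#' (each root stands for its whole disease subtree) plus a list of GO
#' biological-process keywords used by the GO coverage stage.
#'
#' @param name Endpoint label, e.g. `"hypersensitivity"`.
#' @param mesh_root_ids Character vector of MeSH descriptor IDs in
#'   `"MESH:D......."` form (the `MESH:` prefix is added if missing).
#' @param go_keywords Character vector of case-insensitive substrings used
#'   to select GO biological processes for this endpoint.
#' @return An object of class `endpoint_definition`.
#' @export
endpoint_definition <- function(name, mesh_root_ids, go_keywords = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(mesh_root_ids) == 0L) {
    stop("endpoint '", name, "' needs at least one MeSH root ID", call. = FALSE)
  }
  ids <- toupper(trimws(mesh_root_ids))
  ids <- ifelse(startsWith(ids, "MESH:"), ids, paste0("MESH:", ids))
  ok <- grepl("^MESH:D[0-9]+$", ids)
  if (!all(ok)) {
    stop("malformed MeSH ID(s) for endpoint '", name, "': ",
      paste(mesh_root_ids[!ok], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(name = name, mesh_root_ids = ids, go_keywords = go_keywords),
    class = "endpoint_definition"
  )
}

#' Default immune health endpoint definitions
#'
#' The four endpoints with their MeSH disease roots: hypersensitivity
#' (D006967), autoimmunity (autoimmune diseases, D001327), resistance to
#' infection (parasitic diseases D010272, bacterial infections and mycoses
#' D001423, virus diseases D014777, merged into one endpoint), and
#' resistance to cancer (neoplasms, D009369).
#'
#' @return Named list of [endpoint_definition()] objects in canonical order.
#' @export
default_endpoints <- function() {
  defs <- list(
    endpoint_definition(
      "hypersensitivity", "MESH:D006967",
      c("hypersensitivity", "allerg", "mast cell", "immunoglobulin e")
    ),
    endpoint_definition(
      "autoimmunity", "MESH:D001327",
      c("autoimmun", "tolerance induction", "self antigen")
    ),
    endpoint_definition(
      # D010272 parasitic, D001423 bacterial/mycoses, D014777 viral
      "infection", c("MESH:D010272", "MESH:D001423", "MESH:D014777"),
      c("defense response", "response to bacterium", "response to virus",
        "antimicrobial")
    ),
    endpoint_definition(
      "cancer", "MESH:D009369",
      c("tumor", "apoptotic", "cell cycle", "neoplas")
    )
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

# Canonical global ordering of endpoint labels used for Venn signatures.
ENDPOINT_ORDER <- c("hypersensitivity", "autoimmunity", "infection", "cancer")

canonical_endpoint_order <- function(labels) {
  if (all(labels %in% ENDPOINT_ORDER)) {
    ENDPOINT_ORDER[ENDPOINT_ORDER %in% labels]
  } else {
    sort(labels)
  }
}

#' @export
print.endpoint_definition <- function(x, ...) {
  cat("<endpoint>", x$name, "\n  MeSH roots:",
    paste(x$mesh_root_ids, collapse = ", "), "\n"
  )
  if (length(x$go_keywords)) {
    cat("  GO keywords:", paste(x$go_keywords, collapse = ", "), "\n")
  }
  invisible(x)
}
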