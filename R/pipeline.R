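#' Load a pipeline configuration
#'
#' The configuration is a single YAML file with an `inputs` block (paths
#' to the disease-gene, disease-vocabulary, chemical-gene, secretome
#' annotation, OBO and GAF files), an optional `endpoints` block
#' overriding the default endpoint definitions, and an `options` block.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @param base_dir Directory against which relative input paths are
#'   resolved; defaults to the config file's directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(path, base_dir = NULL) {
  if (is.character(path)) {
    if (!file.exists(path)) {
      stop("input error: config file not found: ", path, call. = FALSE)
    }
    cfg <- yaml::read_yaml(path)
    if (is.null(base_dir)) base_dir <- dirname(path)
  } else {
    cfg <- path
    if (is.null(base_dir)) base_dir <- "."
  }
  defaults <- list(
    curated_only = TRUE, union_go = FALSE, propagate = TRUE,
    top_n = 10L, threshold = 1L, enrichment = FALSE,
    exclude_endpoints = character(0), formats = c("tsv", "markdown", "json")
  )
  opts <- utils::modifyList(defaults, cfg$options %||% list())
  endpoints <- if (is.null(cfg$endpoints)) {
    default_endpoints()
  } else {
    defs <- lapply(cfg$endpoints, function(e) {
      endpoint_definition(e$name, unlist(e$mesh_root_ids),
        unlist(e$go_keywords) %||% character(0)
      )
    })
    names(defs) <- vapply(defs, `[[`, character(1), "name")
    defs
  }
  inputs <- lapply(cfg$inputs %||% list(), function(p) {
    if (is.character(p) && !startsWith(p, "/")) file.path(base_dir, p) else p
  })
  structure(
    list(
      inputs = inputs, endpoints = endpoints, options = opts,
      chemicals = cfg$chemicals, seed = cfg$seed %||% 1L
    ),
    class = "pipeline_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration for a generated fixture
#'
#' Convenience wrapper wiring a [generate_fixture()] manifest's files into
#' a [pipeline_config()].
#'
#' @param manifest A `fixture_manifest`.
#' @param options Named list of option overrides.
#' @param chemicals Chemicals to screen (default: all in the fixture).
#' @return A `pipeline_config`.
#' @export
fixture_pipeline_config <- function(manifest, options = list(),
                                    chemicals = NULL) {
  stopifnot(inherits(manifest, "fixture_manifest"))
  keys <- c(
    "disease_genes", "disease_vocab", "chemical_genes",
    "uniprot", "obo", "gaf"
  )
  pipeline_config(
    list(
      inputs = manifest$files[keys],
      options = options,
      chemicals = chemicals,
      seed = manifest$seed
    ),
    base_dir = "."
  )
}

check_inputs <- function(config, needed) {
  for (key in needed) {
    p <- config$inputs[[key]]
    if (is.null(p)) {
      stop("configuration error: missing input '", key, "'", call. = FALSE)
    }
    if (!file.exists(p)) {
      stop("input error: ", key, " file not found: ", p, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build the endpoint gene sets from configured inputs
#'
#' @param config A [pipeline_config()].
#' @return Named list of `endpoint_gene_set` objects.
#' @export
build_endpoint_sets <- function(config) {
  check_inputs(config, c("disease_genes", "disease_vocab"))
  records <- parse_disease_gene_file(
    config$inputs$disease_genes,
    curated_only = isTRUE(config$options$curated_only)
  )
  hierarchy <- parse_disease_vocab(config$inputs$disease_vocab)
  sets <- lapply(config$endpoints, function(ep) {
    collect_endpoint_genes(records, ep, hierarchy)
  })
  if (isTRUE(config$options$union_go)) {
    cov <- go_coverage(config, sets)
    for (e in names(sets)) {
      sets[[e]] <- merge_endpoint_genes(sets[[e]], cov$genes[[e]])
    }
  }
  sets
}

#' GO process coverage diagnostic
#'
#' Selects the biological processes matching each endpoint's keywords,
#' collects their annotated genes, and reports what fraction is already
#' contained in the CTD-derived endpoint sets. GO genes are a diagnostic
#' and are not merged into the endpoint sets unless `union_go` is set.
#'
#' @param config A [pipeline_config()].
#' @param sets Named list of endpoint gene sets (built if omitted).
#' @return List with `table` (data frame endpoint / n_processes /
#'   n_go_genes / coverage) and `genes` (per-endpoint GO gene vectors).
#' @export
go_coverage <- function(config, sets = NULL) {
  check_inputs(config, c("obo", "gaf"))
  ontology <- parse_obo(config$inputs$obo)
  annotations <- parse_gaf(config$inputs$gaf)
  if (is.null(sets)) sets <- build_endpoint_sets(config)
  rows <- list()
  genes <- list()
  for (e in names(config$endpoints)) {
    kw <- config$endpoints[[e]]$go_keywords
    ids <- if (length(kw)) select_processes(ontology, kw) else character(0)
    g <- if (length(ids)) {
      genes_for_processes(annotations, ontology, ids,
        propagate = isTRUE(config$options$propagate)
      )
    } else {
      character(0)
    }
    genes[[e]] <- g
    ctd <- if (inherits(sets[[e]], "endpoint_gene_set")) {
      sets[[e]]$genes
    } else {
      sets[[e]]
    }
    ctd_atoms <- unique(unlist(gene_members(ctd), use.names = FALSE))
    rows[[e]] <- data.frame(
      endpoint = e, n_processes = length(ids), n_go_genes = length(g),
      coverage = coverage_vs_ctd(g, ctd_atoms), stringsAsFactors = FALSE
    )
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)), genes = genes)
}

#' Run the full screening pipeline
#'
#' Builds the endpoint gene sets, computes the Venn partition and
#' bipartite network, applies the secretome refinement, ranks candidate
#' biomarkers, screens every configured chemical, and writes all
#' artifacts plus a machine-readable run manifest with file digests.
#' Identical config and inputs yield byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- config$options

  sets <- build_endpoint_sets(config)
  files <- character(0)

  sets_df <- do.call(rbind, lapply(sets, function(s) {
    if (length(s$genes) == 0L) {
      return(NULL)
    }
    data.frame(
      endpoint = s$endpoint, gene = s$genes,
      sources = vapply(s$provenance, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  p <- file.path(out_dir, "endpoint_sets.tsv")
  write_tsv_file(sets_df, p)
  files <- c(files, p)

  partition <- venn_partition(lapply(sets, `[[`, "genes"))
  p <- file.path(out_dir, "venn_regions.json")
  write_venn_json(partition, p)
  files <- c(files, p)

  secretome <- NULL
  if (!is.null(config$inputs$uniprot)) {
    check_inputs(config, "uniprot")
    secretome <- parse_uniprot_table(config$inputs$uniprot)
    res <- filter_secreted(partition$universe, secretome)
    p <- file.path(out_dir, "unresolved_symbols.tsv")
    write_unresolved(res$unresolved, p)
    files <- c(files, p)
    sec_partition <- venn_partition(lapply(sets, function(s) {
      filter_secreted(s$genes, secretome)$secreted
    }))
    p <- file.path(out_dir, "venn_regions_secreted.json")
    write_venn_json(sec_partition, p)
    files <- c(files, p)
    sec_net <- build_network(sec_partition, secretome,
      exclude = opts$exclude_endpoints
    )
    p <- file.path(out_dir, "network_secreted.graphml")
    export_graph(sec_net, p, "graphml")
    files <- c(files, p)
  }

  network <- build_network(partition, secretome,
    exclude = opts$exclude_endpoints
  )
  p <- file.path(out_dir, "network.graphml")
  export_graph(network, p, "graphml")
  files <- c(files, p)
  files <- c(files, export_graph(network, out_dir, "tsv"))
  p <- file.path(out_dir, "network_statements.txt")
  export_graph(network, p, "statements")
  files <- c(files, p)

  cov <- NULL
  if (!is.null(config$inputs$obo) && !is.null(config$inputs$gaf)) {
    cov <- go_coverage(config, sets)
    p <- file.path(out_dir, "go_coverage.tsv")
    write_tsv_file(cov$table, p)
    files <- c(files, p)
  }

  interactions <- NULL
  reports <- list()
  if (!is.null(config$inputs$chemical_genes)) {
    check_inputs(config, "chemical_genes")
    interactions <- parse_chemical_gene_file(config$inputs$chemical_genes)
    chems <- config$chemicals %||% unique(interactions$chemical_name)
    dir.create(file.path(out_dir, "screening"), showWarnings = FALSE)
    for (chem in chems) {
      rep <- screen_chemical(interactions, chem, sets,
        n = opts$top_n, threshold = opts$threshold,
        enrichment = isTRUE(opts$enrichment)
      )
      slug <- tolower(gsub("[^A-Za-z0-9]+", "_", chem))
      for (fmt in opts$formats) {
        ext <- c(tsv = "tsv", markdown = "md", json = "json")[[fmt]]
        p <- file.path(out_dir, "screening", paste0(slug, ".", ext))
        write_report(rep, p, fmt)
        files <- c(files, p)
      }
      reports[[chem]] <- rep
    }
  }

  candidates <- rank_candidates(partition, secretome, interactions)
  p <- file.path(out_dir, "ranked_biomarkers.tsv")
  write_ranked_tsv(candidates, p)
  files <- c(files, p)

  manifest <- list(
    package_version = as.character(utils::packageVersion("immunoscreen")),
    options = opts[order(names(opts))],
    inputs = lapply(config$inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  p <- file.path(out_dir, "run_manifest.json")
  write_json_file(manifest, p)

  invisible(list(
    endpoint_sets = sets, partition = partition, network = network,
    secretome = secretome, go_coverage = cov, candidates = candidates,
    reports = reports, files = c(files, p)
  ))
}
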