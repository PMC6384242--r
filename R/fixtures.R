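#' Default Venn region sizes for synthetic fixtures
#'
#' Desk-scale overlap structure over the four endpoints: every
#' single-endpoint region populated, modest pairwise/triple overlaps, and
#' a 15-gene four-way core mirroring the size of the reported all-endpoint
#' overlap.
#'
#' @return Named integer vector signature -> count.
#' @export
default_region_sizes <- function() {
  eps <- ENDPOINT_ORDER
  sizes <- integer(0)
  for (e in eps) sizes[e] <- 12L
  pairs <- utils::combn(eps, 2)
  for (i in seq_len(ncol(pairs))) {
    sizes[paste(pairs[, i], collapse = "+")] <- 4L
  }
  triples <- utils::combn(eps, 3)
  for (i in seq_len(ncol(triples))) {
    sizes[paste(triples[, i], collapse = "+")] <- 2L
  }
  sizes[paste(eps, collapse = "+")] <- 15L
  sizes
}

#' Default fixture chemicals
#'
#' Two screening profiles mirroring the qualitative anti-cancer-drug test
#' cases: one chemical whose top genes touch all four endpoints and one
#' touching only infection.
#'
#' @return List of chemical profile specs (`name`, `pattern`, `n_genes`).
#' @export
default_fixture_chemicals <- function() {
  list(
    list(name = "Bleomycin-like", pattern = ENDPOINT_ORDER, n_genes = 10L),
    list(name = "Bortezomib-like", pattern = "infection", n_genes = 10L)
  )
}

#' Configuration for the synthetic fixture generator
#'
#' @param seed Integer RNG seed; the same seed yields byte-identical
#'   files.
#' @param region_sizes Named vector signature -> planted gene count (see
#'   [default_region_sizes()]).
#' @param secreted_fraction Probability that a planted gene is annotated
#'   secreted.
#' @param chemicals List of profiles, each `list(name, pattern, n_genes)`.
#' @param mesh_depth Depth of the synthetic MeSH subtree under each root;
#'   genes attach to terms 1..depth below the root so that hierarchy
#'   expansion (not just root matching) is exercised.
#' @param decoy_genes Number of genes outside every endpoint set.
#' @param core_symbols Optional explicit symbols for the all-four region
#'   (length must equal its configured size).
#' @param fixed_secreted Optional named logical vector overriding the
#'   random secreted draw for specific (atomic) symbols.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           region_sizes = default_region_sizes(),
                           secreted_fraction = 0.4,
                           chemicals = default_fixture_chemicals(),
                           mesh_depth = 3L,
                           decoy_genes = 30L,
                           core_symbols = NULL,
                           fixed_secreted = NULL) {
  stopifnot(
    all(region_sizes >= 0), secreted_fraction >= 0, secreted_fraction <= 1,
    mesh_depth >= 1, decoy_genes >= 0
  )
  all_sig <- paste(ENDPOINT_ORDER, collapse = "+")
  if (!is.null(core_symbols) &&
    length(core_symbols) != region_sizes[[all_sig]]) {
    stop("configuration error: core_symbols length (", length(core_symbols),
      ") != all-four region size (", region_sizes[[all_sig]], ")",
      call. = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed), region_sizes = region_sizes,
      secreted_fraction = secreted_fraction, chemicals = chemicals,
      mesh_depth = as.integer(mesh_depth),
      decoy_genes = as.integer(decoy_genes),
      core_symbols = core_symbols, fixed_secreted = fixed_secreted
    ),
    class = "fixture_config"
  )
}

# Run expr with a locally seeded RNG, restoring global state afterwards.
with_fixture_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed,
    kind = "Mersenne-Twister", normal.kind = "Inversion",
    sample.kind = "Rejection"
  )
  expr
}

sig_parts <- function(k) strsplit(k, "+", fixed = TRUE)[[1]]

#' Generate a self-consistent synthetic fixture
#'
#' Writes every input dialect the pipeline consumes — disease-gene TSV,
#' disease vocabulary TSV, chemical-gene TSV, UniProt-dialect annotation
#' table, OBO ontology and GAF annotations — with planted endpoint sets,
#' Venn region structure, secretome flags and chemical hit patterns, plus
#' a ground-truth manifest for recovery tests. Decoy symbols come from a
#' synthetic alphabet (`SYN0001`, ...) so fixtures cannot be mistaken for
#' biological claims.
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return An object of class `fixture_manifest` (also written as
#'   `manifest.json` in `out_dir`).
#' @export
generate_fixture <- function(config = fixture_config(), out_dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_fixture_rng(config$seed, build_fixture(config, out_dir))
}

build_fixture <- function(config, out_dir) {
  eps <- default_endpoints()
  ep_names <- ENDPOINT_ORDER
  all_sig <- paste(ep_names, collapse = "+")

  ## --- gene symbol pool -------------------------------------------------
  sizes <- config$region_sizes
  sizes <- sizes[sizes > 0]
  n_planted <- sum(sizes)
  counter <- 0L
  next_syms <- function(k) {
    out <- sprintf("SYN%04d", counter + seq_len(k))
    counter <<- counter + k
    out
  }
  regions <- list()
  for (k in names(sizes)) {
    if (k == all_sig && !is.null(config$core_symbols)) {
      regions[[k]] <- canonicalize_gene(config$core_symbols)
    } else {
      regions[[k]] <- next_syms(sizes[[k]])
    }
  }
  decoys <- next_syms(config$decoy_genes)
  universe <- sort(unique(unlist(regions, use.names = FALSE)))
  if (length(universe) != n_planted) {
    stop("configuration error: duplicate symbols across regions",
      call. = FALSE
    )
  }
  ep_sets <- lapply(ep_names, function(e) {
    sort(unlist(regions[vapply(names(regions), function(k) {
      e %in% sig_parts(k)
    }, logical(1))], use.names = FALSE))
  })
  names(ep_sets) <- ep_names

  ## --- MeSH vocabulary --------------------------------------------------
  mesh_counter <- 0L
  vocab <- data.frame(
    DiseaseName = character(), DiseaseID = character(),
    ParentIDs = character(), stringsAsFactors = FALSE
  )
  ep_terms <- list() # endpoint -> non-root descendant terms
  for (e in ep_names) {
    roots <- eps[[e]]$mesh_root_ids
    vocab <- rbind(vocab, data.frame(
      DiseaseName = paste(e, "root", seq_along(roots)),
      DiseaseID = roots, ParentIDs = "", stringsAsFactors = FALSE
    ))
    terms <- character(0)
    for (root in roots) {
      level <- root
      for (d in seq_len(config$mesh_depth)) {
        mesh_counter <- mesh_counter + 2L
        ids <- sprintf("MESH:D9%05d", mesh_counter - 1:0)
        parent <- sample(level, 2L, replace = TRUE)
        vocab <- rbind(vocab, data.frame(
          DiseaseName = paste0(e, " term L", d, " #", ids),
          DiseaseID = ids, ParentIDs = parent, stringsAsFactors = FALSE
        ))
        terms <- c(terms, ids)
        level <- ids
      }
    }
    ep_terms[[e]] <- terms
  }

  ## --- disease-gene associations ---------------------------------------
  raw_symbol <- function(s) {
    # composites are written with a stray space to exercise canonicalization
    sub("/", "/ ", s, fixed = TRUE)
  }
  pmid <- function(n) {
    paste(9999999L + sample.int(20000000L, n), collapse = "|")
  }
  dg <- list()
  gene_id <- stats::setNames(
    seq_along(c(universe, decoys)) + 1000L, c(universe, decoys)
  )
  for (k in names(regions)) {
    for (g in regions[[k]]) {
      for (e in sig_parts(k)) {
        terms <- sample(ep_terms[[e]], sample(1:2, 1))
        for (t in terms) {
          dg[[length(dg) + 1L]] <- c(
            raw_symbol(g), gene_id[[g]],
            paste("disease", t), t,
            sample(c("marker/mechanism", "therapeutic"), 1,
              prob = c(0.8, 0.2)
            ),
            "", pmid(sample(1:3, 1))
          )
        }
      }
    }
  }
  # inferred-only rows: decoys attached to endpoint terms; the curated
  # filter must exclude them or recovery fails
  n_inf <- min(length(decoys), 10L)
  for (g in sample(decoys, n_inf)) {
    e <- sample(ep_names, 1)
    dg[[length(dg) + 1L]] <- c(
      raw_symbol(g), gene_id[[g]],
      paste("disease", ep_terms[[e]][1]), ep_terms[[e]][1],
      "", sprintf("%.2f", stats::runif(1, 1, 60)), pmid(1)
    )
  }
  dg <- do.call(rbind, dg)
  dg <- dg[sample(nrow(dg)), , drop = FALSE]

  ## --- secretome table --------------------------------------------------
  atoms <- unique(unlist(gene_members(c(universe, decoys)),
    use.names = FALSE
  ))
  # a couple of planted genes stay unannotated (unresolved side list)
  unres_pool <- setdiff(universe, regions[[all_sig]])
  unresolved <- sort(sample(unres_pool, min(2L, length(unres_pool))))
  ann_atoms <- setdiff(atoms, unlist(gene_members(unresolved)))
  sec_draw <- stats::runif(length(ann_atoms)) < config$secreted_fraction
  names(sec_draw) <- ann_atoms
  if (!is.null(config$fixed_secreted)) {
    ov <- intersect(names(config$fixed_secreted), ann_atoms)
    sec_draw[ov] <- config$fixed_secreted[ov]
  }
  kw_style <- stats::runif(length(ann_atoms)) < 0.5
  uni <- data.frame(
    GeneSymbol = ann_atoms,
    Keywords = ifelse(sec_draw & kw_style, "Cytokine;Secreted",
      ifelse(sec_draw, "Immunity", "Membrane")
    ),
    SubcellularLocation = ifelse(sec_draw & !kw_style,
      "Secreted, extracellular space",
      ifelse(sec_draw, "", "Cell membrane")
    ),
    stringsAsFactors = FALSE
  )
  uni <- uni[order(uni$GeneSymbol), , drop = FALSE]
  sec_universe <- sort(universe[genes_in_set(
    universe, ann_atoms[sec_draw]
  )])

  ## --- chemical-gene interactions --------------------------------------
  chem_rows <- list()
  chem_manifest <- list()
  for (ci in seq_along(config$chemicals)) {
    spec <- config$chemicals[[ci]]
    pattern <- spec$pattern
    n_genes <- spec$n_genes
    cid <- sprintf("FXCHEM%03d", ci)
    # eligible planted genes: signature non-empty and within the pattern
    eligible <- unlist(regions[vapply(names(regions), function(k) {
      p <- sig_parts(k)
      length(p) > 0 && all(p %in% pattern)
    }, logical(1))], use.names = FALSE)
    picked <- character(0)
    for (e in pattern) {
      pool <- setdiff(unlist(
        regions[vapply(names(regions), function(k) {
          p <- sig_parts(k)
          e %in% p && all(p %in% pattern)
        }, logical(1))],
        use.names = FALSE
      ), picked)
      if (any(picked %in% ep_sets[[e]])) next # already covered
      if (length(pool) == 0L) {
        stop("configuration error: no gene available to realize pattern ",
          "endpoint '", e, "' for chemical ", spec$name,
          call. = FALSE
        )
      }
      picked <- c(picked, sample(pool, 1))
    }
    n_fill <- n_genes - length(picked)
    # prefer endpoint-free decoys so the flag pattern stays exact
    fill_pool <- c(setdiff(decoys, picked), setdiff(eligible, picked))
    if (n_fill > length(fill_pool)) {
      stop("configuration error: not enough genes for chemical ",
        spec$name,
        call. = FALSE
      )
    }
    fill <- if (n_fill > 0) fill_pool[seq_len(n_fill)] else character(0)
    top <- c(picked, fill)
    counts <- sort(sample(5:40, length(top)), decreasing = TRUE)
    for (i in seq_along(top)) {
      cnt <- counts[i]
      split2 <- cnt > 6 && stats::runif(1) < 0.4
      parts <- if (split2) c(cnt %/% 2, cnt - cnt %/% 2) else cnt
      for (p in parts) {
        chem_rows[[length(chem_rows) + 1L]] <- c(
          spec$name, cid, raw_symbol(top[i]),
          sample(c("increases^expression", "decreases^expression",
            "affects^binding"), 1),
          p, pmid(sample(1:4, 1))
        )
      }
    }
    # sub-panel distractors: low-evidence genes outside the pattern that
    # must be truncated away by the top-n cut
    out_pool <- setdiff(universe, c(top, unlist(
      regions[vapply(names(regions), function(k) {
        all(sig_parts(k) %in% pattern)
      }, logical(1))],
      use.names = FALSE
    )))
    if (length(out_pool)) {
      for (g in sample(out_pool, min(3L, length(out_pool)))) {
        chem_rows[[length(chem_rows) + 1L]] <- c(
          spec$name, cid, raw_symbol(g), "affects^binding", 1, pmid(1)
        )
      }
    }
    expected_flags <- stats::setNames(ep_names %in% pattern, ep_names)
    chem_manifest[[spec$name]] <- list(
      chemical_id = cid, pattern = pattern,
      top_genes = sort(top), expected_flags = as.list(expected_flags)
    )
  }
  chem <- if (length(chem_rows)) {
    rows <- do.call(rbind, chem_rows)
    rows[sample(nrow(rows)), , drop = FALSE]
  } else {
    matrix(character(0), ncol = 6)
  }

  ## --- GO layer ---------------------------------------------------------
  go_keyword <- c(
    hypersensitivity = "hypersensitivity", autoimmunity = "autoimmun",
    infection = "defense response", cancer = "tumor"
  )
  obo <- c(
    "format-version: 1.2", "ontology: fixture-go", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", ""
  )
  go_id_n <- 0L
  new_go <- function() {
    go_id_n <<- go_id_n + 1L
    sprintf("GO:9%06d", go_id_n)
  }
  go_terms <- list()
  gaf_rows <- list()
  go_genes <- list()
  gaf_row <- function(sym, qual, goid) {
    c(
      "FX", paste0("FX:", sym), sym, qual, goid, "FX:ref|0001", "IDA", "",
      "P", sym, "", "protein", "taxon:9606", "20180101", "FX", "", ""
    )
  }
  for (e in ep_names) {
    parent <- new_go()
    child <- new_go()
    obo <- c(
      obo,
      "[Term]", paste0("id: ", parent),
      paste0("name: ", go_keyword[[e]], " process"),
      "namespace: biological_process", "is_a: GO:0008150 ! bp", "",
      "[Term]", paste0("id: ", child),
      paste0("name: regulation of ", e, " signaling"),
      "namespace: biological_process",
      paste0("is_a: ", parent, " ! ", go_keyword[[e]], " process"), ""
    )
    go_terms[[e]] <- c(parent, child)
    pool <- ep_sets[[e]]
    pool <- unlist(gene_members(pool), use.names = FALSE)
    n_ann <- min(length(pool), 6L)
    ann <- sample(pool, n_ann)
    half <- seq_len(ceiling(n_ann / 2))
    for (g in ann[half]) {
      gaf_rows[[length(gaf_rows) + 1L]] <- gaf_row(g, "involved_in", parent)
    }
    for (g in ann[-half]) {
      gaf_rows[[length(gaf_rows) + 1L]] <- gaf_row(g, "involved_in", child)
    }
    # planted NOT row: a decoy that must never surface
    notg <- sample(decoys, 1)
    gaf_rows[[length(gaf_rows) + 1L]] <- gaf_row(notg, "NOT|involved_in",
      parent
    )
    go_genes[[e]] <- sort(unique(ann))
  }
  # namespace / obsolete traps sharing a keyword
  mf <- new_go()
  obs <- new_go()
  obo <- c(
    obo,
    "[Term]", paste0("id: ", mf), "name: tumor antigen binding",
    "namespace: molecular_function", "",
    "[Term]", paste0("id: ", obs), "name: obsolete defense response relic",
    "namespace: biological_process", "is_obsolete: true", ""
  )

  ## --- write files ------------------------------------------------------
  paths <- list(
    disease_genes = file.path(out_dir, "disease_genes.tsv"),
    disease_vocab = file.path(out_dir, "disease_vocab.tsv"),
    chemical_genes = file.path(out_dir, "chemical_genes.tsv"),
    uniprot = file.path(out_dir, "secretome.tsv"),
    obo = file.path(out_dir, "ontology.obo"),
    gaf = file.path(out_dir, "annotations.gaf"),
    manifest = file.path(out_dir, "manifest.json")
  )
  writeLines(c(
    "# Synthetic gene-disease associations (fixture; not biological data)",
    "# GeneSymbol\tGeneID\tDiseaseName\tDiseaseID\tDirectEvidence\tInferenceScore\tPubMedIDs",
    apply(dg, 1, paste, collapse = "\t")
  ), paths$disease_genes)
  writeLines(c(
    "# Synthetic disease vocabulary (fixture)",
    "# DiseaseName\tDiseaseID\tParentIDs",
    paste(vocab$DiseaseName, vocab$DiseaseID, vocab$ParentIDs, sep = "\t")
  ), paths$disease_vocab)
  writeLines(c(
    "# Synthetic chemical-gene interactions (fixture)",
    "# ChemicalName\tChemicalID\tGeneSymbol\tInteractionActions\tInteractionCount\tPubMedIDs",
    apply(chem, 1, paste, collapse = "\t")
  ), paths$chemical_genes)
  writeLines(c(
    "GeneSymbol\tKeywords\tSubcellularLocation",
    paste(uni$GeneSymbol, uni$Keywords, uni$SubcellularLocation, sep = "\t")
  ), paths$uniprot)
  writeLines(obo, paths$obo)
  writeLines(c(
    "!gaf-version: 2.1",
    vapply(gaf_rows, paste, character(1), collapse = "\t")
  ), paths$gaf)

  manifest <- structure(
    list(
      seed = config$seed,
      files = paths,
      endpoints = ep_sets,
      regions = regions[order(names(regions))],
      universe = universe,
      decoys = decoys,
      secreted = sec_universe,
      unresolved = unresolved,
      chemicals = chem_manifest,
      go_terms = go_terms,
      go_genes = go_genes
    ),
    class = "fixture_manifest"
  )
  write_json_file(unclass(manifest), paths$manifest)
  manifest
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf(
    "<fixture manifest> %d genes, %d regions, %d chemicals (seed %d)\n",
    length(x$universe), length(x$regions), length(x$chemicals), x$seed
  ))
  invisible(x)
}

#' The 15-molecule four-way overlap core
#'
#' The molecules reported as shared by all four immune health endpoints;
#' the HLA-DQA2/HLA-DQA1 pair counts as one composite molecule.
#'
#' @return Character vector of 15 canonical symbols.
#' @export
core_molecules <- function() {
  c(
    "ALB", "HLA-DPB1", "HLA-DQA2/HLA-DQA1", "HLA-DRB1", "ICAM1", "IFNG",
    "IL1B", "IL4", "IL6", "IL10", "IL12B", "IL18", "MPO", "CCL2", "TNF"
  )
}

#' Build the worked-example fixture around the published four-way core
#'
#' Each endpoint set contains exactly the 15 shared core molecules plus 5
#' endpoint-unique synthetic decoys (set size 20), with a
#' bleomycin-like chemical profile touching all four endpoints and a
#' bortezomib-like profile touching only infection. Secretion flags for
#' the core molecules follow their UniProt annotations (cytokines,
#' albumin and MPO secreted; ICAM1 and the HLA molecules membrane-bound);
#' decoys draw randomly.
#'
#' @param out_dir Output directory.
#' @param seed RNG seed (default 20180101 is arbitrary but fixed).
#' @return A `fixture_manifest`.
#' @export
worked_example_fixture <- function(out_dir, seed = 20180101L) {
  sizes <- stats::setNames(
    rep(0L, length(default_region_sizes())), names(default_region_sizes())
  )
  for (e in ENDPOINT_ORDER) sizes[e] <- 5L
  sizes[paste(ENDPOINT_ORDER, collapse = "+")] <- 15L
  secreted_core <- c(
    ALB = TRUE, `HLA-DPB1` = FALSE, `HLA-DQA2` = FALSE, `HLA-DQA1` = FALSE,
    `HLA-DRB1` = FALSE, ICAM1 = FALSE, IFNG = TRUE, IL1B = TRUE, IL4 = TRUE,
    IL6 = TRUE, IL10 = TRUE, IL12B = TRUE, IL18 = TRUE, MPO = TRUE,
    CCL2 = TRUE, TNF = TRUE
  )
  cfg <- fixture_config(
    seed = seed,
    region_sizes = sizes,
    core_symbols = core_molecules(),
    fixed_secreted = secreted_core,
    chemicals = default_fixture_chemicals(),
    mesh_depth = 3L,
    decoy_genes = 30L
  )
  generate_fixture(cfg, out_dir)
}
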