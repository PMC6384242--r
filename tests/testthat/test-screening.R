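make_chem_file <- function(rows) {
  write_lines_tmp(c(
    "# ChemicalName\tChemicalID\tGeneSymbol\tInteractionActions\tInteractionCount\tPubMedIDs",
    rows
  ))
}

test_that("chemical-gene rows aggregate per (chemical, gene)", {
  path <- make_chem_file(c(
    "drugA\tC1\tIL6\tincreases^expression\t2\t111|222",
    "drugA\tC1\til6\tdecreases^expression\t3\t222|333",
    "drugA\tC1\tTNF\taffects^binding\t1\t444",
    "drugB\tC2\tIL6\taffects^binding\t4\t555"
  ))
  tbl <- parse_chemical_gene_file(path)
  expect_equal(nrow(tbl), 3L)
  row <- tbl[tbl$chemical_id == "C1" & tbl$gene_symbol == "IL6", ]
  expect_equal(row$interaction_count, 5L)
  expect_equal(row$reference_count, 3L) # distinct PMIDs 111,222,333
  expect_error(
    parse_chemical_gene_file(make_chem_file("drugA\tC1\tIL6\tx\t0\t1")),
    "InteractionCount"
  )
})

test_that("top genes follow the (interaction, reference, symbol) key", {
  path <- make_chem_file(c(
    "drugA\tC1\tG1\tx\t5\t1|2",
    "drugA\tC1\tG2\tx\t3\t1",
    "drugA\tC1\tG3\tx\t1\t1",
    "drugA\tC1\tZZ\tx\t3\t1" # count tie with G2, equal refs
  ))
  tbl <- parse_chemical_gene_file(path)
  top2 <- top_interacting_genes(tbl, "drugA", 2)
  expect_equal(top2$gene_symbol, c("G1", "G2")) # tie broken alphabetically
  all4 <- top_interacting_genes(tbl, "C1", 10) # fewer than n: all returned
  expect_equal(nrow(all4), 4L)
  expect_equal(all4$gene_symbol, c("G1", "G2", "ZZ", "G3"))
  by_ref <- top_interacting_genes(tbl, "drugA", 4, rank_by = "reference")
  expect_equal(by_ref$gene_symbol[1], "G1")
  expect_error(top_interacting_genes(tbl, "drugZZ", 2), "did you mean")
})

test_that("top-gene ordering equals an independent full sort", {
  set.seed(47)
  n <- 40
  rows <- sprintf(
    "drugR\tCR\tG%02d\tx\t%d\t%s", seq_len(n),
    sample(1:8, n, replace = TRUE),
    vapply(seq_len(n), function(i) {
      paste(sample(1000:9999, sample(1:4, 1)), collapse = "|")
    }, character(1))
  )
  tbl <- parse_chemical_gene_file(make_chem_file(rows))
  got <- top_interacting_genes(tbl, "drugR", 10)$gene_symbol
  o <- tbl[order(-tbl$interaction_count, -tbl$reference_count,
    tbl$gene_symbol
  ), ]
  expect_equal(got, o$gene_symbol[1:10])
})

test_that("screening reproduces planted qualitative flag patterns", {
  manifest <- cached_core_fixture()
  sets <- recover_sets(manifest)
  tbl <- parse_chemical_gene_file(manifest$files$chemical_genes)

  all4 <- screen_chemical(tbl, "Bleomycin-like", sets)
  expect_true(all(all4$flagged))
  only_inf <- screen_chemical(tbl, "Bortezomib-like", sets)
  expect_equal(
    names(only_inf$flagged)[only_inf$flagged], "infection"
  )
  # matrix/hit-count consistency
  for (r in list(all4, only_inf)) {
    expect_equal(r$hit_counts, colSums(r$membership), ignore_attr = TRUE)
    expect_true(all(r$hit_counts <= nrow(r$top_genes)))
    expect_equal(sum(r$membership), sum(r$hit_counts))
    expect_true(all(r$hit_counts[r$flagged] >= r$threshold))
  }
  # expected top-gene panel from the manifest
  expect_setequal(
    all4$top_genes$gene_symbol,
    manifest$chemicals$`Bleomycin-like`$top_genes
  )
})

test_that("a chemical whose genes miss every endpoint yields zero flags", {
  tbl <- parse_chemical_gene_file(make_chem_file(c(
    "inert\tC9\tXX1\tx\t3\t1",
    "inert\tC9\tXX2\tx\t2\t1"
  )))
  sets <- list(
    hypersensitivity = c("IL6"), autoimmunity = c("TNF"),
    infection = c("ALB"), cancer = c("MPO")
  )
  r <- screen_chemical(tbl, "inert", sets)
  expect_false(any(r$membership))
  expect_false(any(r$flagged))
})

test_that("screening is invariant to interaction-file row order", {
  manifest <- cached_core_fixture()
  sets <- recover_sets(manifest)
  lines <- readLines(manifest$files$chemical_genes)
  hdr <- startsWith(lines, "#")
  set.seed(53)
  shuffled <- write_lines_tmp(c(lines[hdr], sample(lines[!hdr])))
  a <- screen_chemical(
    parse_chemical_gene_file(manifest$files$chemical_genes),
    "Bleomycin-like", sets
  )
  b <- screen_chemical(parse_chemical_gene_file(shuffled),
    "Bleomycin-like", sets
  )
  expect_equal(a$top_genes, b$top_genes)
  expect_equal(a$membership, b$membership)
})

test_that("hypergeometric tail matches exhaustive enumeration and is monotone", {
  # oracle: enumerate all k-subsets of the background and count hits
  enum_tail <- function(hits, k, m, N) {
    pop <- c(rep(TRUE, m), rep(FALSE, N - m))
    subsets <- utils::combn(N, k)
    mean(colSums(matrix(pop[subsets], nrow = k)) >= hits)
  }
  expect_identical(enrichment_tail(0, 3, 5, 10), 1.0)
  expect_equal(enrichment_tail(3, 3, 10, 10), 1.0) # all-success urn
  expect_equal(
    enrichment_tail(2, 4, 5, 12),
    enum_tail(2, 4, 5, 12),
    tolerance = 1e-12
  )
  set.seed(59)
  for (rep in 1:20) {
    N <- sample(2:20, 1)
    k <- sample(1:min(N, 8), 1)
    m <- sample(0:N, 1)
    prev <- Inf
    for (hits in 0:k) {
      got <- enrichment_tail(hits, k, m, N)
      expect_equal(got, enum_tail(hits, k, m, N), tolerance = 1e-12)
      expect_lte(got, prev + 1e-15) # non-increasing in hits
      prev <- got
    }
  }
  expect_error(enrichment_tail(5, 3, 2, 10), "bounds")
})

test_that("reports render and round-trip in every format", {
  manifest <- cached_core_fixture()
  sets <- recover_sets(manifest)
  tbl <- parse_chemical_gene_file(manifest$files$chemical_genes)
  r <- screen_chemical(tbl, "Bleomycin-like", sets, enrichment = TRUE)
  expect_true(all(r$enrichment > 0 & r$enrichment <= 1))

  md <- tempfile(fileext = ".md")
  write_report(r, md, "markdown")
  body <- grep("^\\| [A-Z]", readLines(md), value = TRUE)
  expect_equal(length(body), nrow(r$top_genes)) # one row per top gene
  expect_true(any(grepl("×", body)))

  tsv <- tempfile(fileext = ".tsv")
  write_report(r, tsv, "tsv")
  df <- read.delim(tsv)
  expect_equal(nrow(df), nrow(r$top_genes) + 2L) # + hits and flags rows

  js <- tempfile(fileext = ".json")
  write_report(r, js, "json")
  x <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(x$chemical, r$chemical)
  expect_equal(x$top_genes$gene_symbol, r$top_genes$gene_symbol)
  expect_equal(unlist(x$hit_counts), r$hit_counts, ignore_attr = TRUE)
  expect_equal(
    as.matrix(x$membership), r$membership,
    ignore_attr = TRUE
  )
  expect_error(write_report(r, tempfile(), "xlsx"), "unknown report format")
})
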