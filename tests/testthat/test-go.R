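make_obo <- function() {
  write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000001", "name: mast cell degranulation",
    "namespace: biological_process", "is_a: GO:0008150 ! bp", "",
    "[Term]", "id: GO:0000002", "name: regulation of mast cell degranulation",
    "namespace: biological_process", "is_a: GO:0000001 ! parent", "",
    "[Term]", "id: GO:0000003", "name: mast cell antigen binding",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000004", "name: obsolete mast cell process",
    "namespace: biological_process", "is_obsolete: true", ""
  ), ".obo")
}

gaf_line <- function(sym, qual, goid) {
  paste(c(
    "FX", paste0("FX:", sym), sym, qual, goid, "FX:ref", "IDA", "",
    "P", sym, "", "protein", "taxon:9606", "20180101", "FX"
  ), collapse = "\t")
}

make_gaf <- function(lines) {
  write_lines_tmp(c("!gaf-version: 2.1", lines), ".gaf")
}

test_that("OBO parsing captures terms, namespaces, is_a edges and obsolete flags", {
  obo <- parse_obo(make_obo())
  expect_equal(nrow(obo$terms), 5L)
  expect_true(obo$terms$obsolete[obo$terms$id == "GO:0000004"])
  expect_equal(obo$parents[["GO:0000002"]], "GO:0000001")
  # per-namespace counts match a direct grep of the file
  raw <- readLines(make_obo())
  expect_equal(
    as.vector(table(obo$terms$namespace)),
    as.vector(table(sub("^namespace: ", "",
      grep("^namespace:", raw, value = TRUE)
    )))
  )
  minimal <- parse_obo(write_lines_tmp(c(
    "[Term]", "id: GO:0000009", "name: x", "namespace: biological_process"
  ), ".obo"))
  expect_equal(nrow(minimal$terms), 1L)
  expect_error(
    parse_obo(write_lines_tmp(c("[Term]", "name: no id"), ".obo")),
    "line 1"
  )
})

test_that("process selection is keyword-based, BP-only, non-obsolete", {
  obo <- parse_obo(make_obo())
  sel <- select_processes(obo, "mast cell")
  # the MF term and the obsolete BP term share the keyword but are excluded
  expect_setequal(sel, c("GO:0000001", "GO:0000002"))
  expect_equal(select_processes(obo, "MAST CELL"), sel) # case-insensitive
  expect_equal(select_processes(obo, "no such process"), character(0))
  expect_error(select_processes(obo, character(0)), "keyword")
})

test_that("annotation propagation climbs is_a edges and NOT rows never contribute", {
  obo <- parse_obo(make_obo())
  ann <- parse_gaf(make_gaf(c(
    gaf_line("KIT", "involved_in", "GO:0000002"), # child term
    gaf_line("IL6", "involved_in", "GO:0000001"), # queried term
    gaf_line("TNF", "NOT|involved_in", "GO:0000001")
  )))
  with_prop <- genes_for_processes(ann, obo, "GO:0000001", propagate = TRUE)
  expect_setequal(with_prop, c("IL6", "KIT"))
  without <- genes_for_processes(ann, obo, "GO:0000001", propagate = FALSE)
  expect_equal(without, "IL6")
  expect_true(all(without %in% with_prop)) # propagation is monotone
  expect_false("TNF" %in% with_prop)
  expect_error(
    genes_for_processes(ann, obo, "GO:9999999"),
    "unknown GO id"
  )
  expect_error(parse_gaf(make_gaf("too\tshort")), "parse error")
})

test_that("propagated membership equals a brute-force ancestor-closure oracle", {
  set.seed(5)
  # random ontology: 30 BP terms, each with 0-2 parents among earlier terms
  ids <- sprintf("GO:%07d", seq_len(30))
  lines <- c("format-version: 1.2", "")
  for (i in seq_along(ids)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
      paste0("name: process ", i), "namespace: biological_process"
    )
    if (i > 1) {
      for (p in sample(ids[seq_len(i - 1)], sample(0:2, 1))) {
        lines <- c(lines, paste0("is_a: ", p))
      }
    }
    lines <- c(lines, "")
  }
  obo <- parse_obo(write_lines_tmp(lines, ".obo"))
  genes <- sprintf("G%02d", 1:20)
  ann <- parse_gaf(make_gaf(vapply(genes, function(g) {
    gaf_line(g, "involved_in", sample(ids, 1))
  }, character(1))))
  query <- sample(ids, 5)
  got <- genes_for_processes(ann, obo, query, propagate = TRUE)
  # oracle: per-gene ancestor closure membership test
  closure <- function(id) {
    out <- id
    repeat {
      more <- unique(unlist(obo$parents[out]))
      if (all(more %in% out)) {
        return(out)
      }
      out <- union(out, more)
    }
  }
  oracle <- sort(unique(ann$gene_symbol[vapply(ann$go_id, function(t) {
    any(closure(t) %in% query)
  }, logical(1))]))
  expect_equal(got, oracle)
})

test_that("coverage fraction behaves at the boundaries and is stable under CTD padding", {
  expect_equal(coverage_vs_ctd(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(coverage_vs_ctd(c("A", "B"), c("C", "D")), 0.0)
  expect_equal(coverage_vs_ctd(character(0), c("A")), 1.0)
  go <- sprintf("G%02d", 1:10)
  ctd <- c(go[1:7], "X1", "X2")
  expect_equal(coverage_vs_ctd(go, ctd), 0.7)
  # adding CTD genes outside the GO set never changes coverage
  expect_equal(coverage_vs_ctd(go, c(ctd, "Y1", "Y2", "Y3")), 0.7)
})

test_that("the fixture GO layer recovers the planted process genes", {
  manifest <- cached_random_fixture(7)
  obo <- parse_obo(manifest$files$obo)
  ann <- parse_gaf(manifest$files$gaf)
  eps <- default_endpoints()
  for (e in names(manifest$go_genes)) {
    ids <- select_processes(obo, eps[[e]]$go_keywords)
    expect_true(all(unlist(manifest$go_terms[[e]]) %in% obo$terms$id))
    got <- genes_for_processes(ann, obo, ids, propagate = TRUE)
    expect_equal(got, sort(manifest$go_genes[[e]]))
  }
})
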