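test_that("gene symbols canonicalize: case, trim, composite whitespace", {
  expect_equal(canonicalize_gene("il6"), "IL6")
  expect_equal(canonicalize_gene(" tnf "), "TNF")
  expect_equal(
    canonicalize_gene("HLA-DQA2/ HLA-DQA1"),
    "HLA-DQA2/HLA-DQA1"
  )
  expect_equal(
    gene_members("HLA-DQA2/HLA-DQA1")[[1]],
    c("HLA-DQA2", "HLA-DQA1")
  )
  expect_error(canonicalize_gene(""), "empty")
  expect_error(canonicalize_gene("   "), "empty")
})

test_that("disease-gene parser applies the curated-evidence filter", {
  path <- tiny_disease_gene_file()
  direct <- parse_disease_gene_file(path, curated_only = TRUE)
  expect_equal(nrow(direct), 3L)
  expect_true(all(direct$evidence_class == "direct"))
  expect_true(all(nzchar(direct$direct_evidence_label)))
  all_rows <- parse_disease_gene_file(path, curated_only = FALSE)
  expect_equal(nrow(all_rows), 5L)
  expect_equal(sum(all_rows$evidence_class == "inferred"), 2L)
  # evidence_class is direct iff the label is non-empty
  expect_equal(
    all_rows$evidence_class == "direct",
    nzchar(all_rows$direct_evidence_label)
  )
  # composite symbol canonicalized, reference counts from distinct PMIDs
  expect_true("HLA-DQA2/HLA-DQA1" %in% all_rows$gene_symbol)
  expect_equal(all_rows$reference_count[all_rows$gene_symbol == "IL6"], 2L)
  marker <- parse_disease_gene_file(path,
    evidence_labels = "marker/mechanism"
  )
  expect_equal(nrow(marker), 2L)
})

test_that("comment-only files give empty collections; errors are precise", {
  empty <- write_lines_tmp(c("# only", "# comments"))
  expect_equal(nrow(parse_disease_gene_file(empty)), 0L)
  expect_error(parse_disease_gene_file(tempfile()), "not found")
  bad <- write_lines_tmp(c("# h", "A\tB", "A\tB\tC"))
  expect_error(parse_disease_gene_file(bad), "line 2")
})

test_that("parser row count matches a naive line-count oracle on a generated file", {
  set.seed(41)
  n <- 50
  rows <- sprintf(
    "G%02d\t%d\tdisease\tMESH:D%07d\t%s\t\t%d",
    seq_len(n), seq_len(n), sample(100, n, replace = TRUE),
    sample(c("marker/mechanism", ""), n, replace = TRUE), seq_len(n)
  )
  path <- write_lines_tmp(c("# header", rows))
  # oracle: count non-comment lines directly
  oracle <- sum(!startsWith(readLines(path), "#"))
  expect_equal(nrow(parse_disease_gene_file(path, curated_only = FALSE)),
    oracle
  )
})

test_that("readers tolerate CRLF endings and trailing empty columns", {
  path <- tempfile(fileext = ".tsv")
  con <- file(path, "wb")
  writeLines(c(
    "# h",
    "IL6\t1\tasthma\tMESH:D001249\tmarker/mechanism\t\t",
    "TNF\t2\tasthma\tMESH:D001249\tmarker/mechanism\t\t123"
  ), con, sep = "\r\n")
  close(con)
  rec <- parse_disease_gene_file(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$disease_id, rep("MESH:D001249", 2))
  expect_equal(rec$reference_count, c(0L, 1L))
})

test_that("MeSH expansion covers leaves, chains, and errors on unknown roots", {
  leaf <- mesh_hierarchy("MESH:D1")
  expect_equal(expand_mesh_descendants(leaf, "MESH:D1"), "MESH:D1")
  chain <- chain_hierarchy()
  expect_setequal(
    expand_mesh_descendants(chain, "MESH:D1"),
    c("MESH:D1", "MESH:D2", "MESH:D3")
  )
  expect_error(
    expand_mesh_descendants(chain, "MESH:D9"),
    "MESH:D9"
  )
  expect_error(
    mesh_hierarchy(c("A", "B"), list(A = "B", B = "A")),
    "cycle"
  )
})

test_that("expansion equals the fixpoint oracle and is idempotent/monotone", {
  set.seed(11)
  for (rep in 1:10) {
    h <- random_hierarchy(50)
    roots <- sample(h$nodes, 3)
    got <- expand_mesh_descendants(h, roots)
    expect_equal(got, expand_fixpoint_oracle(h, roots))
    # idempotence: expanding the closure returns the closure
    expect_equal(expand_mesh_descendants(h, got), got)
    # monotonicity: adding a root never shrinks the closure
    extra <- sample(setdiff(h$nodes, roots), 1)
    bigger <- expand_mesh_descendants(h, c(roots, extra))
    expect_true(all(got %in% bigger))
  }
})

test_that("endpoint collection follows descendant expansion", {
  records <- parse_disease_gene_file(tiny_disease_gene_file())
  hierarchy <- parse_disease_vocab(tiny_vocab_file())
  eps <- default_endpoints()
  hyp <- collect_endpoint_genes(records, eps$hypersensitivity, hierarchy)
  # asthma is a child term of the hypersensitivity root
  expect_setequal(hyp$genes, c("IL6", "TNF"))
  expect_true(all(vapply(hyp$provenance, identical, logical(1), "ctd")))
  auto <- collect_endpoint_genes(records, eps$autoimmunity, hierarchy)
  expect_equal(auto$genes, "HLA-DQA2/HLA-DQA1")
  # disjoint subtree: lupus/asthma genes never leak into infection
  vocab2 <- parse_disease_vocab(write_lines_tmp(c(
    "infection root\tMESH:D010272\t",
    "bacterial\tMESH:D001423\t",
    "viral\tMESH:D014777\t",
    "hypersensitivity\tMESH:D006967\t",
    "asthma\tMESH:D001249\tMESH:D006967"
  )))
  inf <- collect_endpoint_genes(records, eps$infection, vocab2)
  expect_equal(inf$genes, character(0))
})

test_that("planted endpoint sets are recovered exactly from fixture files", {
  manifest <- cached_random_fixture(7)
  sets <- recover_sets(manifest)
  for (e in names(manifest$endpoints)) {
    expect_equal(sets[[e]]$genes, sort(manifest$endpoints[[e]]))
  }
})
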