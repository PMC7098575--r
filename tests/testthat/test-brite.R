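brite_fixture <- function() {
  write_tsv_fixture(c(
    "A<b>Genes and Proteins</b>",
    "B  First category",
    "C    br:sy001  Alpha hierarchy",
    "C    sy002  Beta hierarchy",
    "B  Second category",
    "C    sy003  Gamma hierarchy"
  ))
}

test_that("BRITE reference parsing yields the catalogue in file order", {
  cat <- parse_brite_reference(brite_fixture())
  expect_equal(nrow(cat), 3L)
  expect_equal(cat$brite_id, c("sy001", "sy002", "sy003")) # prefixes stripped
  expect_equal(cat$category,
               c("First category", "First category", "Second category"))
  # empty file -> empty catalogue
  empty <- parse_brite_reference(write_tsv_fixture(character(0)))
  expect_equal(nrow(empty), 0L)
  # orphan hierarchy line before any category
  orphan <- write_tsv_fixture(c("A<b>Genes and Proteins</b>",
                                "C    sy001  Orphan"))
  expect_error(parse_brite_reference(orphan), "line 2")
  # unknown level marker
  bad <- write_tsv_fixture(c("A<b>x</b>", "B  cat", "D  nonsense"))
  expect_error(parse_brite_reference(bad), "unknown level")
})

test_that("the packaged catalogue has the documented category structure", {
  path <- system.file("extdata", "synthetic_br08902.keg", package = "gximage")
  cat <- parse_brite_reference(path)
  expect_equal(length(unique(cat$category)), 4L)
  expect_equal(nrow(cat), 45L)
  expect_equal(sum(cat$category == "Protein families: metabolism"), 9L)
  # sections other than Genes and Proteins are excluded
  expect_false(any(grepl("compound", cat$category, ignore.case = TRUE)))
})

test_that("link tables are de-duplicated and prefix-normalized", {
  p <- write_tsv_fixture(c("br:sy001\thsa:10", "sy001\t11", "br:sy002\thsa:12"))
  links <- parse_link_table(p)
  expect_equal(nrow(links), 3L)
  expect_equal(links$brite_id, c("sy001", "sy001", "sy002"))
  expect_equal(links$kegg_gene_id, c("10", "11", "12"))
  # duplicated row collapses
  pd <- write_tsv_fixture(c("br:sy001\thsa:10", "sy001\t10"))
  expect_equal(nrow(parse_link_table(pd)), 1L)
  # wrong column count
  pb <- write_tsv_fixture(c("a\tb", "c"))
  expect_error(parse_link_table(pb), "row 2")
})

chain_fixture <- function(hgnc_rows = NULL) {
  list_path <- write_tsv_fixture(c(
    "hsa:10\tSYMA, aliasA; a synthetic gene",
    "hsa:11\tSYMB; another one",
    "hsa:12\tSYMC"
  ))
  if (is.null(hgnc_rows)) {
    hgnc_rows <- c("SYMA\tENSG1", "SYMB\tENSG2")
  }
  hgnc_path <- write_tsv_fixture(c("symbol\tensembl_gene_id", hgnc_rows))
  build_id_chain(list_path, hgnc_path)
}

test_that("the identifier chain composes KEGG -> HUGO -> ENSEMBL", {
  ch <- chain_fixture()
  expect_s3_class(ch, "gx_id_chain")
  expect_equal(ch$kegg_to_hugo$hugo, c("SYMA", "SYMB", "SYMC"))
  # SYMC has no ENSEMBL id: excluded but counted
  expect_equal(ch$report$n_symbols_without_ensembl, 1L)
  # many-to-many: one symbol with two ENSEMBL ids keeps both
  ch2 <- chain_fixture(c("SYMA\tENSG1", "SYMA\tENSG9", "SYMB\tENSG2"))
  expect_equal(sort(ch2$hugo_to_ensembl$ensembl[ch2$hugo_to_ensembl$hugo == "SYMA"]),
               c("ENSG1", "ENSG9"))
  # schema error
  bad_hgnc <- write_tsv_fixture(c("symbol\tother", "SYMA\tx"))
  list_path <- write_tsv_fixture("hsa:10\tSYMA; d")
  expect_error(build_id_chain(list_path, bad_hgnc), "ensembl_gene_id")
})

test_that("tree construction maps, prunes and counts leaves correctly", {
  cat <- parse_brite_reference(brite_fixture())
  links <- parse_link_table(write_tsv_fixture(c(
    "br:sy001\thsa:10", "br:sy002\thsa:10", "br:sy003\thsa:10",
    "br:sy001\thsa:11", "br:sy003\thsa:12"
  )))
  ch <- chain_fixture(c("SYMA\tENSG1", "SYMB\tENSG2", "SYMC\tENSG3"))
  tree <- build_hierarchy_tree(cat, links, ch, c("ENSG1", "ENSG2", "ENSG3"))
  # ENSG1 (via hsa:10) is annotated under all three hierarchies
  expect_equal(sum(tree$leaves$gene_id == "ENSG1"), 3L)
  expect_setequal(annotated_gene_set(tree), c("ENSG1", "ENSG2", "ENSG3"))
  # D(root) equals the brute-force count of distinct (gene, hierarchy) pairs
  oracle_pairs <- unique(data.frame(
    g = c("ENSG1", "ENSG1", "ENSG1", "ENSG2", "ENSG3"),
    h = c("sy001", "sy002", "sy003", "sy001", "sy003")
  ))
  d <- leaf_counts(tree)
  expect_equal(d$d[d$level == "root"], nrow(oracle_pairs))
  # universe disjoint from chain
  expect_error(build_hierarchy_tree(cat, links, ch, c("ENSGX")), "no annotated")
  # pruning: a universe covering only sy001/sy002 genes drops Second category
  tree2 <- build_hierarchy_tree(cat, links, ch, c("ENSG2"))
  expect_equal(tree2$categories, "First category")
})

test_that("D-counts are conserved and rebuilds are deterministic", {
  for (seed in 1:3) {
    cfg <- synthetic_config(n_categories = 3, hierarchies_per_category = 3,
                            genes_per_hierarchy = 7,
                            multi_annotation_rate = 0.3, seed = seed)
    tree <- simulate_hierarchy(cfg)
    d <- leaf_counts(tree)
    droot <- d$d[d$level == "root"]
    expect_equal(sum(d$d[d$level == "category"]), droot)
    expect_equal(sum(d$d[d$level == "hierarchy"]), droot)
    expect_equal(droot, nrow(tree$leaves))
    # leaf multiplicity: at least as many leaves as distinct genes
    expect_gte(nrow(tree$leaves), length(annotated_gene_set(tree)))
    # deterministic rebuild
    expect_identical(tree, simulate_hierarchy(cfg))
  }
})

test_that("tree invariants reject malformed input", {
  h <- tibble::tibble(brite_id = "h1", name = "H", category = "c")
  expect_error(gx_tree(h, tibble::tibble(gene_id = character(),
                                         brite_id = character())),
               "no leaves")
  expect_error(gx_tree(h, tibble::tibble(gene_id = c("g", "g"),
                                         brite_id = c("h1", "h1"))),
               "at most once")
  expect_error(gx_tree(h, tibble::tibble(gene_id = "g", brite_id = "h9")),
               "unknown hierarchy")
})
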