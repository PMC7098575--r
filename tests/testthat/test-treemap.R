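test_that("rectangle areas follow the leaf-count area rule", {
  # root with three children of leaf counts (2, 1, 1) on a 4 x 1 canvas
  tree <- gx_tree(
    hierarchies = tibble::tibble(brite_id = c("h1", "h2", "h3"),
                                 name = c("a", "b", "c"),
                                 category = c("c1", "c2", "c3")),
    leaves = tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                            brite_id = c("h1", "h1", "h2", "h3"))
  )
  rects <- layout_tree(tree, 4, 1)
  a <- 4 * 1 / 4
  d <- leaf_counts(tree)
  for (lev in c("root", "category", "hierarchy")) {
    sub <- rects[rects$level == lev, ]
    dd <- d$d[match(sub$node_id, d$node_id)]
    area <- (sub$x1 - sub$x0) * (sub$y1 - sub$y0)
    expect_lt(max(abs(area - dd * a)), 1e-9)
  }
  lf <- rects[rects$level == "leaf", ]
  expect_lt(max(abs((lf$x1 - lf$x0) * (lf$y1 - lf$y0) - a)), 1e-9)
  # category areas are (2, 1, 1)
  cats <- rects[rects$level == "category", ]
  expect_equal((cats$x1 - cats$x0) * (cats$y1 - cats$y0), c(2, 1, 1),
               tolerance = 1e-12)
})

test_that("a four-category tree tiles level 1 into four rectangles", {
  cfg <- synthetic_config(n_categories = 4, hierarchies_per_category = 2,
                          genes_per_hierarchy = 5, multi_annotation_rate = 0)
  tree <- simulate_hierarchy(cfg)
  rects <- layout_tree(tree, 10, 10)
  cats <- rects[rects$level == "category", ]
  expect_equal(nrow(cats), 4L)
  expect_equal(sum((cats$x1 - cats$x0) * (cats$y1 - cats$y0)), 100,
               tolerance = 1e-9)
})

test_that("a single-leaf tree fills the whole canvas", {
  tree <- gx_tree(
    hierarchies = tibble::tibble(brite_id = "h1", name = "a", category = "c1"),
    leaves = tibble::tibble(gene_id = "g1", brite_id = "h1")
  )
  rects <- layout_tree(tree, 7, 3)
  lf <- rects[rects$level == "leaf", ]
  expect_equal(unlist(lf[, c("x0", "y0", "x1", "y1")], use.names = FALSE),
               c(0, 0, 7, 3))
  expect_error(layout_tree(tree, 0, 3), "positive")
})

test_that("area conservation holds at every node of larger trees", {
  for (seed in 1:3) {
    cfg <- synthetic_config(n_categories = 4, hierarchies_per_category = 3,
                            genes_per_hierarchy = 20,
                            multi_annotation_rate = 0.15, seed = seed)
    tree <- simulate_hierarchy(cfg)
    rects <- layout_tree(tree, 64, 64)
    d <- leaf_counts(tree)
    a <- 64 * 64 / nrow(tree$leaves)
    nonleaf <- rects[rects$level != "leaf", ]
    dd <- d$d[match(nonleaf$node_id, d$node_id)]
    area <- (nonleaf$x1 - nonleaf$x0) * (nonleaf$y1 - nonleaf$y0)
    expect_lt(max(abs(area - dd * a)), 1e-9)
    lf <- rects[rects$level == "leaf", ]
    expect_lt(max(abs((lf$x1 - lf$x0) * (lf$y1 - lf$y0) - a)), 1e-9)
    # deterministic: identical inputs give bit-identical layouts
    expect_identical(rects, layout_tree(tree, 64, 64))
  }
})

test_that("genes are sorted by mean expression within each hierarchy", {
  tree <- tiny_tree()
  means <- c(g1 = 5, g2 = 1, g3 = 3, g4 = 2, g5 = 2)
  sorted <- order_genes_within_hierarchy(tree, means)
  h1 <- sorted$leaves$gene_id[sorted$leaves$brite_id == "h1"]
  expect_equal(h1, c("g2", "g1")) # means 1 < 5
  # ties broken by gene id
  h3 <- sorted$leaves$gene_id[sorted$leaves$brite_id == "h3"]
  expect_equal(h3, c("g4", "g5"))
  # hierarchy order untouched
  expect_equal(sorted$hierarchies$brite_id, tree$hierarchies$brite_id)
  expect_error(order_genes_within_hierarchy(tree, means[-1]), "g1")
})

test_that("within-hierarchy ordering matches an independent sort oracle", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:20)
  tree <- gx_tree(
    hierarchies = tibble::tibble(brite_id = "h1", name = "a", category = "c"),
    leaves = tibble::tibble(gene_id = genes, brite_id = "h1")
  )
  means <- stats::setNames(stats::rnorm(20), genes)
  got <- order_genes_within_hierarchy(tree, means)$leaves$gene_id
  oracle <- genes[order(means[genes], genes)]
  expect_equal(got, oracle)
})

test_that("rasterization produces disjoint non-empty integer blocks", {
  # one leaf on a 10 x 10 canvas owns all 100 pixels
  tree1 <- gx_tree(
    hierarchies = tibble::tibble(brite_id = "h1", name = "a", category = "c"),
    leaves = tibble::tibble(gene_id = "g1", brite_id = "h1")
  )
  tpl1 <- rasterize_layout(layout_tree(tree1, 10, 10), 10, 10)
  expect_equal(tpl1$leaves$n_px, 100L)

  # 4-leaf balanced tree on 2 x 2: one pixel each, matching the pixel scan
  tree4 <- gx_tree(
    hierarchies = tibble::tibble(brite_id = c("h1", "h2"), name = c("a", "b"),
                                 category = c("c1", "c2")),
    leaves = tibble::tibble(gene_id = paste0("g", 1:4),
                            brite_id = c("h1", "h1", "h2", "h2"))
  )
  tpl4 <- rasterize_layout(layout_tree(tree4, 2, 2), 2, 2)
  expect_equal(tpl4$leaves$n_px, rep(1L, 4))
  owner <- pixel_owner_oracle(tpl4)
  expect_false(anyNA(owner))
  expect_equal(sort(unique(as.vector(owner))), sort(tpl4$leaves$leaf_id))

  # resolution too low for the tree
  tree_many <- gx_tree(
    hierarchies = tibble::tibble(brite_id = "h1", name = "a", category = "c"),
    leaves = tibble::tibble(gene_id = paste0("g", 1:50), brite_id = "h1")
  )
  expect_error(rasterize_layout(layout_tree(tree_many, 3, 3), 3, 3),
               "resolution")
})

test_that("templates validate cleanly and report corruption", {
  cfg <- synthetic_config(n_categories = 3, hierarchies_per_category = 2,
                          genes_per_hierarchy = 17, multi_annotation_rate = 0.1)
  tree <- simulate_hierarchy(cfg)
  tpl <- rasterize_layout(layout_tree(tree, 32, 32), 32, 32)
  rep <- validate_template(tpl)
  expect_true(rep$disjoint)
  expect_true(rep$all_leaves_nonempty)
  expect_equal(rep$n_leaves, nrow(tree$leaves))
  # rasterized pixel counts stay near the nominal area (rounding bound:
  # at most ~1 pixel along each of the two block sides)
  side <- sqrt(rep$nominal_px)
  expect_lte(rep$max_px - rep$nominal_px, 2 * side + 1)
  # hand-corrupted overlap is reported
  broken <- tpl
  broken$leaves$row0[2] <- broken$leaves$row0[1]
  broken$leaves$row1[2] <- broken$leaves$row1[1]
  broken$leaves$col0[2] <- broken$leaves$col0[1]
  broken$leaves$col1[2] <- broken$leaves$col1[1]
  expect_false(validate_template(broken)$disjoint)
})

test_that("the template depends on tree and means, never on sample values", {
  cfg <- synthetic_config(n_categories = 2, hierarchies_per_category = 2,
                          genes_per_hierarchy = 10, multi_annotation_rate = 0)
  ds1 <- simulate_dataset(cfg)
  means <- mean_expression(ds1$expr)
  tpl_a <- rasterize_layout(
    layout_tree(order_genes_within_hierarchy(ds1$tree, means), 16, 16), 16, 16)
  tpl_b <- rasterize_layout(
    layout_tree(order_genes_within_hierarchy(ds1$tree, means), 16, 16), 16, 16)
  expect_identical(tpl_a, tpl_b)
  expect_identical(tpl_a$fingerprint, tpl_b$fingerprint)
})

test_that("template export writes JSON and TSV", {
  tree <- tiny_tree()
  tpl <- rasterize_layout(layout_tree(tree, 8, 8), 8, 8)
  stem <- withr::local_tempfile()
  paths <- export_template(tpl, stem)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$r, 8)
  expect_equal(js$fingerprint, tpl$fingerprint)
})
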