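test_that("sample rendering writes each gene to all of its pixel blocks", {
  tree <- tiny_tree() # g1 annotated under h1 and h2
  tpl <- rasterize_layout(layout_tree(tree, 12, 12), 12, 12)
  g <- c(g1 = 5, g2 = 1, g3 = 2, g4 = 3, g5 = 4)
  img <- render_sample(g, tpl, background = 0, sample_id = "s1")
  lv <- tpl$leaves[tpl$leaves$gene_id == "g1", ]
  expect_equal(nrow(lv), 2L)
  for (i in 1:2) {
    block <- unclass(img)[(lv$row0[i] + 1):lv$row1[i],
                          (lv$col0[i] + 1):lv$col1[i]]
    expect_true(all(block == 5))
  }
  # identical vectors give identical images
  expect_identical(unclass(render_sample(g, tpl, 0)),
                   unclass(render_sample(g, tpl, 0)))
  expect_error(render_sample(g[-1], tpl), "g1")
})

test_that("every pixel equals the exhaustive pixel-lookup oracle", {
  tree <- gx_tree(
    hierarchies = tibble::tibble(brite_id = c("h1", "h2"), name = c("a", "b"),
                                 category = c("c1", "c1")),
    leaves = tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                            brite_id = c("h1", "h1", "h2", "h2"))
  )
  tpl <- rasterize_layout(layout_tree(tree, 9, 9), 9, 9)
  g <- c(g1 = 1.5, g2 = -2, g3 = 7, g4 = 0.25)
  bg <- -9
  img <- unclass(render_sample(g, tpl, background = bg))
  owner <- pixel_owner_oracle(tpl)
  gene_of <- stats::setNames(tpl$leaves$gene_id, tpl$leaves$leaf_id)
  for (rr in 1:9) for (cc in 1:9) {
    expected <- if (is.na(owner[rr, cc])) bg else unname(g[gene_of[owner[rr, cc]]])
    expect_identical(img[rr, cc], expected)
  }
})

test_that("mean-sorted layout fills the grid row-major in ascending mean", {
  g <- c(g1 = 10, g2 = 20, g3 = 30)
  means <- c(g1 = 3, g2 = 1, g3 = 2)
  img <- unclass(render_mean_sorted(g, means, 2, 2, background = 0))
  expect_equal(img[1, 1], 20) # g2, smallest mean
  expect_equal(img[1, 2], 30) # g3
  expect_equal(img[2, 1], 10) # g1
  expect_equal(img[2, 2], 0)  # background
  # single gene lands top-left
  img1 <- unclass(render_mean_sorted(c(gA = 7), c(gA = 1), 3, 3, 0))
  expect_equal(img1[1, 1], 7)
  expect_equal(sum(img1 != 0), 1L)
  # equal means fall back to gene-id order
  geq <- c(b = 2, a = 1)
  imgeq <- unclass(render_mean_sorted(geq, c(a = 5, b = 5), 1, 2, 0))
  expect_equal(imgeq[1, ], c(1, 2))
  expect_error(render_mean_sorted(g, means, 1, 2), "fit")
})

test_that("random layout uses one seeded permutation shared across samples", {
  g1 <- stats::setNames(1:12, sprintf("g%02d", 1:12))
  g2 <- g1 + 100
  a <- unclass(render_random(g1, seed = 5, r = 4, c = 4, background = 0))
  b <- unclass(render_random(g1, seed = 5, r = 4, c = 4, background = 0))
  expect_identical(a, b)
  # different seeds give a different permutation
  d <- unclass(render_random(g1, seed = 6, r = 4, c = 4, background = 0))
  expect_false(identical(a, d))
  # the same permutation is applied to every sample
  a2 <- unclass(render_random(g2, seed = 5, r = 4, c = 4, background = 0))
  nz <- a != 0
  expect_equal(a2[nz], a[nz] + 100)
  # permutation equals an independent seeded shuffle of the sorted gene ids
  old_seed <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  set.seed(5)
  oracle_order <- sample(sort(names(g1)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  flat <- as.vector(t(a))[1:12] # row-major reading of the grid
  expect_equal(flat, unname(g1[oracle_order]))
})

test_that("lossless export round-trips and PNG scaling hits the endpoints", {
  tree <- tiny_tree()
  tpl <- rasterize_layout(layout_tree(tree, 8, 8), 8, 8)
  x <- gx_matrix(matrix(stats::rnorm(5 * 3), 5, 3,
                        dimnames = list(paste0("g", 1:5), paste0("s", 1:3))))
  imgs <- render_images(x, template = tpl, layout = "G")
  stem <- withr::local_tempfile()
  export_images(imgs, stem, format = "array")
  back <- readRDS(paste0(stem, ".rds"))
  expect_identical(unclass(back), unclass(imgs))
  side <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(side$fingerprint, tpl$fingerprint)

  # PNG: constant image is uniform mid-gray, max value maps to 255
  dirp <- withr::local_tempdir()
  const <- array(3, dim = c(1, 4, 4), dimnames = list("s", NULL, NULL))
  f <- export_images(const, file.path(dirp, "c"), format = "png")
  px <- unique(as.vector(png::readPNG(f[1])))
  expect_length(px, 1)
  expect_equal(px, 0.5, tolerance = 1 / 255)
  ramp <- array(c(0, 1, 2, 3), dim = c(1, 2, 2), dimnames = list("s", NULL, NULL))
  f2 <- export_images(ramp, file.path(dirp, "r"), format = "png")
  expect_equal(max(png::readPNG(f2[1])) * 255, 255)
  expect_equal(min(png::readPNG(f2[1])), 0)

  # mixed shapes abort
  bad <- list(matrix(1, 2, 2), matrix(1, 3, 3))
  expect_error(export_images(bad, stem), "shape")
})

test_that("pixel-to-gene map is constant across samples and splits", {
  cfg <- synthetic_config(n_categories = 2, hierarchies_per_category = 2,
                          genes_per_hierarchy = 8, multi_annotation_rate = 0.2)
  ds <- simulate_dataset(cfg)
  means <- mean_expression(ds$expr)
  tpl <- rasterize_layout(
    layout_tree(order_genes_within_hierarchy(ds$tree, means), 16, 16), 16, 16)
  sub1 <- ds$expr[, 1:5]
  sub2 <- ds$expr[, 6:10]
  i1 <- render_images(sub1, template = tpl, layout = "G", background = 0)
  i2 <- render_images(sub2, template = tpl, layout = "G", background = 0)
  expect_identical(attr(i1, "fingerprint"), attr(i2, "fingerprint"))
  # same gene vector rendered in either batch gives the same image
  g <- unclass(ds$expr)[, 3]
  expect_identical(unclass(render_sample(g, tpl, 0)),
                   unclass(render_sample(g, tpl, 0)))
})
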