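new_gx_image <- function(grid, sample_id, layout_kind, fingerprint) {
  structure(grid, sample_id = sample_id, layout_kind = layout_kind,
            fingerprint = fingerprint, class = c("gx_image", "matrix", "array"))
}

#' @export
print.gx_image <- function(x, ...) {
  cat(sprintf("<gx_image> sample '%s', %d x %d, layout %s\n",
              attr(x, "sample_id"), nrow(x), ncol(x), attr(x, "layout_kind")))
  invisible(x)
}

#' Render one sample's gene-expression image from the template
#'
#' Writes each gene's (continuous) expression value to all of its pixel
#' blocks in the template; a gene annotated under several hierarchies appears
#' at each of its positions. Pixels not covered by any leaf (rounding slack)
#' take the `background` value. Pixel positions are determined entirely by
#' the template and are therefore identical across samples.
#'
#' @param g One sample's expression vector, named by gene id; must cover
#'   every gene in the template.
#' @param template A [rasterize_layout()] result.
#' @param background Value for uncovered pixels; conventionally the global
#'   minimum of the training expression matrix (darkest gray).
#' @param sample_id Optional sample identifier stored on the image.
#' @return A `gx_image`: an r x c numeric matrix with layout metadata.
#' @export
render_sample <- function(g, template, background = min(g),
                          sample_id = NA_character_) {
  stopifnot(inherits(template, "gx_template"))
  lv <- template$leaves
  missing <- setdiff(unique(lv$gene_id), names(g))
  if (length(missing) > 0) {
    stop("expression vector lacks gene(s) present in the template: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  grid <- matrix(background, template$r, template$c)
  vals <- unname(g[lv$gene_id])
  for (i in seq_len(nrow(lv))) {
    grid[(lv$row0[i] + 1):lv$row1[i], (lv$col0[i] + 1):lv$col1[i]] <- vals[i]
  }
  new_gx_image(grid, sample_id, "G", template$fingerprint)
}

# shared helper: fill a grid row-major with one pixel per gene
fill_row_major <- function(g, gene_order, r, c, background, kind, sample_id,
                           fingerprint) {
  n <- length(gene_order)
  if (n > r * c) {
    stop(sprintf("%d genes do not fit on a %d x %d grid", n, r, c),
         call. = FALSE)
  }
  grid <- matrix(background, r, c)
  pos <- seq_len(n) - 1L
  grid[cbind(pos %/% c + 1L, pos %% c + 1L)] <- unname(g[gene_order])
  new_gx_image(grid, sample_id, kind, fingerprint)
}

#' Render the mean-sorted ablation image
#'
#' Arranges genes on the grid purely by their mean expression across all
#' samples, ascending from the top-left to the bottom-right corner, one pixel
#' per gene, ignoring all hierarchy information. Remaining pixels take the
#' background value. This is the layout used to test whether the functional
#' arrangement (rather than mean-expression sorting alone) is what a CNN
#' exploits.
#'
#' @param g One sample's expression vector, named by gene id.
#' @param means Named numeric vector of per-gene means covering `names(g)`.
#' @param r,c Grid dimensions.
#' @param background Value for unused pixels.
#' @param sample_id Optional sample identifier.
#' @return A `gx_image` with `layout_kind = "M"`.
#' @export
render_mean_sorted <- function(g, means, r, c, background = min(g),
                               sample_id = NA_character_) {
  missing <- setdiff(names(g), names(means))
  if (length(missing) > 0) {
    stop("no mean for gene(s): ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  ord <- names(g)[order(unname(means[names(g)]), names(g))]
  fingerprint <- rlang::hash(list("M", r, c, ord))
  fill_row_major(g, ord, r, c, background, "M", sample_id, fingerprint)
}

# one permutation per seed, shared by every sample rendered with that seed
random_gene_order <- function(gene_ids, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample(gene_ids)
}

#' Render the random-arrangement ablation image
#'
#' Places genes on the grid in a completely random order (one fixed
#' permutation per `seed`, shared by all samples), destroying any local
#' structure a convolutional network could exploit.
#'
#' @param g One sample's expression vector, named by gene id.
#' @param seed Integer seed determining the permutation.
#' @param r,c Grid dimensions.
#' @param background Value for unused pixels.
#' @param sample_id Optional sample identifier.
#' @return A `gx_image` with `layout_kind = "R"`.
#' @export
render_random <- function(g, seed, r, c, background = min(g),
                          sample_id = NA_character_) {
  ord <- random_gene_order(sort(names(g)), seed)
  fingerprint <- rlang::hash(list("R", r, c, ord))
  fill_row_major(g, ord, r, c, background, "R", sample_id, fingerprint)
}

#' Render a whole expression matrix to an image stack
#'
#' @param x A [gx_matrix()] (genes x samples).
#' @param template A `gx_template` for `layout = "G"`; ignored otherwise.
#' @param layout `"G"` (hierarchy template), `"M"` (mean-sorted) or `"R"`
#'   (random).
#' @param r,c Grid dimensions for `"M"`/`"R"` layouts.
#' @param means Per-gene means for `"M"` (defaults to [mean_expression()]
#'   of `x`).
#' @param seed Permutation seed for `"R"`.
#' @param background Background value; defaults to the global minimum of `x`.
#' @return A 3-d array `samples x r x c` with sample ids on the first
#'   dimension and attributes `layout_kind` and `fingerprint`.
#' @export
render_images <- function(x, template = NULL, layout = c("G", "M", "R"),
                          r = NULL, c = NULL, means = NULL, seed = 1L,
                          background = min(x)) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "gx_matrix"))
  render_one <- switch(layout,
    G = {
      stopifnot(inherits(template, "gx_template"))
      r <- template$r; c <- template$c
      function(g, id) render_sample(g, template, background, id)
    },
    M = {
      if (is.null(means)) means <- mean_expression(x)
      function(g, id) render_mean_sorted(g, means, r, c, background, id)
    },
    R = function(g, id) render_random(g, seed, r, c, background, id)
  )
  if (layout != "G" && (is.null(r) || is.null(c))) {
    stop("`r` and `c` are required for M/R layouts", call. = FALSE)
  }
  out <- array(NA_real_, dim = c(ncol(x), r, c),
               dimnames = list(colnames(x), NULL, NULL))
  fp <- NA_character_
  xm <- unclass(x)
  for (i in seq_len(ncol(x))) {
    img <- render_one(xm[, i], colnames(x)[i])
    out[i, , ] <- img
    fp <- attr(img, "fingerprint")
  }
  attr(out, "layout_kind") <- layout
  attr(out, "fingerprint") <- fp
  out
}

#' Export images losslessly or as 8-bit PNG
#'
#' `format = "array"` stores the continuous values losslessly (RDS container)
#' with a JSON sidecar recording the layout fingerprint and scaling
#' constants. `format = "png"` writes one 8-bit grayscale PNG per image,
#' min-max scaled with the supplied (training-set) range so that the lighter
#' the gray level, the higher the expression; models should always consume
#' the lossless container, never the quantized PNGs.
#'
#' @param images A list of `gx_image`s or a 3-d array from
#'   [render_images()].
#' @param path Output stem (array) or directory (png).
#' @param format `"array"` or `"png"`.
#' @param scale_range Length-2 numeric range used for PNG scaling; defaults
#'   to the range of the supplied images.
#' @return Invisibly, the written file path(s).
#' @export
export_images <- function(images, path, format = c("array", "png"),
                          scale_range = NULL) {
  format <- match.arg(format)
  if (is.list(images)) {
    shapes <- vapply(images, function(m) paste(dim(m), collapse = "x"), "")
    if (length(unique(shapes)) > 1) {
      stop("all images must share the same shape", call. = FALSE)
    }
    arr <- array(NA_real_, dim = c(length(images), nrow(images[[1]]),
                                   ncol(images[[1]])))
    ids <- vapply(images, function(m) {
      id <- attr(m, "sample_id")
      if (is.null(id)) NA_character_ else id
    }, "")
    for (i in seq_along(images)) arr[i, , ] <- images[[i]]
    dimnames(arr) <- list(ids, NULL, NULL)
    attr(arr, "layout_kind") <- attr(images[[1]], "layout_kind")
    attr(arr, "fingerprint") <- attr(images[[1]], "fingerprint")
    images <- arr
  }
  if (is.null(scale_range)) scale_range <- range(images)
  if (format == "array") {
    rds <- paste0(path, ".rds")
    saveRDS(images, rds)
    jsonlite::write_json(list(
      n = dim(images)[1], r = dim(images)[2], c = dim(images)[3],
      layout_kind = attr(images, "layout_kind"),
      fingerprint = attr(images, "fingerprint"),
      scale_min = scale_range[1], scale_max = scale_range[2],
      sample_ids = dimnames(images)[[1]]
    ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(c(rds, paste0(path, ".json"))))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lo <- scale_range[1]
  hi <- scale_range[2]
  files <- character(dim(images)[1])
  for (i in seq_len(dim(images)[1])) {
    m <- images[i, , ]
    scaled <- if (hi > lo) (m - lo) / (hi - lo) else matrix(0.5, nrow(m), ncol(m))
    scaled[scaled < 0] <- 0
    scaled[scaled > 1] <- 1
    id <- dimnames(images)[[1]][i]
    if (is.null(id) || is.na(id)) id <- sprintf("image_%04d", i)
    files[i] <- file.path(path, paste0(id, ".png"))
    png::writePNG(round(scaled * 255) / 255, files[i])
  }
  invisible(files)
}
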