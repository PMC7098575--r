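# Ordered treemap, pivot-by-size.
#
# Conventions used throughout: continuous canvas coordinates with the origin
# at the top-left corner, x growing to the right (columns) and y growing
# downwards (rows); rectangles are half-open on their high edges. The pivot
# of a sibling list is its largest-size member (ties: first). The list splits
# into (L1, pivot, L2, L3); L1 occupies a strip before the pivot, the pivot
# and L2 share a middle strip (pivot on the top/left), L3 the remaining
# strip. L2 is the prefix of the items after the pivot that makes the pivot's
# rectangle as square as possible. Strips run along the longer side of the
# current rectangle. All splits are proportional to size sums, so every
# rectangle's area equals size/total * parent area exactly (up to floating
# error), and reading order approximately preserves input order.

# rectangles for <= 2 items: proportional slices along the longer side
slice_rects <- function(sizes, x0, y0, x1, y1) {
  n <- length(sizes)
  out <- matrix(NA_real_, n, 4)
  if (n == 1) {
    out[1, ] <- c(x0, y0, x1, y1)
    return(out)
  }
  total <- sum(sizes)
  if ((x1 - x0) >= (y1 - y0)) {
    xm <- x0 + (x1 - x0) * sizes[1] / total
    out[1, ] <- c(x0, y0, xm, y1)
    out[2, ] <- c(xm, y0, x1, y1)
  } else {
    ym <- y0 + (y1 - y0) * sizes[1] / total
    out[1, ] <- c(x0, y0, x1, ym)
    out[2, ] <- c(x0, ym, x1, y1)
  }
  out
}

# ordered layout of n equal-size items as row strips: k rows chosen so cells
# are as square as possible, items spread evenly over rows (order preserved,
# row-major reading), every cell with area exactly (w*h)/n. Used for gene
# leaves, whose weights are all 1; pivot-by-size degenerates there (any item
# is "largest") and tends to leave sub-pixel slivers, while row strips keep
# cells fat enough that each survives rasterization.
equal_strip_rects <- function(n, x0, y0, x1, y1) {
  out <- matrix(NA_real_, n, 4)
  w <- x1 - x0
  h <- y1 - y0
  side <- sqrt(w * h / n)
  k <- max(1L, min(n, as.integer(round(h / side))))
  bounds <- round(seq_len(k) * n / k) # cumulative item counts per row
  bounds <- c(0L, as.integer(bounds))
  i <- 1L
  for (row in seq_len(k)) {
    cnt <- bounds[row + 1] - bounds[row]
    if (cnt == 0) next
    ry0 <- y0 + h * bounds[row] / n
    ry1 <- y0 + h * bounds[row + 1] / n
    xs <- x0 + w * (0:cnt) / cnt
    for (jj in seq_len(cnt)) {
      out[i, ] <- c(xs[jj], ry0, xs[jj + 1], ry1)
      i <- i + 1L
    }
  }
  out
}

# ordered pivot-by-size layout of one sibling list; returns an n x 4 matrix
# (x0, y0, x1, y1) in input order
pivot_rects <- function(sizes, x0, y0, x1, y1) {
  n <- length(sizes)
  if (any(sizes <= 0)) stop("all sizes must be positive", call. = FALSE)
  out <- matrix(NA_real_, n, 4)
  idx <- seq_len(n)
  # the recursion on L3 is a tail call: run it as a loop
  repeat {
    m <- length(idx)
    if (m == 0) break
    if (m <= 2) {
      out[idx, ] <- slice_rects(sizes[idx], x0, y0, x1, y1)
      break
    }
    s <- sizes[idx]
    total <- sum(s)
    w <- x1 - x0
    h <- y1 - y0
    horiz <- w >= h # strips run left-to-right when the rect is wide
    p <- which.max(s)
    s_p <- s[p]
    # L1 strip before the pivot
    if (p > 1) {
      l1 <- idx[seq_len(p - 1)]
      f1 <- sum(s[seq_len(p - 1)]) / total
      if (horiz) {
        xm <- x0 + f1 * w
        out[l1, ] <- pivot_rects(sizes[l1], x0, y0, xm, y1)
        x0 <- xm
        w <- x1 - x0
      } else {
        ym <- y0 + f1 * h
        out[l1, ] <- pivot_rects(sizes[l1], x0, y0, x1, ym)
        y0 <- ym
        h <- y1 - y0
      }
    }
    rest <- idx[seq(p + 1, m)[seq_len(m - p)]]
    if (length(rest) == 0) { # pivot is last: it fills what is left
      out[idx[p], ] <- c(x0, y0, x1, y1)
      break
    }
    s_rest <- sizes[rest]
    # choose |L2| = j so the pivot rectangle is as square as possible; the
    # pivot/L2 split inside the middle strip follows the strip's own longer
    # side (pivot first in reading order either way)
    j_opts <- 0:length(s_rest)
    s_l2 <- c(0, cumsum(s_rest))
    frac_p <- s_p / (s_p + s_l2)
    if (horiz) {
      wm <- w * (s_p + s_l2) / (s_p + sum(s_rest))
      wide_strip <- wm >= h
      pw <- ifelse(wide_strip, wm * frac_p, wm)
      ph <- ifelse(wide_strip, h, h * frac_p)
      aspect <- pmax(pw / ph, ph / pw)
      j <- j_opts[which.min(aspect)]
      wm <- wm[j + 1]
      if (wide_strip[j + 1]) { # pivot left, L2 right within the strip
        wp <- wm * frac_p[j + 1]
        out[idx[p], ] <- c(x0, y0, x0 + wp, y1)
        if (j > 0) {
          l2 <- rest[seq_len(j)]
          out[l2, ] <- pivot_rects(sizes[l2], x0 + wp, y0, x0 + wm, y1)
        }
      } else { # pivot on top, L2 below
        hp <- h * frac_p[j + 1]
        out[idx[p], ] <- c(x0, y0, x0 + wm, y0 + hp)
        if (j > 0) {
          l2 <- rest[seq_len(j)]
          out[l2, ] <- pivot_rects(sizes[l2], x0, y0 + hp, x0 + wm, y1)
        }
      }
      idx <- rest[seq_len(length(rest) - j) + j]
      x0 <- x0 + wm
    } else {
      hm <- h * (s_p + s_l2) / (s_p + sum(s_rest))
      tall_strip <- hm >= w
      pw <- ifelse(tall_strip, w, w * frac_p)
      ph <- ifelse(tall_strip, hm * frac_p, hm)
      aspect <- pmax(pw / ph, ph / pw)
      j <- j_opts[which.min(aspect)]
      hm <- hm[j + 1]
      if (tall_strip[j + 1]) { # pivot on top, L2 below within the strip
        hp <- hm * frac_p[j + 1]
        out[idx[p], ] <- c(x0, y0, x1, y0 + hp)
        if (j > 0) {
          l2 <- rest[seq_len(j)]
          out[l2, ] <- pivot_rects(sizes[l2], x0, y0 + hp, x1, y0 + hm)
        }
      } else { # pivot left, L2 right
        wp <- w * frac_p[j + 1]
        out[idx[p], ] <- c(x0, y0, x0 + wp, y0 + hm)
        if (j > 0) {
          l2 <- rest[seq_len(j)]
          out[l2, ] <- pivot_rects(sizes[l2], x0 + wp, y0, x1, y0 + hm)
        }
      }
      idx <- rest[seq_len(length(rest) - j) + j]
      y0 <- y0 + hm
    }
    if (length(idx) == 0) break
  }
  out
}

#' Lay out a hierarchy tree as nested treemap rectangles
#'
#' Recursively subdivides the canvas level by level: the root rectangle is
#' split into one rectangle per category and each category into its
#' hierarchies with the ordered (pivot-by-size) treemap algorithm; each
#' hierarchy rectangle is then subdivided into its gene leaves with an
#' ordered equal-area row-strip layout (all leaves weigh 1, so pivot choice
#' is degenerate there and row strips keep the cells close to square).
#' Every node's rectangle has area `D(node) * a`, where `D` is
#' the descendant-leaf count and `a = width * height / D(root)` is the
#' common per-leaf area. Sibling order follows the tree's child order, so the
#' reading order of the layout approximately preserves it.
#'
#' @param tree A [gx_tree()] (run [order_genes_within_hierarchy()] first if
#'   gene rectangles should be sorted by mean expression).
#' @param width,height Continuous canvas extents (use the pixel dimensions of
#'   the final image, e.g. 175 x 175).
#' @return A tibble of rectangles with columns `node_id`, `level`
#'   (`root`/`category`/`hierarchy`/`leaf`), `parent`, `gene_id`, `brite_id`,
#'   `x0`, `y0`, `x1`, `y1`. Leaf `node_id`s are `"<brite_id>|<gene_id>"`.
#' @export
layout_tree <- function(tree, width, height) {
  stopifnot(inherits(tree, "gx_tree"))
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    stop("`width` and `height` must be positive", call. = FALSE)
  }
  d <- leaf_counts(tree)
  d_cat <- d$d[d$level == "category"]
  d_h <- stats::setNames(d$d[d$level == "hierarchy"],
                         d$node_id[d$level == "hierarchy"])

  rows <- list()
  rows[[1]] <- tibble::tibble(
    node_id = tree$root, level = "root", parent = NA_character_,
    gene_id = NA_character_, brite_id = NA_character_,
    x0 = 0, y0 = 0, x1 = width, y1 = height
  )
  cat_rects <- pivot_rects(d_cat, 0, 0, width, height)
  rows[[2]] <- tibble::tibble(
    node_id = tree$categories, level = "category", parent = tree$root,
    gene_id = NA_character_, brite_id = NA_character_,
    x0 = cat_rects[, 1], y0 = cat_rects[, 2],
    x1 = cat_rects[, 3], y1 = cat_rects[, 4]
  )
  for (ci in seq_along(tree$categories)) {
    cat_name <- tree$categories[ci]
    hs <- tree$hierarchies[tree$hierarchies$category == cat_name, ]
    cr <- cat_rects[ci, ]
    h_rects <- pivot_rects(unname(d_h[hs$brite_id]), cr[1], cr[2], cr[3], cr[4])
    rows[[length(rows) + 1]] <- tibble::tibble(
      node_id = hs$brite_id, level = "hierarchy", parent = cat_name,
      gene_id = NA_character_, brite_id = hs$brite_id,
      x0 = h_rects[, 1], y0 = h_rects[, 2],
      x1 = h_rects[, 3], y1 = h_rects[, 4]
    )
    for (hi in seq_len(nrow(hs))) {
      genes <- tree$leaves$gene_id[tree$leaves$brite_id == hs$brite_id[hi]]
      hr <- h_rects[hi, ]
      l_rects <- equal_strip_rects(length(genes), hr[1], hr[2], hr[3], hr[4])
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_id = paste0(hs$brite_id[hi], "|", genes),
        level = "leaf", parent = hs$brite_id[hi],
        gene_id = genes, brite_id = hs$brite_id[hi],
        x0 = l_rects[, 1], y0 = l_rects[, 2],
        x1 = l_rects[, 3], y1 = l_rects[, 4]
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Sort gene leaves by mean expression within each hierarchy
#'
#' Reorders the leaves of the tree so that, inside every functional-hierarchy
#' rectangle, genes appear in ascending order of their mean expression across
#' all samples (ties broken by gene id). Category and hierarchy order are
#' untouched; the layout therefore stays sample-independent.
#'
#' @param tree A [gx_tree()].
#' @param means Named numeric vector of per-gene means
#'   (see [mean_expression()]); must cover every leaf gene.
#' @return A `gx_tree` with sorted leaves.
#' @export
order_genes_within_hierarchy <- function(tree, means) {
  stopifnot(inherits(tree, "gx_tree"))
  missing <- setdiff(unique(tree$leaves$gene_id), names(means))
  if (length(missing) > 0) {
    stop("no mean expression value for gene(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  lv <- tree$leaves |>
    dplyr::mutate(
      .h = match(.data$brite_id, tree$hierarchies$brite_id),
      .m = unname(means[.data$gene_id])
    ) |>
    dplyr::arrange(.data$.h, .data$.m, .data$gene_id) |>
    dplyr::select(-".h", -".m")
  gx_tree(tree$hierarchies, lv, root = tree$root)
}

# round half away from zero (coordinates are non-negative here)
round_half_up <- function(x) floor(x + 0.5)

#' Rasterize a continuous layout to an integer pixel template
#'
#' Maps every leaf rectangle to the integer pixel block
#' `[round(y0), round(y1)) x [round(x0), round(x1))` (rows x columns,
#' rounding half away from zero). Because neighbouring rectangles share
#' boundary coordinates exactly, rounding produces neither gaps nor overlaps
#' between blocks; disjointness is nevertheless verified. Every leaf must end
#' up owning at least one pixel, otherwise the resolution is too low for the
#' tree and an error asks for a larger canvas.
#'
#' @param rects Rectangle tibble from [layout_tree()] computed on a canvas of
#'   `width = c`, `height = r`.
#' @param r,c Pixel dimensions of the template (rows, columns).
#' @return An object of class `gx_template`: list with `r`, `c`, `a`
#'   (continuous per-leaf area), `a_px` (nominal pixels per leaf), `rects`,
#'   `leaves` (tibble: `leaf_id`, `gene_id`, `brite_id`, `row0`, `row1`,
#'   `col0`, `col1` half-open, `n_px`) and a layout `fingerprint`.
#' @export
rasterize_layout <- function(rects, r, c) {
  stopifnot(is.data.frame(rects), r >= 1, c >= 1)
  root <- rects[rects$level == "root", ]
  if (nrow(root) != 1 || abs(root$x1 - c) > 1e-6 || abs(root$y1 - r) > 1e-6) {
    stop("`rects` must come from layout_tree(tree, width = c, height = r)",
         call. = FALSE)
  }
  lf <- rects[rects$level == "leaf", ]
  leaves <- tibble::tibble(
    leaf_id = lf$node_id,
    gene_id = lf$gene_id,
    brite_id = lf$brite_id,
    row0 = as.integer(round_half_up(lf$y0)),
    row1 = as.integer(round_half_up(lf$y1)),
    col0 = as.integer(round_half_up(lf$x0)),
    col1 = as.integer(round_half_up(lf$x1))
  )
  leaves$n_px <- (leaves$row1 - leaves$row0) * (leaves$col1 - leaves$col0)
  empty <- leaves$n_px <= 0
  if (any(empty)) {
    stop(sprintf(paste0(
      "%d leaf rectangle(s) collapsed to zero pixels at %d x %d; ",
      "increase the template resolution so that every gene keeps at least ",
      "one pixel"), sum(empty), r, c), call. = FALSE)
  }
  # occupancy check: no pixel may belong to two leaves
  occ <- matrix(0L, r, c)
  for (i in seq_len(nrow(leaves))) {
    rr <- (leaves$row0[i] + 1):leaves$row1[i]
    cc <- (leaves$col0[i] + 1):leaves$col1[i]
    occ[rr, cc] <- occ[rr, cc] + 1L
  }
  if (any(occ > 1L)) {
    stop("internal error: overlapping leaf pixel blocks", call. = FALSE)
  }
  out <- structure(list(
    r = as.integer(r), c = as.integer(c),
    a = (root$x1 - root$x0) * (root$y1 - root$y0) / nrow(leaves),
    a_px = r * c / nrow(leaves),
    rects = rects,
    leaves = leaves,
    fingerprint = NA_character_
  ), class = "gx_template")
  out$fingerprint <- rlang::hash(list(out$r, out$c, leaves))
  out
}

#' @export
print.gx_template <- function(x, ...) {
  cat(sprintf("<gx_template> %d x %d px, %d leaves (%d genes), ~%.2f px/leaf\n",
              x$r, x$c, nrow(x$leaves), dplyr::n_distinct(x$leaves$gene_id),
              x$a_px))
  invisible(x)
}

#' Validate a pixel template
#'
#' Report-only checks of the rasterized template: leaf count, pixel-set size
#' summary, maximum relative deviation of leaf pixel counts from the nominal
#' per-leaf area, pixel disjointness and canvas coverage.
#'
#' @param template A [rasterize_layout()] result.
#' @return A one-row tibble report.
#' @export
validate_template <- function(template) {
  stopifnot(inherits(template, "gx_template"))
  lv <- template$leaves
  occ <- matrix(0L, template$r, template$c)
  for (i in seq_len(nrow(lv))) {
    rr <- (lv$row0[i] + 1):lv$row1[i]
    cc <- (lv$col0[i] + 1):lv$col1[i]
    occ[rr, cc] <- occ[rr, cc] + 1L
  }
  tibble::tibble(
    n_leaves = nrow(lv),
    n_genes = dplyr::n_distinct(lv$gene_id),
    min_px = min(lv$n_px),
    max_px = max(lv$n_px),
    mean_px = mean(lv$n_px),
    nominal_px = template$a_px,
    max_rel_deviation = max(abs(lv$n_px - template$a_px)) / template$a_px,
    all_leaves_nonempty = all(lv$n_px > 0),
    disjoint = !any(occ > 1L),
    covered_px = sum(occ > 0L),
    canvas_px = template$r * template$c
  )
}

#' Export a template layout to JSON and TSV
#'
#' Writes the per-node rectangle coordinates as JSON and the per-leaf pixel
#' blocks as TSV next to it.
#'
#' @param template A `gx_template`.
#' @param path Output path stem; `.json` and `.tsv` are appended.
#' @return Invisibly, the two file paths.
#' @export
export_template <- function(template, path) {
  stopifnot(inherits(template, "gx_template"))
  json_path <- paste0(path, ".json")
  tsv_path <- paste0(path, ".tsv")
  jsonlite::write_json(list(
    r = template$r, c = template$c, a = template$a,
    fingerprint = template$fingerprint,
    rects = template$rects
  ), json_path, auto_unbox = TRUE, digits = NA)
  readr::write_tsv(template$leaves, tsv_path, progress = FALSE)
  invisible(c(json_path, tsv_path))
}
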