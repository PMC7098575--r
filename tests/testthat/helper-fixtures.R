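# shared in-code fixtures; everything is generated at test time

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# small expression matrix with known values
tiny_matrix <- function() {
  gx_matrix(matrix(c(1, 3, 5,
                     2, 2, 2,
                     0, 4, 8), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("s1", "s2", "s3"))))
}

# three-level tree: 2 categories, 3 hierarchies, 6 leaves over 5 genes
tiny_tree <- function() {
  gx_tree(
    hierarchies = tibble::tibble(
      brite_id = c("h1", "h2", "h3"),
      name = paste("Hierarchy", 1:3),
      category = c("catA", "catA", "catB")
    ),
    leaves = tibble::tibble(
      gene_id = c("g1", "g2", "g1", "g3", "g4", "g5"),
      brite_id = c("h1", "h1", "h2", "h2", "h3", "h3")
    )
  )
}

# independent MAD oracle: brute-force median of absolute deviations
mad_oracle <- function(v) {
  med <- sort(v)[ceiling(length(v) / 2)]
  if (length(v) %% 2 == 0) {
    sv <- sort(v)
    med <- (sv[length(v) / 2] + sv[length(v) / 2 + 1]) / 2
  }
  dev <- abs(v - med)
  sd <- sort(dev)
  if (length(dev) %% 2 == 1) sd[(length(dev) + 1) / 2]
  else (sd[length(dev) / 2] + sd[length(dev) / 2 + 1]) / 2
}

# confusion-matrix metric oracle computed by direct arithmetic
metrics_oracle <- function(tp, fp, fn, tn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  acc <- (tp + tn) / (tp + fp + fn + tn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  list(sensitivity = sens, specificity = spec, f_measure = f,
       accuracy = acc, mcc = mcc)
}

# map every canvas pixel to its owning leaf by exhaustive block scan
pixel_owner_oracle <- function(template) {
  owner <- matrix(NA_character_, template$r, template$c)
  lv <- template$leaves
  for (i in seq_len(nrow(lv))) {
    owner[(lv$row0[i] + 1):lv$row1[i], (lv$col0[i] + 1):lv$col1[i]] <-
      lv$leaf_id[i]
  }
  owner
}
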