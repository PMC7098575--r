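#' @keywords internal
strip_kegg_prefix <- function(x) {
  sub("^(br|hsa|ko):", "", trimws(x))
}

strip_html <- function(x) gsub("<[^>]+>", "", x)

#' Parse a KEGG BRITE reference hierarchy file
#'
#' Parses the br08902-style flat-text dialect in which each content line
#' starts with a level letter: `A` marks a top-level section (e.g.
#' "Genes and Proteins"), `B` a functional category, and `C` a functional
#' hierarchy entry of the form `C   br08901  Hierarchy name`. HTML markup
#' (`<b>...</b>`) is stripped. Files without `A` lines are accepted, with `B`
#' lines read as categories directly.
#'
#' @param path Path to a BRITE flat file.
#' @param section If non-NULL, keep only categories under this `A`-level
#'   section (default `"Genes and Proteins"`; ignored when the file has no
#'   `A` lines or the section is absent).
#' @return A tibble (the hierarchy catalogue) with columns `brite_id`, `name`,
#'   `category`, in file order.
#' @export
parse_brite_reference <- function(path, section = "Genes and Proteins") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  cur_section <- NA_character_
  cur_category <- NA_character_
  out <- list()
  has_sections <- any(grepl("^A", lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || grepl("^[#!+]", ln)) next
    level <- substr(ln, 1, 1)
    body <- trimws(strip_html(substr(ln, 2, nchar(ln))))
    if (level == "A") {
      cur_section <- body
      cur_category <- NA_character_
    } else if (level == "B") {
      if (body == "") next
      cur_category <- body
    } else if (level == "C") {
      if (is.na(cur_category)) {
        stop(sprintf("line %d: hierarchy entry before any category", i),
             call. = FALSE)
      }
      m <- regmatches(body, regexec("^(\\S+)\\s+(.*)$", body))[[1]]
      if (length(m) < 3) {
        stop(sprintf("line %d: cannot parse hierarchy entry '%s'", i, body),
             call. = FALSE)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        section = if (has_sections) cur_section else NA_character_,
        brite_id = strip_kegg_prefix(m[2]),
        name = m[3],
        category = cur_category
      )
    } else {
      stop(sprintf("line %d: unknown level marker '%s'", i, level),
           call. = FALSE)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(brite_id = character(), name = character(),
                          category = character()))
  }
  cat <- dplyr::bind_rows(out)
  if (!is.null(section) && has_sections && section %in% cat$section) {
    cat <- dplyr::filter(cat, .data$section == !!section)
  }
  dplyr::select(cat, "brite_id", "name", "category")
}

#' Parse a KEGG link table (BRITE id to KEGG gene id)
#'
#' Two-column TSV as served by the KEGG REST link endpoint; `br:`/`hsa:`
#' prefixes are stripped and duplicate pairs collapsed.
#'
#' @param path Path to a two-column TSV.
#' @return A tibble with columns `brite_id`, `kegg_gene_id`.
#' @export
parse_link_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2)) {
    stop(sprintf("row %d: expected 2 tab-separated columns, found %d",
                 which(nfield != 2)[1], nfield[which(nfield != 2)[1]]),
         call. = FALSE)
  }
  dplyr::distinct(tibble::tibble(
    brite_id = strip_kegg_prefix(vapply(parts, `[[`, "", 1)),
    kegg_gene_id = strip_kegg_prefix(vapply(parts, `[[`, "", 2))
  ))
}

#' Build the identifier-mapping chain KEGG gene <-> HUGO <-> ENSEMBL
#'
#' Composes the two castings needed to connect KEGG human gene ids with the
#' ENSEMBL ids used by Pan-Cancer expression exports: the KEGG gene-list file
#' supplies KEGG id -> HUGO symbol (the symbol is taken as the first
#' comma/semicolon-delimited token of the description field), and the HGNC
#' complete-set table supplies HUGO symbol <-> ENSEMBL gene id. Both
#' relations may be many-to-many and are kept so.
#'
#' @param kegg_list_path KEGG gene-list TSV (id column + free-text
#'   description whose leading token is the symbol).
#' @param hgnc_path HGNC complete-set TSV; must contain `symbol` and
#'   `ensembl_gene_id` columns.
#' @return An object of class `gx_id_chain`: list with tibbles
#'   `kegg_to_hugo` (`kegg_gene_id`, `hugo`), `hugo_to_ensembl` (`hugo`,
#'   `ensembl`) and a `report` of unmapped-symbol counts.
#' @export
build_id_chain <- function(kegg_list_path, hgnc_path) {
  for (p in c(kegg_list_path, hgnc_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  lines <- readLines(kegg_list_path, warn = FALSE)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("KEGG list file rows must have at least 2 tab-separated columns",
         call. = FALSE)
  }
  desc <- vapply(parts, function(p) p[[length(p)]], "")
  symbol <- trimws(vapply(strsplit(desc, "[,;]"), `[[`, "", 1))
  kegg_to_hugo <- dplyr::distinct(tibble::tibble(
    kegg_gene_id = strip_kegg_prefix(vapply(parts, `[[`, "", 1)),
    hugo = symbol
  ))

  hgnc <- readr::read_tsv(hgnc_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("symbol", "ensembl_gene_id") %in% names(hgnc))) {
    stop("HGNC file must contain 'symbol' and 'ensembl_gene_id' columns",
         call. = FALSE)
  }
  hugo_to_ensembl <- hgnc |>
    dplyr::transmute(hugo = .data$symbol, ensembl = .data$ensembl_gene_id) |>
    dplyr::filter(!is.na(.data$ensembl), .data$ensembl != "") |>
    dplyr::distinct()

  unmapped <- setdiff(kegg_to_hugo$hugo, hugo_to_ensembl$hugo)
  structure(list(
    kegg_to_hugo = kegg_to_hugo,
    hugo_to_ensembl = hugo_to_ensembl,
    report = tibble::tibble(
      n_kegg_genes = dplyr::n_distinct(kegg_to_hugo$kegg_gene_id),
      n_symbols = dplyr::n_distinct(kegg_to_hugo$hugo),
      n_symbols_without_ensembl = length(unmapped)
    )
  ), class = "gx_id_chain")
}

#' Hierarchy tree container
#'
#' A `gx_tree` is the rooted functional-hierarchies tree: root
#' ("Genes and Proteins") -> categories -> hierarchies -> gene leaves.
#' A gene may appear as a leaf under several hierarchies, at most once per
#' hierarchy. Child order is the order of the input tibbles and is preserved
#' throughout (deterministic layouts depend on it).
#'
#' @param hierarchies Tibble with columns `brite_id`, `name`, `category`
#'   (categories ordered by first appearance).
#' @param leaves Tibble with columns `gene_id`, `brite_id`.
#' @param root Root label.
#' @return A validated `gx_tree`.
#' @export
gx_tree <- function(hierarchies, leaves, root = "Genes and Proteins") {
  stopifnot(all(c("brite_id", "name", "category") %in% names(hierarchies)),
            all(c("gene_id", "brite_id") %in% names(leaves)))
  if (anyDuplicated(hierarchies$brite_id)) {
    stop("duplicate hierarchy ids in tree", call. = FALSE)
  }
  if (nrow(leaves) == 0) stop("tree has no leaves", call. = FALSE)
  if (!all(leaves$brite_id %in% hierarchies$brite_id)) {
    stop("leaf refers to unknown hierarchy", call. = FALSE)
  }
  if (anyDuplicated(leaves[, c("gene_id", "brite_id")])) {
    stop("a gene may appear at most once per hierarchy", call. = FALSE)
  }
  structure(list(
    root = root,
    categories = unique(hierarchies$category),
    hierarchies = tibble::as_tibble(hierarchies[, c("brite_id", "name", "category")]),
    leaves = tibble::as_tibble(leaves[, c("gene_id", "brite_id")])
  ), class = "gx_tree")
}

#' @export
print.gx_tree <- function(x, ...) {
  cat(sprintf("<gx_tree> '%s': %d categories, %d hierarchies, %d leaves (%d distinct genes)\n",
              x$root, length(x$categories), nrow(x$hierarchies),
              nrow(x$leaves), dplyr::n_distinct(x$leaves$gene_id)))
  invisible(x)
}

#' Descendant-leaf counts of a hierarchy tree
#'
#' Returns D(node), the number of descendant leaves, for the root, every
#' category and every hierarchy node (leaves count 1 each).
#'
#' @param tree A [gx_tree()].
#' @return Tibble with columns `node_id`, `level` (`root`/`category`/
#'   `hierarchy`) and `d`.
#' @export
leaf_counts <- function(tree) {
  stopifnot(inherits(tree, "gx_tree"))
  per_h <- tree$leaves |>
    dplyr::count(.data$brite_id, name = "d")
  h <- tree$hierarchies |>
    dplyr::left_join(per_h, by = "brite_id") |>
    dplyr::mutate(d = dplyr::coalesce(.data$d, 0L))
  cat_d <- h |>
    dplyr::group_by(category = .data$category) |>
    dplyr::summarise(d = sum(.data$d), .groups = "drop")
  cat_d <- cat_d[match(tree$categories, cat_d$category), ]
  dplyr::bind_rows(
    tibble::tibble(node_id = tree$root, level = "root", d = nrow(tree$leaves)),
    tibble::tibble(node_id = cat_d$category, level = "category", d = cat_d$d),
    tibble::tibble(node_id = h$brite_id, level = "hierarchy", d = h$d)
  )
}

#' Build the annotated functional-hierarchies tree
#'
#' Links BRITE functional hierarchies to the genes of an expression matrix by
#' composing catalogue -> link table -> KEGG gene -> HUGO -> ENSEMBL, then
#' pruning: leaves are exactly the (gene, hierarchy) pairs whose ENSEMBL id is
#' in `gene_universe`; hierarchies without mapped genes and categories without
#' hierarchies are removed. Genes reaching the same hierarchy through several
#' KEGG ids collapse to a single leaf.
#'
#' @param catalogue Output of [parse_brite_reference()].
#' @param links Output of [parse_link_table()].
#' @param chain Output of [build_id_chain()].
#' @param gene_universe Character vector of gene ids (e.g. rownames of the
#'   expression matrix).
#' @return A [gx_tree()].
#' @export
build_hierarchy_tree <- function(catalogue, links, chain, gene_universe) {
  stopifnot(inherits(chain, "gx_id_chain"))
  pairs <- links |>
    dplyr::inner_join(chain$kegg_to_hugo, by = "kegg_gene_id") |>
    dplyr::inner_join(chain$hugo_to_ensembl, by = "hugo",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$ensembl %in% gene_universe) |>
    dplyr::distinct(gene_id = .data$ensembl, brite_id = .data$brite_id)
  pairs <- dplyr::semi_join(pairs, catalogue, by = "brite_id")
  if (nrow(pairs) == 0) {
    stop("no annotated genes: the gene universe does not intersect the ",
         "mapping chain", call. = FALSE)
  }
  hier <- dplyr::semi_join(catalogue, pairs, by = "brite_id")
  # leaves ordered by hierarchy catalogue order, then gene id
  pairs <- pairs |>
    dplyr::mutate(.h = match(.data$brite_id, hier$brite_id)) |>
    dplyr::arrange(.data$.h, .data$gene_id) |>
    dplyr::select(-".h")
  gx_tree(hier, pairs)
}

#' Distinct annotated genes of a tree
#'
#' @param tree A [gx_tree()].
#' @return Character vector of distinct gene ids among the leaves; use it to
#'   subset the expression matrix before imaging.
#' @export
annotated_gene_set <- function(tree) {
  stopifnot(inherits(tree, "gx_tree"))
  unique(tree$leaves$gene_id)
}
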