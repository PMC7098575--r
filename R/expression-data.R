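#' Expression matrix container
#'
#' A `gx_matrix` is a numeric genes x samples matrix of log-scale abundance
#' values (typically log2(TPM + 0.001)) with gene identifiers as rownames and
#' sample identifiers as colnames. The constructor validates the container
#' invariants: unique gene and sample identifiers, matching dimensions and
#' finite values.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   `colnames(values)`.
#' @return A validated `gx_matrix`.
#' @examples
#' m <- gx_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:2))))
#' dim(m)
#' @export
gx_matrix <- function(values, gene_ids = rownames(values),
                      sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths must match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 3),
               collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("gx_matrix", class(values))
  values
}

#' @export
print.gx_matrix <- function(x, ...) {
  cat(sprintf("<gx_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

# drop the class when subsetting would break invariants is not a concern;
# keep plain matrix semantics for `[`
#' @export
`[.gx_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("gx_matrix", class(out))
  out
}

#' Read an expression matrix from a tab-separated file
#'
#' Reads a Xena-style TSV export: one identifier column followed by one column
#' per sample (or the transpose with `orientation = "samples-in-rows"`).
#' Gzip-compressed files are accepted. Any non-numeric cell aborts with the
#' offending row and column named.
#'
#' @param path Path to a TSV (optionally .gz).
#' @param orientation `"genes-in-rows"` (default, Xena dialect) or
#'   `"samples-in-rows"`.
#' @return A [gx_matrix()] in genes x samples orientation.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes-in-rows",
                                                   "samples-in-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) < 2) stop("malformed header: need an identifier column plus ",
                          "at least one data column", call. = FALSE)
  ids <- tab[[1]]
  dat <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(dat), dim = dim(dat)))
  bad <- which(is.na(num) & !is.na(dat), arr.ind = TRUE)
  if (nrow(bad) > 0 || anyNA(dat)) {
    if (nrow(bad) == 0) bad <- which(is.na(dat), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(dat)[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(dat))
  if (orientation == "samples-in-rows") num <- t(num)
  gx_matrix(num)
}

#' Read a phenotype table
#'
#' Expects a TSV with columns `sample`, `cohort`, `PFI`, `PFI.time` (the
#' Pan-Cancer survival-export dialect). Missing outcome values are tolerated
#' at load time and flagged; they are rejected only when labels are derived.
#'
#' @param path Path to a TSV.
#' @return A tibble with columns `sample_id`, `cohort`, `pfi_event`,
#'   `pfi_time`.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("sample", "cohort", "PFI", "PFI.time")
  if (!all(need %in% names(tab))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = tab$sample,
    cohort = tab$cohort,
    pfi_event = suppressWarnings(as.integer(tab$PFI)),
    pfi_time = suppressWarnings(as.numeric(tab$`PFI.time`))
  )
  bad_ev <- !is.na(out$pfi_event) & !out$pfi_event %in% c(0L, 1L)
  if (any(bad_ev)) stop("pfi_event must be 0/1; offending sample: ",
                        out$sample_id[which(bad_ev)[1]], call. = FALSE)
  bad_t <- !is.na(out$pfi_time) & out$pfi_time < 0
  if (any(bad_t)) stop("pfi_time must be non-negative; offending sample: ",
                       out$sample_id[which(bad_t)[1]], call. = FALSE)
  out
}

#' Remove genes with constant expression
#'
#' Drops every gene whose expression is identical in all samples (population
#' standard deviation exactly zero). This is the first, unsupervised filtering
#' step applied to the expression matrix before variability ranking.
#'
#' @param x A [gx_matrix()].
#' @return A `gx_matrix` with the constant genes removed; samples unchanged.
#' @export
filter_constant_genes <- function(x) {
  stopifnot(inherits(x, "gx_matrix"))
  xv <- unclass(x)
  keep <- rowSums(abs(xv - xv[, 1])) > 0
  if (!any(keep)) {
    stop("all genes have constant expression across samples", call. = FALSE)
  }
  x[keep, , drop = FALSE]
}

#' Keep the k most variable genes by median absolute deviation
#'
#' Ranks genes by raw MAD, `median(|x - median(x)|)` without consistency
#' scaling, and keeps the `k` largest. Ties at the k-th rank are broken by
#' input order (stable), and the surviving genes keep their input order.
#'
#' @param x A [gx_matrix()].
#' @param k Number of genes to retain (default 20000, the conventional
#'   top-20K cut for Pan-Cancer data).
#' @return A `gx_matrix` with at most `k` genes.
#' @export
select_top_mad <- function(x, k = 20000) {
  stopifnot(inherits(x, "gx_matrix"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  if (k >= nrow(x)) return(x)
  mads <- apply(unclass(x), 1, function(v) stats::median(abs(v - stats::median(v))))
  ord <- order(mads, decreasing = TRUE) # stable: ties keep input order
  keep <- sort(ord[seq_len(k)])
  x[keep, , drop = FALSE]
}

#' Per-gene mean expression
#'
#' Arithmetic mean of each gene across all samples; this vector drives the
#' within-hierarchy ordering of gene rectangles in the template layout.
#'
#' @param x A [gx_matrix()].
#' @return Named numeric vector, one mean per gene.
#' @export
mean_expression <- function(x) {
  stopifnot(inherits(x, "gx_matrix"))
  rowMeans(unclass(x))
}

#' Split samples into base (pre-training) and target (fine-tuning) cohorts
#'
#' Partitions the samples of `x` by cohort label: samples whose cohort is in
#' `target_cohorts` form the target set (e.g. LUAD + LUSC for the lung
#' fine-tuning cohort), all others the base set used for pre-training.
#'
#' @param x A [gx_matrix()].
#' @param pheno Phenotype tibble as returned by [read_phenotype()].
#' @param target_cohorts Character vector of cohort labels.
#' @return A list with `gx_matrix` elements `base` and `target`.
#' @export
split_cohorts <- function(x, pheno, target_cohorts) {
  stopifnot(inherits(x, "gx_matrix"))
  missing <- setdiff(colnames(x), pheno$sample_id)
  if (length(missing) > 0) {
    stop("samples absent from phenotype table: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  cohort <- pheno$cohort[match(colnames(x), pheno$sample_id)]
  is_target <- cohort %in% target_cohorts
  list(
    base = x[, !is_target, drop = FALSE],
    target = x[, is_target, drop = FALSE]
  )
}
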