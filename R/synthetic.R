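#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a small
#' functional-hierarchy tree, cohorts of expression samples whose outcome
#' signal is concentrated in a few hierarchy blocks (the mechanism that makes
#' the hierarchy-driven image layout genuinely informative), and
#' right-censored progression times. Defaults are desk-scale: 4 categories x
#' 4 hierarchies x 30 genes (480 genes), 4 cohorts of 120 samples, a 64 x 64
#' canvas, ~12% events by the 230-day horizon and ~30% censoring.
#'
#' @param n_categories,hierarchies_per_category,genes_per_hierarchy Tree
#'   shape (all >= 1).
#' @param multi_annotation_rate Fraction of genes annotated under a second
#'   hierarchy, in `[0, 1]`.
#' @param n_samples Samples per cohort.
#' @param n_cohorts Number of cohorts (tumor types); all share the signal
#'   mechanism, so transfer from base to target cohorts helps by
#'   construction.
#' @param signal_hierarchies Number of (leading) hierarchies carrying the
#'   outcome effect.
#' @param risk_prevalence Fraction of samples with elevated latent risk.
#' @param effect_size Mean shift (log-expression units) added to signal-
#'   hierarchy genes of high-risk samples.
#' @param noise_sd Per-value Gaussian noise SD (log-expression units).
#' @param baseline_rate Exponential event rate (per day) of low-risk
#'   samples.
#' @param hazard_ratio Rate multiplier for high-risk samples.
#' @param censoring_rate Target fraction of censored samples, in `[0, 1]`.
#' @param horizon Fixed-time horizon in days used downstream.
#' @param canvas Image dimensions `c(r, c)` for rendering.
#' @param seed Integer seed.
#' @return A `gx_synth_config` list.
#' @export
synthetic_config <- function(n_categories = 4, hierarchies_per_category = 4,
                             genes_per_hierarchy = 30,
                             multi_annotation_rate = 0.1,
                             n_samples = 120, n_cohorts = 4,
                             signal_hierarchies = 2, risk_prevalence = 0.3,
                             effect_size = 1, noise_sd = 1,
                             baseline_rate = 3e-4, hazard_ratio = 4,
                             censoring_rate = 0.3, horizon = 230,
                             canvas = c(64, 64), seed = 1L) {
  cfg <- list(
    n_categories = n_categories,
    hierarchies_per_category = hierarchies_per_category,
    genes_per_hierarchy = genes_per_hierarchy,
    multi_annotation_rate = multi_annotation_rate,
    n_samples = n_samples, n_cohorts = n_cohorts,
    signal_hierarchies = signal_hierarchies,
    risk_prevalence = risk_prevalence,
    effect_size = effect_size, noise_sd = noise_sd,
    baseline_rate = baseline_rate, hazard_ratio = hazard_ratio,
    censoring_rate = censoring_rate, horizon = horizon,
    canvas = as.integer(canvas), seed = as.integer(seed)
  )
  counts <- c("n_categories", "hierarchies_per_category",
              "genes_per_hierarchy", "n_samples", "n_cohorts",
              "signal_hierarchies")
  if (any(unlist(cfg[counts]) < 1)) stop("all counts must be >= 1", call. = FALSE)
  rates <- c("multi_annotation_rate", "censoring_rate", "risk_prevalence")
  if (any(unlist(cfg[rates]) < 0 | unlist(cfg[rates]) > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "gx_synth_config")
}

#' Simulate a functional-hierarchy tree
#'
#' Builds a rooted tree shaped like a BRITE functional-hierarchies tree:
#' root -> categories -> hierarchies -> gene leaves, with a
#' `multi_annotation_rate` fraction of genes duplicated into a second,
#' randomly chosen hierarchy (so some genes occupy several template
#' positions, as multiply-annotated genes do).
#'
#' @param cfg A [synthetic_config()].
#' @return A [gx_tree()].
#' @export
simulate_hierarchy <- function(cfg) {
  stopifnot(inherits(cfg, "gx_synth_config"))
  set.seed(cfg$seed)
  n_h <- cfg$n_categories * cfg$hierarchies_per_category
  hier <- tibble::tibble(
    brite_id = sprintf("sh%03d", seq_len(n_h)),
    name = sprintf("Synthetic hierarchy %d", seq_len(n_h)),
    category = rep(sprintf("Category %d", seq_len(cfg$n_categories)),
                   each = cfg$hierarchies_per_category)
  )
  n_g <- n_h * cfg$genes_per_hierarchy
  genes <- sprintf("G%05d", seq_len(n_g))
  leaves <- tibble::tibble(
    gene_id = genes,
    brite_id = rep(hier$brite_id, each = cfg$genes_per_hierarchy)
  )
  dup <- which(stats::runif(n_g) < cfg$multi_annotation_rate)
  if (length(dup) > 0 && n_h > 1) {
    second <- vapply(dup, function(i) {
      sample(setdiff(hier$brite_id, leaves$brite_id[i]), 1)
    }, "")
    leaves <- dplyr::bind_rows(
      leaves, tibble::tibble(gene_id = genes[dup], brite_id = second))
    leaves <- leaves |>
      dplyr::mutate(.h = match(.data$brite_id, hier$brite_id)) |>
      dplyr::arrange(.data$.h, .data$gene_id) |>
      dplyr::select(-".h")
  }
  gx_tree(hier, leaves)
}

#' Simulate expression data with hierarchy-localized outcome signal
#'
#' Draws per-gene baseline means once (giving a non-trivial mean-expression
#' ordering), adds Gaussian noise per (gene, sample), assigns samples to
#' cohorts and to a latent high/low risk state, and shifts all genes of the
#' first `signal_hierarchies` hierarchies upward by `effect_size` in
#' high-risk samples. All cohorts share the same signal mechanism.
#'
#' @param tree A [simulate_hierarchy()] result.
#' @param cfg The same [synthetic_config()].
#' @return List with `expr` ([gx_matrix()]), `risk` (0/1 per sample),
#'   `cohorts` (tibble `sample_id`, `cohort`), `signal_hierarchies`,
#'   `signal_genes`.
#' @export
simulate_expression <- function(tree, cfg) {
  stopifnot(inherits(tree, "gx_tree"), inherits(cfg, "gx_synth_config"))
  set.seed(cfg$seed + 1L)
  genes <- annotated_gene_set(tree)
  n_g <- length(genes)
  n <- cfg$n_samples * cfg$n_cohorts
  sample_ids <- sprintf("S%05d", seq_len(n))
  cohort <- rep(sprintf("C%02d", seq_len(cfg$n_cohorts)), each = cfg$n_samples)
  baseline <- stats::rnorm(n_g, mean = 6, sd = 2)
  values <- baseline + matrix(stats::rnorm(n_g * n, sd = cfg$noise_sd), n_g, n)
  risk <- stats::rbinom(n, 1, cfg$risk_prevalence)
  sig_h <- tree$hierarchies$brite_id[seq_len(min(cfg$signal_hierarchies,
                                                 nrow(tree$hierarchies)))]
  sig_genes <- unique(tree$leaves$gene_id[tree$leaves$brite_id %in% sig_h])
  values[genes %in% sig_genes, risk == 1] <-
    values[genes %in% sig_genes, risk == 1] + cfg$effect_size
  dimnames(values) <- list(genes, sample_ids)
  list(
    expr = gx_matrix(values),
    risk = stats::setNames(risk, sample_ids),
    cohorts = tibble::tibble(sample_id = sample_ids, cohort = cohort),
    signal_hierarchies = sig_h,
    signal_genes = sig_genes
  )
}

# uniform-censoring upper bound achieving the target censoring fraction
censoring_bound <- function(cfg) {
  rates <- cfg$baseline_rate * c(1, cfg$hazard_ratio)
  wts <- c(1 - cfg$risk_prevalence, cfg$risk_prevalence)
  frac <- function(M) sum(wts * (1 - exp(-rates * M)) / (rates * M))
  stats::uniroot(function(M) frac(M) - cfg$censoring_rate,
                 lower = 1, upper = 1e8, tol = 1e-6)$root
}

#' Simulate right-censored progression outcomes
#'
#' Event times are exponential with rate `baseline_rate` for low-risk and
#' `baseline_rate * hazard_ratio` for high-risk samples; censoring times are
#' independent Uniform(0, M) with M chosen analytically so the expected
#' censored fraction equals `censoring_rate` (no censoring when the rate is
#' 0). Binarizing the result at the configured horizon recovers labels
#' correlated with the latent risk.
#'
#' @param risk Named 0/1 vector from [simulate_expression()].
#' @param cfg The same [synthetic_config()].
#' @param cohorts Optional tibble (`sample_id`, `cohort`) carried through.
#' @return Phenotype tibble: `sample_id`, `cohort`, `pfi_event`, `pfi_time`.
#' @export
simulate_survival <- function(risk, cfg, cohorts = NULL) {
  stopifnot(inherits(cfg, "gx_synth_config"))
  set.seed(cfg$seed + 2L)
  n <- length(risk)
  rate <- cfg$baseline_rate * cfg$hazard_ratio^risk
  event_time <- stats::rexp(n, rate)
  if (cfg$censoring_rate > 0) {
    cens_time <- stats::runif(n, 0, censoring_bound(cfg))
  } else {
    cens_time <- rep(Inf, n)
  }
  observed <- pmin(event_time, cens_time)
  ids <- names(risk)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
  tibble::tibble(
    sample_id = ids,
    cohort = if (is.null(cohorts)) NA_character_ else
      cohorts$cohort[match(ids, cohorts$sample_id)],
    pfi_event = as.integer(event_time <= cens_time),
    pfi_time = observed
  )
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_hierarchy()],
#' [simulate_expression()] and [simulate_survival()] under one
#' configuration.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `tree`, `expr`, `risk`, `cohorts`, `pheno`,
#'   `signal_hierarchies`, `signal_genes` and the `cfg` itself.
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  tree <- simulate_hierarchy(cfg)
  ex <- simulate_expression(tree, cfg)
  pheno <- simulate_survival(ex$risk, cfg, ex$cohorts)
  list(tree = tree, expr = ex$expr, risk = ex$risk, cohorts = ex$cohorts,
       pheno = pheno, signal_hierarchies = ex$signal_hierarchies,
       signal_genes = ex$signal_genes, cfg = cfg)
}

#' Write a simulated dataset in the same dialects the readers consume
#'
#' Emits an expression TSV (identifier column + one column per sample), a
#' phenotype TSV (`sample`, `cohort`, `PFI`, `PFI.time`), a BRITE-style
#' flat file and the accompanying link/list/HGNC-style mapping tables, so
#' that fixtures and real downloads are interchangeable end to end.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named vector of the file paths written.
#' @export
write_simulated_files <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    brite = file.path(dir, "brite.keg"),
    link = file.path(dir, "link.tsv"),
    list = file.path(dir, "list.tsv"),
    hgnc = file.path(dir, "hgnc.tsv")
  )
  expr_tab <- tibble::as_tibble(unclass(ds$expr), rownames = "gene")
  readr::write_tsv(expr_tab, paths["expression"], progress = FALSE)
  readr::write_tsv(
    tibble::tibble(sample = ds$pheno$sample_id, cohort = ds$pheno$cohort,
                   PFI = ds$pheno$pfi_event, `PFI.time` = ds$pheno$pfi_time),
    paths["phenotype"], progress = FALSE)

  tree <- ds$tree
  lines <- c(paste0("A<b>", tree$root, "</b>"))
  for (cat_name in tree$categories) {
    lines <- c(lines, paste0("B  ", cat_name))
    hs <- tree$hierarchies[tree$hierarchies$category == cat_name, ]
    lines <- c(lines, sprintf("C    %s  %s", hs$brite_id, hs$name))
  }
  writeLines(lines, paths["brite"])

  genes <- annotated_gene_set(tree)
  kegg_id <- stats::setNames(sprintf("%d", 1000L + seq_along(genes)), genes)
  link <- sprintf("br:%s\thsa:%s", tree$leaves$brite_id,
                  kegg_id[tree$leaves$gene_id])
  writeLines(unique(link), paths["link"])
  writeLines(sprintf("hsa:%s\tSYM%s, alias%s; synthetic gene", kegg_id[genes],
                     genes, genes), paths["list"])
  readr::write_tsv(
    tibble::tibble(hgnc_id = sprintf("HGNC:%d", seq_along(genes)),
                   symbol = paste0("SYM", genes),
                   ensembl_gene_id = genes),
    paths["hgnc"], progress = FALSE)
  invisible(paths)
}
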