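#' Restrict a hierarchy tree to a gene universe
#'
#' Keeps only leaves whose gene is in `universe`, pruning hierarchies and
#' categories left empty. Used to re-align a tree with an expression matrix
#' after gene filtering.
#'
#' @param tree A [gx_tree()].
#' @param universe Character vector of gene ids.
#' @return A pruned `gx_tree`.
#' @export
prune_tree <- function(tree, universe) {
  stopifnot(inherits(tree, "gx_tree"))
  lv <- tree$leaves[tree$leaves$gene_id %in% universe, ]
  if (nrow(lv) == 0) stop("no annotated genes left after pruning", call. = FALSE)
  hs <- tree$hierarchies[tree$hierarchies$brite_id %in% lv$brite_id, ]
  gx_tree(hs, lv, root = tree$root)
}

# per-feature standardization fitted on training data
std_fit <- function(x) {
  if (length(dim(x)) == 3) {
    mu <- apply(x, c(2, 3), mean)
    sd <- apply(x, c(2, 3), stats::sd)
  } else {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
  }
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

std_apply <- function(x, st) {
  if (length(dim(x)) == 3) {
    for (i in seq_len(dim(x)[1])) x[i, , ] <- (x[i, , ] - st$mu) / st$sd
    x
  } else {
    sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
  }
}

#' Transfer-learning pipeline for repeated cross-validation
#'
#' Wraps [pretrain_finetune()] as a pipeline usable with [repeated_cv()]:
#' per training fold, features are standardized with training-fold
#' statistics (applied identically to the base set and the validation
#' fold), the model is pre-trained on the base set and fine-tuned on the
#' fold, and probabilities for the training and validation folds are
#' returned.
#'
#' @param spec A [model_spec()].
#' @param base_x,base_y Base-set features and labels (pre-training data).
#' @return A function `(x_train, y_train, x_val, seed)` for
#'   [repeated_cv()].
#' @export
tl_cv_pipeline <- function(spec, base_x, base_y) {
  force(spec); force(base_x); force(base_y)
  function(x_tr, y_tr, x_val, seed) {
    st <- std_fit(x_tr)
    sp <- spec
    sp$seed <- as.integer(seed %% .Machine$integer.max)
    model <- pretrain_finetune(sp, std_apply(base_x, st), base_y,
                               std_apply(x_tr, st), y_tr)
    list(val_scores = stats::predict(model, std_apply(x_val, st)),
         train_scores = stats::predict(model, std_apply(x_tr, st)))
  }
}

#' Fine-tuning-only pipeline (no pre-training)
#'
#' Ablation counterpart of [tl_cv_pipeline()]: identical architecture and
#' fine-tuning phase, but weights start from random initialization instead
#' of base-set pre-training.
#'
#' @inheritParams tl_cv_pipeline
#' @return A pipeline function for [repeated_cv()].
#' @export
finetune_only_pipeline <- function(spec) {
  force(spec)
  function(x_tr, y_tr, x_val, seed) {
    st <- std_fit(x_tr)
    sp <- spec
    sp$seed <- as.integer(seed %% .Machine$integer.max)
    model <- if (sp$kind == "cnn") build_cnn(sp, dim(x_tr)[-1])
             else build_mlnn(sp, ncol(x_tr))
    os <- random_oversample(std_apply(x_tr, st), y_tr, seed = sp$seed + 1L)
    model <- fit_model(model, os$features, os$labels, sp$epochs_finetune,
                       sp$lr_finetune, sp$batch_finetune, seed = sp$seed + 2L)
    list(val_scores = stats::predict(model, std_apply(x_val, st)),
         train_scores = stats::predict(model, std_apply(x_tr, st)))
  }
}

#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: either file paths
#' (expression, phenotype and the BRITE/link/list/HGNC mapping files) or a
#' synthetic-data configuration, plus the horizon, canvas, layout kind, CV
#' scheme, model specification and seed.
#'
#' @param synth A [synthetic_config()], or NULL when `paths` are given.
#' @param paths Named list of file paths (`expression`, `phenotype`,
#'   `brite`, `link`, `list`, `hgnc`), or NULL when simulating.
#' @param target_cohorts Cohort labels forming the fine-tuning target set;
#'   defaults to the first simulated cohort (`"C01"`).
#' @param t Fixed horizon in days.
#' @param k_top Top-MAD gene count retained during preprocessing.
#' @param canvas `c(r, c)` image dimensions.
#' @param layout `"G"`, `"M"` or `"R"`.
#' @param repeats,folds CV scheme.
#' @param spec A [model_spec()].
#' @param seed Master seed.
#' @param out_dir Optional output directory for artifacts.
#' @return A `gx_run_config` list.
#' @export
run_config <- function(synth = synthetic_config(), paths = NULL,
                       target_cohorts = "C01", t = 230, k_top = 20000,
                       canvas = c(64, 64), layout = "G",
                       repeats = 2, folds = 3,
                       spec = model_spec("cnn", epochs_pretrain = 3,
                                         epochs_finetune = 3),
                       seed = 1L, out_dir = NULL) {
  if (is.null(synth) && is.null(paths)) {
    stop("either `synth` or `paths` must be provided", call. = FALSE)
  }
  if (!is.null(paths)) {
    need <- c("expression", "phenotype", "brite", "link", "list", "hgnc")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0) {
      stop("`paths` lacks: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    absent <- !vapply(paths[need], file.exists, logical(1))
    if (any(absent)) {
      stop("missing file(s): ", paste(unlist(paths[need][absent]),
                                      collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    synth = synth, paths = paths, target_cohorts = target_cohorts,
    t = t, k_top = k_top, canvas = as.integer(canvas), layout = layout,
    repeats = repeats, folds = folds, spec = spec, seed = as.integer(seed),
    out_dir = out_dir
  ), class = "gx_run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes preprocess -> hierarchy tree -> template layout -> image
#' rendering -> fixed-time labelling -> transfer-learning evaluation in
#' order, returning every artifact with a provenance record (configuration
#' hash, seeds, package version, template fingerprint). With `out_dir` set,
#' the template (JSON/TSV), labels (TSV), CV metrics (TSV) and provenance
#' (JSON) are also written to disk.
#'
#' @param cfg A [run_config()].
#' @return List with `expr`, `tree`, `template`, `template_report`,
#'   `labels`, `label_report`, `cv`, `cv_summary` and `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "gx_run_config"))
  if (!is.null(cfg$paths)) {
    expr <- run_stage("ingest", read_expression_matrix(cfg$paths$expression))
    pheno <- run_stage("ingest", read_phenotype(cfg$paths$phenotype))
    expr <- run_stage("preprocess",
                      select_top_mad(filter_constant_genes(expr), cfg$k_top))
    tree <- run_stage("tree", {
      catalogue <- parse_brite_reference(cfg$paths$brite)
      links <- parse_link_table(cfg$paths$link)
      chain <- build_id_chain(cfg$paths$list, cfg$paths$hgnc)
      build_hierarchy_tree(catalogue, links, chain, rownames(expr))
    })
  } else {
    ds <- run_stage("simulate", simulate_dataset(cfg$synth))
    pheno <- ds$pheno
    expr <- run_stage("preprocess",
                      select_top_mad(filter_constant_genes(ds$expr), cfg$k_top))
    tree <- run_stage("tree", prune_tree(ds$tree, rownames(expr)))
  }
  expr <- expr[annotated_gene_set(tree), , drop = FALSE]
  means <- mean_expression(expr)
  r <- cfg$canvas[1]
  cc <- cfg$canvas[2]
  template <- run_stage("layout", {
    rects <- layout_tree(order_genes_within_hierarchy(tree, means), cc, r)
    rasterize_layout(rects, r, cc)
  })
  report <- validate_template(template)

  lab <- run_stage("label", label_dataset(pheno, cfg$t))
  retained <- lab$labels |> dplyr::filter(!is.na(.data$label))
  keep <- intersect(colnames(expr), retained$sample_id)
  expr_used <- expr[, keep, drop = FALSE]
  y <- retained$label[match(keep, retained$sample_id)]
  cohort <- retained$cohort[match(keep, retained$sample_id)]

  images <- run_stage("render", render_images(
    expr_used, template = template, layout = cfg$layout,
    r = r, c = cc, means = means, seed = cfg$seed,
    background = min(expr_used)))

  is_target <- cohort %in% cfg$target_cohorts
  if (!any(is_target) || all(is_target)) {
    stop("pipeline stage 'split' failed: target cohorts must be a proper, ",
         "non-empty subset of the samples", call. = FALSE)
  }
  cv <- run_stage("evaluate", {
    pipe <- if (cfg$spec$kind == "cnn") {
      tl_cv_pipeline(cfg$spec, images[!is_target, , , drop = FALSE],
                     y[!is_target])
    } else {
      tl_cv_pipeline(cfg$spec, t(unclass(expr_used))[!is_target, , drop = FALSE],
                     y[!is_target])
    }
    x_target <- if (cfg$spec$kind == "cnn") {
      images[is_target, , , drop = FALSE]
    } else {
      t(unclass(expr_used))[is_target, , drop = FALSE]
    }
    repeated_cv(x_target, y[is_target], pipe,
                repeats = cfg$repeats, folds = cfg$folds, seed = cfg$seed)
  })

  provenance <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    template_fingerprint = template$fingerprint,
    package_version = as.character(utils::packageVersion("gximage")),
    r_version = R.version.string
  )
  out <- list(expr = expr, tree = tree, template = template,
              template_report = report, labels = lab$labels,
              label_report = lab$report, cv = cv,
              cv_summary = glance(cv), provenance = provenance)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_template(template, file.path(cfg$out_dir, "template"))
    readr::write_tsv(lab$labels, file.path(cfg$out_dir, "labels.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(cv), file.path(cfg$out_dir, "cv.tsv"),
                     progress = FALSE)
    jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out
}
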