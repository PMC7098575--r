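test_that("simulated trees have the configured shape", {
  cfg <- synthetic_config(n_categories = 4, hierarchies_per_category = 11,
                          genes_per_hierarchy = 12, multi_annotation_rate = 0)
  tree <- simulate_hierarchy(cfg)
  expect_equal(length(tree$categories), 4L)
  expect_equal(nrow(tree$hierarchies), 44L)
  # no multi-annotation: leaf count equals the gene count
  expect_equal(nrow(tree$leaves), length(annotated_gene_set(tree)))
})

test_that("leaf count grows with the multi-annotation rate as expected", {
  rate <- 0.25
  n_genes <- 4 * 4 * 10
  extra <- sapply(1:30, function(s) {
    cfg <- synthetic_config(n_categories = 4, hierarchies_per_category = 4,
                            genes_per_hierarchy = 10,
                            multi_annotation_rate = rate, seed = s)
    nrow(simulate_hierarchy(cfg)$leaves) - n_genes
  })
  # binomial mean n * rate with SE sqrt(n p (1-p) / 30)
  se <- sqrt(n_genes * rate * (1 - rate) / 30)
  expect_lt(abs(mean(extra) - n_genes * rate), 4 * se)
})

test_that("expression simulation is reproducible and block-structured", {
  cfg <- synthetic_config(n_categories = 2, hierarchies_per_category = 2,
                          genes_per_hierarchy = 10, n_samples = 30,
                          n_cohorts = 2, effect_size = 2)
  tree <- simulate_hierarchy(cfg)
  ex1 <- simulate_expression(tree, cfg)
  ex2 <- simulate_expression(tree, cfg)
  expect_identical(unclass(ex1$expr), unclass(ex2$expr))
  # signal genes are exactly the genes of the signal hierarchies
  expect_setequal(
    ex1$signal_genes,
    unique(tree$leaves$gene_id[tree$leaves$brite_id %in%
                                 ex1$signal_hierarchies]))
  # high-risk samples have elevated signal-gene means
  sig <- rownames(ex1$expr) %in% ex1$signal_genes
  gap <- mean(unclass(ex1$expr)[sig, ex1$risk == 1]) -
    mean(unclass(ex1$expr)[sig, ex1$risk == 0])
  expect_gt(gap, 1) # effect_size 2 with noise
})

test_that("a zero effect size carries no class signal", {
  aucs <- sapply(1:20, function(s) {
    cfg <- synthetic_config(n_categories = 2, hierarchies_per_category = 2,
                            genes_per_hierarchy = 10, n_samples = 40,
                            n_cohorts = 2, effect_size = 0, seed = s)
    ds <- simulate_dataset(cfg)
    x <- t(unclass(ds$expr))
    y <- ds$risk
    # single split, ANOVA + logistic; split RNG decoupled from the data seed
    set.seed(5000 + s)
    tr <- sample(nrow(x), 50)
    te <- setdiff(seq_len(nrow(x)), tr)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) return(NA)
    red <- gximage:::fit_reducer("anova-k-best", x[tr, ], y[tr], 5, 5)
    fit <- suppressWarnings(stats::glm.fit(cbind(1, red$transform(x[tr, ])),
                                           y[tr],
                                           family = stats::binomial()))
    sc <- cbind(1, red$transform(x[te, ])) %*% fit$coefficients
    gximage:::auc_rank(as.vector(sc), y[te])
  })
  # 20 seeds with per-split AUC sd ~0.13: tolerance ~3 standard errors
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.1)
})

test_that("a strong effect is nearly perfectly separable", {
  cfg <- synthetic_config(n_categories = 2, hierarchies_per_category = 2,
                          genes_per_hierarchy = 10, n_samples = 60,
                          n_cohorts = 2, effect_size = 5, noise_sd = 1)
  ds <- simulate_dataset(cfg)
  x <- t(unclass(ds$expr))
  y <- ds$risk
  cv <- run_ml_baseline("anova-k-best", "lr", x, y, repeats = 1, folds = 3,
                        seed = 2, n_features = 10, smote_k = 3)
  expect_gt(mean(cv$auc), 0.95)
})

test_that("survival simulation matches its closed-form properties", {
  cfg <- synthetic_config(n_samples = 500, n_cohorts = 1,
                          censoring_rate = 0, seed = 3)
  risk <- stats::setNames(rep(c(0L, 1L), each = 250), sprintf("s%d", 1:500))
  ph <- simulate_survival(risk, cfg)
  # no censoring: every event observed
  expect_true(all(ph$pfi_event == 1))
  # median event times near log(2)/rate for each risk group
  med0 <- stats::median(ph$pfi_time[risk == 0])
  med1 <- stats::median(ph$pfi_time[risk == 1])
  expect_lt(med1, med0)
  expect_lt(abs(med0 - log(2) / cfg$baseline_rate) /
              (log(2) / cfg$baseline_rate), 0.25)
  expect_lt(abs(med1 - log(2) / (cfg$baseline_rate * cfg$hazard_ratio)) /
              (log(2) / (cfg$baseline_rate * cfg$hazard_ratio)), 0.25)
})

test_that("the positive fraction after binarization matches the analytic value", {
  cfg <- synthetic_config()
  # analytic P(event observed before t): event time T ~ Exp(rate),
  # censoring C ~ U(0, M); positive <=> T < min(t, C)
  M <- gximage:::censoring_bound(cfg)
  t <- cfg$horizon
  p_pos_given_rate <- function(lam) {
    f <- function(u) lam * exp(-lam * u) * (1 - u / M)
    stats::integrate(f, 0, t)$value
  }
  p_neg_given_rate <- function(lam) exp(-lam * t) * (1 - t / M)
  lam <- cfg$baseline_rate * c(1, cfg$hazard_ratio)
  w <- c(1 - cfg$risk_prevalence, cfg$risk_prevalence)
  p_pos <- sum(w * sapply(lam, p_pos_given_rate))
  p_neg <- sum(w * sapply(lam, p_neg_given_rate))
  analytic <- p_pos / (p_pos + p_neg)
  fracs <- sapply(1:25, function(s) {
    cfg_s <- synthetic_config(seed = s)
    ds <- simulate_dataset(cfg_s)
    label_dataset(ds$pheno, cfg_s$horizon)$report$positive_fraction
  })
  expect_lt(abs(mean(fracs) - analytic), 0.03)
})

test_that("ANOVA ranking recovers most signal genes at moderate effect", {
  hits <- sapply(1:5, function(s) {
    cfg <- synthetic_config(n_samples = 100, n_cohorts = 4,
                            effect_size = 2, noise_sd = 1, seed = s)
    ds <- simulate_dataset(cfg)
    x <- t(unclass(ds$expr))
    f <- gximage:::anova_f_scores(x, ds$risk)
    top <- colnames(x)[order(f, decreasing = TRUE)[seq_along(ds$signal_genes)]]
    mean(ds$signal_genes %in% top)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("simulated files round-trip through the package readers", {
  cfg <- synthetic_config(n_categories = 2, hierarchies_per_category = 2,
                          genes_per_hierarchy = 6, n_samples = 10,
                          n_cohorts = 2, multi_annotation_rate = 0.2)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulated_files(ds, dir)
  x <- read_expression_matrix(paths["expression"])
  expect_equal(unclass(x), unclass(ds$expr))
  ph <- read_phenotype(paths["phenotype"])
  expect_equal(ph$pfi_event, ds$pheno$pfi_event)
  cat <- parse_brite_reference(paths["brite"])
  links <- parse_link_table(paths["link"])
  chain <- build_id_chain(paths["list"], paths["hgnc"])
  tree <- build_hierarchy_tree(cat, links, chain, rownames(x))
  # the reconstructed tree matches the simulated one leaf for leaf
  expect_equal(dplyr::arrange(tree$leaves, gene_id, brite_id),
               dplyr::arrange(ds$tree$leaves, gene_id, brite_id))
})
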