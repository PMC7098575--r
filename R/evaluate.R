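#' ROC threshold balancing sensitivity and specificity
#'
#' Returns the score cut-off maximizing Youden's J = sensitivity +
#' specificity - 1 (samples scoring at or above the threshold are called
#' positive). Among tied maxima the lowest threshold is returned.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return A single threshold value.
#' @export
roc_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to choose a threshold", call. = FALSE)
  }
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, numeric(1))
  cand[which.max(j)] # which.max returns the first (lowest) maximiser
}

# rank-based AUC (equals the trapezoidal ROC area; midranks handle ties)
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-based classification metrics plus AUC
#'
#' AUC is computed threshold-free by the rank (Wilcoxon) definition; the
#' remaining measures come from the confusion matrix at `threshold`
#' (positive when `score >= threshold`). MCC is defined as 0 whenever a
#' denominator factor vanishes; the F-measure is 0 when precision and
#' sensitivity are both undefined or zero.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold.
#' @return One-row tibble with `auc`, `sensitivity`, `specificity`,
#'   `f_measure`, `accuracy`, `mcc`, `threshold`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (!is.na(sens) && (prec + sens) > 0) 2 * prec * sens / (prec + sens) else 0
  acc <- (tp + tn) / length(labels)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  tibble::tibble(
    auc = auc_rank(scores, labels),
    sensitivity = sens, specificity = spec, f_measure = f,
    accuracy = acc, mcc = mcc, threshold = threshold
  )
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < folds) {
      stop(sprintf("class %s has %d members, fewer than %d folds",
                   cls, length(idx), folds), call. = FALSE)
    }
    assignment[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Repeated stratified k-fold cross-validation
#'
#' Evaluates a modelling pipeline under an R-repeated F-fold stratified CV
#' scheme (the conventional setting is 10 repeats of 5 folds, i.e. 50
#' validation records). Everything that is fitted — the model, any
#' oversampling or feature reduction inside `pipeline`, and the decision
#' threshold — sees training folds only; validation folds are scored once.
#'
#' @param x Features: `samples x features` matrix or `samples x r x c`
#'   image array.
#' @param y Binary labels (0/1).
#' @param pipeline Function `(x_train, y_train, x_val, seed)` returning a
#'   list with numeric `val_scores` and `train_scores`.
#' @param repeats,folds CV scheme (both >= 1).
#' @param seed Integer seed driving fold assignment and the per-fold
#'   pipeline seeds.
#' @param threshold_on `"train"` (default; threshold chosen on training-fold
#'   scores, avoiding validation leakage) or `"validation"`.
#' @return A `gx_cv` tibble with one row per (repeat, fold) and metric
#'   columns; provenance (seed, scheme) is stored in attributes.
#' @export
repeated_cv <- function(x, y, pipeline, repeats = 10, folds = 5, seed = 1L,
                        threshold_on = c("train", "validation")) {
  threshold_on <- match.arg(threshold_on)
  stopifnot(repeats >= 1, folds >= 1)
  y <- as.integer(y)
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  stopifnot(length(y) == n)
  take <- function(idx) {
    if (length(dim(x)) == 3) x[idx, , , drop = FALSE] else x[idx, , drop = FALSE]
  }
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    set.seed(seed + rep_i * 1000L)
    fold_of <- stratified_folds(y, folds)
    for (fold_i in seq_len(folds)) {
      val <- which(fold_of == fold_i)
      tr <- which(fold_of != fold_i)
      res <- pipeline(take(tr), y[tr], take(val),
                      seed = seed + rep_i * 1000L + fold_i)
      th <- if (threshold_on == "train") {
        roc_threshold(res$train_scores, y[tr])
      } else {
        roc_threshold(res$val_scores, y[val])
      }
      m <- classification_metrics(res$val_scores, y[val], th)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_i = rep_i, fold = fold_i,
                       n_train = length(tr), n_val = length(val)), m)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "repeats") <- repeats
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  attr(out, "threshold_on") <- threshold_on
  class(out) <- c("gx_cv", class(out))
  out
}

#' Paired Wilcoxon comparison of CV results with Hochberg correction
#'
#' Compares a reference model's fold-wise AUC vector against each competitor
#' with a one-sided paired Wilcoxon signed-rank test (alternative: the
#' reference is greater), then applies the Hochberg step-up correction to
#' the family of p-values. Identical paired vectors give p = 1.
#'
#' @param cv_results Named list of `gx_cv` results (or tibbles with an `auc`
#'   column) to compare against.
#' @param reference The reference `gx_cv` result.
#' @param alternative Only `"greater"` is offered: is the reference better?
#' @return Tibble with `model`, `p_value`, `p_adjusted` (Hochberg), sorted
#'   as supplied.
#' @export
compare_models <- function(cv_results, reference, alternative = "greater") {
  alternative <- match.arg(alternative, "greater")
  stopifnot(is.list(cv_results), length(cv_results) > 0)
  ref_auc <- reference$auc
  p <- vapply(seq_along(cv_results), function(i) {
    other <- cv_results[[i]]$auc
    if (length(other) != length(ref_auc)) {
      stop("fold-wise AUC vectors must be paired (equal length)", call. = FALSE)
    }
    d <- ref_auc - other
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(ref_auc, other, paired = TRUE,
                                        alternative = alternative,
                                        exact = FALSE)$p.value)
  }, numeric(1))
  nms <- names(cv_results)
  if (is.null(nms)) nms <- paste0("model_", seq_along(cv_results))
  tibble::tibble(model = nms, p_value = p,
                 p_adjusted = stats::p.adjust(p, method = "hochberg"))
}

# ---- classical ML baselines ---------------------------------------------

# vectorized one-way ANOVA F statistic per column for a binary grouping
anova_f_scores <- function(x, y) {
  y <- as.integer(y)
  n <- nrow(x)
  g1 <- y == 1
  n1 <- sum(g1)
  n0 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((x[g1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[!g1, , drop = FALSE] - rep(m0, each = n0))^2)
  (ssb / 1) / (ssw / (n - 2))
}

fit_reducer <- function(reducer, x, y, n_features, n_components) {
  switch(reducer,
    "anova-k-best" = {
      f <- anova_f_scores(x, y)
      keep <- sort(order(f, decreasing = TRUE)[seq_len(min(n_features, ncol(x)))])
      list(transform = function(newx) newx[, keep, drop = FALSE], keep = keep)
    },
    pca = {
      k <- min(n_components, ncol(x), nrow(x) - 1)
      pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
      list(transform = function(newx) stats::predict(pc, newx)[, seq_len(k), drop = FALSE])
    },
    kpca = {
      if (!requireNamespace("kernlab", quietly = TRUE)) {
        stop("kernlab is required for KPCA", call. = FALSE)
      }
      k <- min(n_components, nrow(x) - 2)
      sig <- mean(kernlab::sigest(x, scaled = FALSE)[c(1, 3)])
      kp <- kernlab::kpca(x, kernel = "rbfdot", kpar = list(sigma = sig),
                          features = k)
      list(transform = function(newx) kernlab::predict(kp, newx))
    },
    stop("unknown reducer: ", reducer, call. = FALSE)
  )
}

fit_classifier <- function(classifier, x, y, seed) {
  set.seed(seed)
  switch(classifier,
    lr = {
      df <- data.frame(x)
      fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                         family = stats::binomial()))
      function(newx) {
        suppressWarnings(as.vector(stats::predict(fit, data.frame(newx),
                                                  type = "response")))
      }
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("e1071 is required for SVM", call. = FALSE)
      }
      fit <- e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE)
      function(newx) {
        p <- stats::predict(fit, newx, probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }
    },
    "shallow-nn" = {
      if (!requireNamespace("nnet", quietly = TRUE)) {
        stop("nnet is required for the shallow NN", call. = FALSE)
      }
      fit <- nnet::nnet(x, y, size = 8, decay = 0.01, maxit = 200,
                        trace = FALSE)
      function(newx) as.vector(stats::predict(fit, newx))
    },
    rf = {
      fit <- randomForest::randomForest(x, factor(y, levels = c(0, 1)))
      function(newx) stats::predict(fit, newx, type = "prob")[, "1"]
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
}

#' Run a classical ML baseline under repeated CV
#'
#' The traditional pipeline the transfer-learning models are compared
#' against: per training fold, fit a dimensionality reducer (ANOVA top-k
#' feature selection, PCA or RBF kernel PCA), balance the reduced training
#' data with SMOTE, fit the classifier, and score the (reduced, untouched)
#' validation fold. Twelve reducer x classifier combinations are available.
#'
#' @param reducer `"anova-k-best"`, `"pca"` or `"kpca"`.
#' @param classifier `"lr"`, `"svm"`, `"shallow-nn"` or `"rf"`.
#' @param x Feature matrix, samples in rows.
#' @param y Binary labels (0/1).
#' @param repeats,folds,seed CV scheme, as in [repeated_cv()].
#' @param n_features ANOVA: number of features kept.
#' @param n_components PCA/KPCA: number of extracted components.
#' @param smote_k SMOTE neighbourhood size.
#' @return A `gx_cv` tibble.
#' @export
run_ml_baseline <- function(reducer, classifier, x, y, repeats = 10,
                            folds = 5, seed = 1L, n_features = 50,
                            n_components = 10, smote_k = 5) {
  reducer <- match.arg(reducer, c("anova-k-best", "pca", "kpca"))
  classifier <- match.arg(classifier, c("lr", "svm", "shallow-nn", "rf"))
  pipeline <- function(x_tr, y_tr, x_val, seed) {
    red <- fit_reducer(reducer, x_tr, y_tr, n_features, n_components)
    z_tr <- as.matrix(red$transform(x_tr))
    z_val <- as.matrix(red$transform(x_val))
    sm <- smote_oversample(z_tr, y_tr, k_neighbors = smote_k, seed = seed)
    predict_fn <- fit_classifier(classifier, sm$features, sm$labels, seed)
    list(val_scores = as.vector(predict_fn(z_val)),
         train_scores = as.vector(predict_fn(z_tr)))
  }
  out <- repeated_cv(x, y, pipeline, repeats, folds, seed)
  attr(out, "model") <- paste(reducer, classifier, sep = "-")
  out
}

# ---- sequential model-based hyper-parameter search -----------------------

#' Sequential model-based (Bayesian) hyper-parameter search
#'
#' Maximizes a black-box objective (conventionally the mean CV AUC of a
#' model configuration) over a bounded space: an initial maximin
#' Latin-hypercube design is evaluated, then a random-forest surrogate is
#' fitted to the trials and each next configuration is chosen by expected
#' improvement over the incumbent (surrogate uncertainty taken across
#' trees). With very few iterations this degrades gracefully to the initial
#' design.
#'
#' @param space Named list; each element is `list(lower =, upper =,
#'   integer = FALSE)`.
#' @param objective Function taking a named list of parameter values,
#'   returning a single numeric score to maximize.
#' @param iterations Total number of objective evaluations (>= 1).
#' @param seed Integer seed.
#' @return List with `best` (named parameter list), `value`, and `trials`
#'   (tibble of all evaluated configurations in order).
#' @export
bayesian_search <- function(space, objective, iterations = 10, seed = 1L) {
  stopifnot(is.list(space), length(space) > 0, iterations >= 1)
  d <- length(space)
  nms <- names(space)
  lower <- vapply(space, `[[`, numeric(1), "lower")
  upper <- vapply(space, `[[`, numeric(1), "upper")
  is_int <- vapply(space, function(s) isTRUE(s$integer), logical(1))
  decode <- function(u) { # u in [0,1]^d
    v <- lower + u * (upper - lower)
    v[is_int] <- round(v[is_int])
    stats::setNames(as.list(v), nms)
  }
  set.seed(seed)
  n_init <- min(iterations, max(4, d + 1))
  design <- lhs::maximinLHS(n_init, d)
  trials <- matrix(NA_real_, 0, d)
  values <- numeric(0)
  evaluate <- function(u) {
    par <- decode(u)
    val <- objective(par)
    trials <<- rbind(trials, u)
    values <<- c(values, val)
  }
  for (i in seq_len(n_init)) evaluate(design[i, , drop = TRUE])
  while (length(values) < iterations) {
    # the surrogate may see very few distinct objective values early on;
    # randomForest's regression warning about that is expected here
    rf <- suppressWarnings(randomForest::randomForest(
      x = as.data.frame(trials), y = values, ntree = 200))
    cand <- matrix(stats::runif(256 * d), ncol = d)
    pr <- stats::predict(rf, as.data.frame(cand), predict.all = TRUE)
    mu <- pr$aggregate
    sdv <- apply(pr$individual, 1, stats::sd)
    best <- max(values)
    z <- (mu - best) / pmax(sdv, 1e-9)
    ei <- (mu - best) * stats::pnorm(z) + pmax(sdv, 1e-9) * stats::dnorm(z)
    evaluate(cand[which.max(ei), , drop = TRUE])
  }
  best_i <- which.max(values)
  par_tab <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    as.data.frame(decode(trials[i, , drop = TRUE]))
  }))
  list(
    best = decode(trials[best_i, , drop = TRUE]),
    value = values[best_i],
    trials = tibble::as_tibble(cbind(par_tab, .value = values))
  )
}
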