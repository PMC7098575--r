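#' Fixed-time binarization of a right-censored PFI outcome
#'
#' Converts (event indicator, time) pairs into fixed-horizon class labels: a
#' sample is `positive` if the event occurred strictly before `t` days,
#' `negative` if it was followed (event or not) for at least `t` days, and
#' `excluded` if it was censored strictly before `t` — for such samples it
#' cannot be determined whether an event happened by `t`. Records with a
#' missing event or time are flagged `missing`. "Before t" is read strictly
#' (`< t`): a sample with `pfi_time == t` is negative/retained.
#'
#' @param pfi_event Integer vector in \{0, 1\} (1 = new tumor event).
#' @param pfi_time Non-negative numeric vector of days.
#' @param t Horizon in days (> 0); 230 is the conventional operating point
#'   for Pan-Cancer PFI.
#' @return Character vector with values `positive`, `negative`, `excluded`,
#'   `missing`.
#' @export
binarize_pfi <- function(pfi_event, pfi_time, t = 230) {
  if (length(t) != 1 || !is.numeric(t) || t <= 0) {
    stop("`t` must be a single positive number of days", call. = FALSE)
  }
  if (length(pfi_event) != length(pfi_time)) {
    stop("event and time vectors must have equal length", call. = FALSE)
  }
  ok_ev <- !is.na(pfi_event) & pfi_event %in% c(0, 1)
  ok_t <- !is.na(pfi_time) & pfi_time >= 0
  status <- rep("missing", length(pfi_event))
  known <- ok_ev & ok_t
  status[known & pfi_time >= t] <- "negative"
  status[known & pfi_time < t & pfi_event == 1] <- "positive"
  status[known & pfi_time < t & pfi_event == 0] <- "excluded"
  status
}

#' Horizon expressed in months
#'
#' Converts a horizon in days to (30-day) months, the unit in which fixed
#' time points are conventionally quoted (230 days is about 7.67 months).
#'
#' @param t Horizon in days.
#' @return Months as a numeric value.
#' @export
pfi_horizon_months <- function(t) t / 30

#' Label a phenotype table at a fixed horizon
#'
#' Applies [binarize_pfi()] to every sample and reports the class balance of
#' the retained (non-excluded, non-missing) samples.
#'
#' @param pheno Phenotype tibble (see [read_phenotype()]).
#' @param t Horizon in days.
#' @return A list with `labels` (tibble: `sample_id`, `cohort`, `status`,
#'   `label` with 1 = positive / 0 = negative / NA otherwise, `horizon`) and
#'   `report` (tibble: totals, retained count, positive count and fraction).
#' @export
label_dataset <- function(pheno, t = 230) {
  stopifnot(is.data.frame(pheno),
            all(c("sample_id", "pfi_event", "pfi_time") %in% names(pheno)))
  status <- binarize_pfi(pheno$pfi_event, pheno$pfi_time, t)
  labels <- tibble::tibble(
    sample_id = pheno$sample_id,
    cohort = if ("cohort" %in% names(pheno)) pheno$cohort else NA_character_,
    status = status,
    label = dplyr::case_when(status == "positive" ~ 1L,
                             status == "negative" ~ 0L,
                             TRUE ~ NA_integer_),
    horizon = t
  )
  report <- labels |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_retained = sum(.data$status %in% c("positive", "negative")),
      n_positive = sum(.data$status == "positive"),
      n_excluded = sum(.data$status == "excluded"),
      n_missing = sum(.data$status == "missing"),
      positive_fraction = ifelse(.data$n_retained > 0,
                                 .data$n_positive / .data$n_retained, NA_real_)
    )
  list(labels = labels, report = report)
}

#' Random oversampling of the minority class
#'
#' Duplicates minority-class rows (sampling with replacement) until both
#' classes have equal counts. Apply to training folds only; every output row
#' is an exact copy of an input row.
#'
#' @param features Numeric matrix (rows = samples) or 3-d image array
#'   (first dimension = samples).
#' @param labels Binary vector (0/1) of length equal to the sample count.
#' @param seed Integer seed.
#' @return A list with resampled `features` and `labels`.
#' @export
random_oversample <- function(features, labels, seed = 1L) {
  n <- if (is.array(features) && length(dim(features)) == 3) dim(features)[1] else nrow(features)
  stopifnot(length(labels) == n)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  minority <- as.integer(names(tab)[which.min(tab)])
  need <- abs(diff(as.integer(tab)))
  idx_min <- which(labels == minority)
  extra <- if (need > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    idx_min[sample.int(length(idx_min), need, replace = TRUE)]
  } else integer(0)
  keep <- c(seq_len(n), extra)
  feats <- if (length(dim(features)) == 3) {
    features[keep, , , drop = FALSE]
  } else {
    features[keep, , drop = FALSE]
  }
  list(features = feats, labels = labels[keep])
}

#' SMOTE oversampling of the minority class
#'
#' Generates synthetic minority samples as convex combinations
#' `x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`, between a minority point and
#' one of its `k` nearest minority neighbours (Euclidean distance), until
#' classes are balanced. Apply after any feature selection/extraction and to
#' training folds only.
#'
#' @param features Numeric matrix, rows = samples.
#' @param labels Binary vector (0/1).
#' @param k_neighbors Number of minority nearest neighbours (default 5);
#'   must be smaller than the minority count.
#' @param seed Integer seed.
#' @return A list with augmented `features` and `labels`.
#' @export
smote_oversample <- function(features, labels, k_neighbors = 5, seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  minority <- as.integer(names(tab)[which.min(tab)])
  idx_min <- which(labels == minority)
  n_min <- length(idx_min)
  if (n_min <= k_neighbors) {
    stop(sprintf("minority count (%d) must exceed k_neighbors (%d)",
                 n_min, k_neighbors), call. = FALSE)
  }
  need <- max(tab) - n_min
  if (need == 0) return(list(features = features, labels = labels))
  xm <- features[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(0L, n_min, k_neighbors)
  for (i in seq_len(n_min)) nn[i, ] <- order(d[i, ])[seq_len(k_neighbors)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base <- sample(n_min, need, replace = TRUE)
  pick <- nn[cbind(base, sample(k_neighbors, need, replace = TRUE))]
  u <- stats::runif(need)
  synth <- xm[base, , drop = FALSE] +
    u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  list(
    features = rbind(features, synth),
    labels = c(labels, rep(minority, need))
  )
}
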