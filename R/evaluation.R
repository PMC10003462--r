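#' Classification metrics for probabilistic predictions
#'
#' Accuracy at the 0.5 threshold (a probability of exactly 0.5 is classified
#' as a case), weighted F1 (per-class F1 averaged with weights equal to each
#' class's true support), and AUC from the rank statistic (Mann-Whitney)
#' with tied scores credited 0.5.
#'
#' @param probabilities case probabilities in \[0, 1\].
#' @param labels binary 0/1 true labels.
#' @return list with `accuracy`, `weighted_f1`, `auc`, `n_samples`,
#'   `threshold`. `auc` is `NA` (with a warning) when only one class is
#'   present.
#' @export
compute_metrics <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  labels <- as.integer(labels)
  pred <- as.integer(probabilities >= 0.5)
  acc <- mean(pred == labels)
  f1 <- weighted_f1(pred, labels)
  if (length(unique(labels)) < 2) {
    warning("AUC undefined with a single class; returning NA")
    auc <- NA_real_
  } else {
    auc <- rank_auc(probabilities, labels)
  }
  list(accuracy = acc, weighted_f1 = f1, auc = auc,
       n_samples = length(labels), threshold = 0.5)
}

# Mann-Whitney AUC; ties get half credit via midranks
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

weighted_f1 <- function(pred, labels) {
  n <- length(labels)
  f1_total <- 0
  for (cls in c(0L, 1L)) {
    support <- sum(labels == cls)
    if (support == 0) next
    tp <- sum(pred == cls & labels == cls)
    fp <- sum(pred == cls & labels != cls)
    fn <- sum(pred != cls & labels == cls)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    f1_total <- f1_total + (support / n) * f1
  }
  f1_total
}

#' Repeated-run stability summary
#'
#' Re-runs a seedable pipeline `n` times (seeds `base_seed` to
#' `base_seed + n - 1`), collects its metrics, and summarizes each metric by
#' its mean and the empirical 2.5th/97.5th percentile interval. The best
#' iteration is identified by test AUC by default (configurable, since a
#' best model could also be picked by validation loss).
#'
#' @param run_fn function(seed) returning a named list / one-row data.frame
#'   of numeric metrics (e.g. `train_acc`, `test_acc`, `test_auc`).
#' @param n number of iterations (default 100).
#' @param base_seed first seed.
#' @param select_by metric name used to pick `best_iteration`
#'   (default `"test_auc"`).
#' @return list with `per_iteration` (data.frame, one row per successful
#'   run, with `iteration` and `seed`), `mean`, `ci95` (2-row data.frame of
#'   percentile bounds), `best_iteration`, `n_failed`.
#' @export
repeat_runs <- function(run_fn, n = 100, base_seed = 1, select_by = "test_auc") {
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n)) {
    seed <- base_seed + i - 1L
    res <- tryCatch(run_fn(seed), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[length(rows) + 1]] <- cbind(
      data.frame(iteration = i, seed = seed),
      as.data.frame(res, stringsAsFactors = FALSE))
  }
  if (length(rows) == 0) stop("every iteration failed")
  per_iteration <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_iteration), c("iteration", "seed"))
  means <- vapply(per_iteration[metric_cols], mean, numeric(1))
  ci <- vapply(per_iteration[metric_cols],
               function(v) quantile(v, c(0.025, 0.975), names = FALSE),
               numeric(2))
  ci <- as.data.frame(ci)
  rownames(ci) <- c("low", "high")
  best_iteration <- NA_integer_
  if (select_by %in% metric_cols)
    best_iteration <- per_iteration$iteration[which.max(per_iteration[[select_by]])]
  list(per_iteration = per_iteration, mean = means, ci95 = ci,
       best_iteration = best_iteration, n_failed = n_failed)
}
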