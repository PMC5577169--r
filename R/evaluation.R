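#' Two-class confusion matrix with row, column and total accuracies
#'
#' Rows are actual strategies, columns predicted. Row-wise accuracy is the
#' share of each actual strategy predicted correctly; column-wise accuracy the
#' share of each prediction that is correct; total accuracy the trace over the
#' grand total. The print method reports percentages to 0.1.
#'
#' @param pred,actual character vectors of `"LFRR"` / `"RFLR"` labels.
#' @return object of class `confusion_matrix`.
#' @export
confusion <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch")
  if (length(pred) < 1L) stop("need at least one prediction")
  lv <- c("LFRR", "RFLR")
  counts <- table(factor(actual, lv), factor(pred, lv))
  counts <- matrix(as.numeric(counts), 2, 2, dimnames = list(
    actual = lv, predicted = lv))
  structure(list(
    counts = counts,
    total_accuracy = sum(diag(counts)) / sum(counts),
    row_accuracy = diag(counts) / rowSums(counts),
    col_accuracy = diag(counts) / colSums(counts)),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  cat("            Prediction\n")
  cat(sprintf("             LFRR (%s)  RFLR (%s)\n",
              pct(x$col_accuracy[1]), pct(x$col_accuracy[2])))
  for (i in 1:2)
    cat(sprintf("Actual %s (%s)  %6d      %6d\n",
                rownames(x$counts)[i], pct(x$row_accuracy[i]),
                x$counts[i, 1], x$counts[i, 2]))
  cat(sprintf("Total accuracy: %s\n", pct(x$total_accuracy)))
  invisible(x)
}

#' Seeded (optionally stratified) k-fold partition
#'
#' Folds are disjoint, cover all indices and differ in size by at most one;
#' with stratification, each label's count per fold also differs by at most
#' one (fold offsets rotate across strata so total sizes stay balanced).
#'
#' @param n number of items.
#' @param k number of folds (`k <= n`).
#' @param seed integer seed.
#' @param stratify_labels optional label vector of length `n`.
#' @return integer vector of fold assignments in `1..k`.
#' @export
kfold <- function(n, k, seed = 1L, stratify_labels = NULL) {
  if (k > n) stop("k must not exceed n")
  set.seed(seed)
  folds <- integer(n)
  groups <- if (is.null(stratify_labels)) list(seq_len(n))
            else split(seq_len(n), stratify_labels)
  offset <- 0L
  for (idx in groups) {
    idx <- sample(idx)
    folds[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds
}

#' Repeated stratified cross-validation
#'
#' `repeats` independent k-fold splits (fold seeds derived from `seed`); for
#' each fold the model factory is fit on the training portion and its
#' predictions scored on the held-out portion.
#'
#' @param model_factory `function(train_data, train_labels)` returning a
#'   prediction function `function(test_data) -> labels`.
#' @param data list (e.g. of `obs_sequence`) or data.frame of trials.
#' @param labels strategy label per trial.
#' @param k folds (default 5).
#' @param repeats repetitions (default 10).
#' @param seed integer seed.
#' @return object of class `cv_result`: data.frame of per-fold accuracies
#'   plus `mean_accuracy` / `sd_accuracy` attributes.
#' @export
cross_validate <- function(model_factory, data, labels, k = 5L, repeats = 10L,
                           seed = 1L) {
  ntrial <- if (is.data.frame(data)) nrow(data) else length(data)
  stopifnot(length(labels) == ntrial)
  take <- function(d, idx) if (is.data.frame(d)) d[idx, , drop = FALSE] else d[idx]
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- kfold(ntrial, k, seed = seed + 7919L * (r - 1L),
                   stratify_labels = labels)
    for (f in seq_len(k)) {
      test <- folds == f
      predictor <- tryCatch(
        model_factory(take(data, which(!test)), labels[!test]),
        error = function(e) stop("model error in repeat ", r, ", fold ", f,
                                 ": ", conditionMessage(e)))
      pred <- predictor(take(data, which(test)))
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, accuracy = mean(pred == labels[test]))
    }
  }
  res <- do.call(rbind, rows)
  structure(res, class = c("cv_result", "data.frame"),
            mean_accuracy = mean(res$accuracy),
            sd_accuracy = stats::sd(res$accuracy))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeats: mean accuracy %.3f (SD %.3f)\n",
              max(x$fold), max(x$rep), attr(x, "mean_accuracy"),
              attr(x, "sd_accuracy")))
  invisible(x)
}

#' Cross-validated selection of the hidden-state configuration
#'
#' Evaluates each candidate state configuration by k-fold cross-validated
#' classification accuracy and returns the smallest configuration (fewest
#' total states, ties broken toward the more balanced split, then grid order)
#' whose mean accuracy is within `margin` of the grid maximum -- an explicit
#' version of picking the point where the accuracy curve levels off.
#'
#' @param seqs list of labelled `obs_sequence`.
#' @param grid list of [state_spec()] candidates.
#' @param k folds.
#' @param seed integer seed (shared across candidates so folds match).
#' @param margin accuracy margin (default 0.01, i.e. one accuracy point).
#' @param trainer `function(train_seqs, spec)` returning a fitted
#'   `block_hmm`; the default is [fit_dhmm()] with `...` passed through.
#' @param ... passed to the default trainer.
#' @return list with `spec` (selected), `curve` (data.frame of per-candidate
#'   mean accuracies) and `results` (per-candidate `cv_result`s).
#' @export
select_states <- function(seqs, grid = default_state_grid(), k = 5L,
                          seed = 1L, margin = 0.01, trainer = NULL, ...) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (is.null(trainer)) {
    dots <- list(...)
    trainer <- function(train_seqs, spec)
      do.call(fit_dhmm, c(list(train_seqs, spec, seed = seed), dots))
  }
  labels <- vapply(seqs, function(s) s$strategy, character(1))
  results <- vector("list", length(grid))
  means <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    spec <- grid[[g]]
    factory <- function(train_data, train_labels) {
      params <- trainer(train_data, spec)
      function(test_data) classify_sequences(test_data, params)$label
    }
    res <- tryCatch(
      cross_validate(factory, seqs, labels, k = k, repeats = 1L, seed = seed),
      error = function(e) {
        warning("state spec ", spec$n_lfrr, "-", spec$n_rflr, " skipped: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      results[[g]] <- res
      means[g] <- attr(res, "mean_accuracy")
    }
  }
  if (all(is.na(means))) stop("every candidate failed")
  ok <- which(!is.na(means) & means >= max(means, na.rm = TRUE) - margin)
  sizes <- vapply(grid, function(s) s$n_lfrr + s$n_rflr, numeric(1))
  imbal <- vapply(grid, function(s) abs(s$n_lfrr - s$n_rflr), numeric(1))
  sel <- ok[order(sizes[ok], imbal[ok], ok)][1]
  curve <- data.frame(
    n_lfrr = vapply(grid, `[[`, integer(1), "n_lfrr"),
    n_rflr = vapply(grid, `[[`, integer(1), "n_rflr"),
    mean_accuracy = means)
  list(spec = grid[[sel]], curve = curve, results = results)
}

#' Majority-vote model selection across participants
#'
#' Compares two state configurations on per-participant accuracies: counts
#' how many participants each configuration wins, tests the paired accuracies
#' with a Wilcoxon signed-rank test (exact for small samples without ties),
#' and keeps the simpler configuration unless the evidence against it is
#' significant at 0.05.
#'
#' @param acc_simple,acc_complex per-participant accuracy vectors under the
#'   simpler and the more complex configuration (paired, length >= 5).
#' @param spec_simple,spec_complex the two [state_spec()]s.
#' @return list with `spec` (selected), `n_favour_complex`, `p_value` and
#'   `statistic`.
#' @export
majority_vote_selection <- function(acc_simple, acc_complex, spec_simple,
                                    spec_complex) {
  stopifnot(length(acc_simple) == length(acc_complex),
            length(acc_simple) >= 5L)
  d <- acc_complex - acc_simple
  n_favour <- sum(d > 0)
  if (all(d == 0)) {
    return(list(spec = spec_simple, n_favour_complex = 0L, p_value = 1,
                statistic = NA_real_))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(acc_complex, acc_simple,
                                            paired = TRUE, exact = exact))
  pick_complex <- n_favour > length(d) / 2 && wt$p.value < 0.05
  list(spec = if (pick_complex) spec_complex else spec_simple,
       n_favour_complex = n_favour, p_value = wt$p.value,
       statistic = unname(wt$statistic))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact null distribution for small samples without ties; normal
#' approximation with tie correction otherwise. Two-sided.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (rank-sum W of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  exact <- length(x) <= 25L && length(y) <= 25L && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # degenerate case: no rank variation at all
  list(statistic = unname(wt$statistic), p_value = min(p, 1))
}

#' Classical one-way ANOVA on classification accuracies
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `F`, `p_value`, `df`.
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) >= 2L))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0)
    stop("F undefined: zero variance within and between groups")
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p_value = ft$p.value,
       df = unname(ft$parameter))
}

#' Ordinary-least-squares angle-effect slope
#'
#' Linear regression of reaction time on angular disparity; the slope is the
#' angle effect in ms/degree.
#'
#' @param rt_table data.frame with columns `angle` (degrees) and `rt_ms`.
#' @return list with `slope` (ms/degree) and `intercept` (ms).
#' @export
angle_effect_slope <- function(rt_table) {
  stopifnot(is.data.frame(rt_table),
            all(c("angle", "rt_ms") %in% names(rt_table)))
  if (length(unique(rt_table$angle)) < 2L)
    stop("need at least two distinct angles")
  fit <- stats::lm(rt_ms ~ angle, data = rt_table)
  co <- stats::coef(fit)
  list(slope = unname(co["angle"]), intercept = unname(co["(Intercept)"]))
}
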