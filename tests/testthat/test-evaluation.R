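labels_from_counts <- function(counts) {
  # build prediction/actual vectors realizing a 2x2 count matrix
  lv <- c("LFRR", "RFLR")
  actual <- rep(rep(lv, each = 2), times = as.vector(t(counts)))
  pred <- rep(rep(lv, times = 2), times = as.vector(t(counts)))
  list(pred = pred, actual = actual)
}

test_that("confusion-matrix arithmetic reproduces the printed accuracies exactly at 0.1% rounding", {
  # logistic-regression test-set table
  t1 <- labels_from_counts(rbind(c(300, 204), c(234, 270)))
  cm1 <- confusion(t1$pred, t1$actual)
  expect_equal(round(100 * cm1$total_accuracy, 1), 56.5)
  expect_equal(round(100 * unname(cm1$row_accuracy), 1), c(59.5, 53.6))
  expect_equal(round(100 * unname(cm1$col_accuracy), 1), c(56.2, 57.0))

  # SVM test-set table
  t2 <- labels_from_counts(rbind(c(357, 147), c(168, 336)))
  cm2 <- confusion(t2$pred, t2$actual)
  expect_equal(round(100 * cm2$total_accuracy, 1), 68.8)
  expect_equal(round(100 * unname(cm2$row_accuracy), 1), c(70.8, 66.7))

  # dHMM test-set table: row-wise accuracy 78.6% for actual LFRR
  t3 <- labels_from_counts(rbind(c(396, 108), c(127, 377)))
  cm3 <- confusion(t3$pred, t3$actual)
  expect_equal(round(100 * unname(cm3$row_accuracy[1]), 1), 78.6)
  expect_equal(round(100 * cm3$total_accuracy, 1), 76.7)

  perfect <- confusion(t1$actual, t1$actual)
  expect_equal(perfect$total_accuracy, 1)
  expect_equal(unname(perfect$row_accuracy), c(1, 1))
  expect_equal(unname(perfect$col_accuracy), c(1, 1))
  expect_error(confusion(c("LFRR"), c("LFRR", "RFLR")), "length mismatch")
})

test_that("k-fold partitions are balanced, stratified, seeded and reproducible", {
  f <- kfold(10, 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))

  lab <- rep(c("a", "b"), c(8, 2))
  fs <- kfold(10, 5, seed = 2, stratify_labels = lab)
  per_fold_b <- table(factor(fs[lab == "b"], levels = 1:5))
  expect_lte(max(per_fold_b) - min(per_fold_b), 1)
  expect_lte(max(table(fs)) - min(table(fs)), 1)

  expect_identical(kfold(100, 5, seed = 7, stratify_labels = rep(1:2, 50)),
                   kfold(100, 5, seed = 7, stratify_labels = rep(1:2, 50)))
  expect_error(kfold(3, 5), "exceed")
})

test_that("cross-validation scores constant and perfect classifiers correctly", {
  labs <- rep(c("LFRR", "RFLR"), each = 30)
  data <- data.frame(x = seq_along(labs))
  const <- function(train, lab) function(test) rep("LFRR", nrow(test))
  cv0 <- cross_validate(const, data, labs, k = 5, repeats = 2, seed = 3)
  expect_equal(attr(cv0, "mean_accuracy"), 0.5)

  oracle <- function(train, lab) function(test)
    ifelse(test$x <= 30, "LFRR", "RFLR")
  cv1 <- cross_validate(oracle, data, labs, k = 5, repeats = 2, seed = 3)
  expect_equal(attr(cv1, "mean_accuracy"), 1)
})

test_that("cross-validation with k = n and one repeat reduces to leave-one-out", {
  labs <- rep(c("LFRR", "RFLR"), each = 6)
  data <- data.frame(x = seq_along(labs))
  cv <- cross_validate(function(train, lab) function(test) rep("LFRR", nrow(test)),
                       data, labs, k = 12, repeats = 1, seed = 5)
  expect_equal(nrow(cv), 12)
  expect_true(all(cv$accuracy %in% c(0, 1)))
  expect_equal(attr(cv, "mean_accuracy"), 0.5)
})

test_that("state selection applies the within-margin-of-max smallest-model rule", {
  seqs <- sim_corpus(30, seed = 41)$sequences
  g1 <- list(state_spec(1, 1))
  # spec-independent trainer: identical accuracies for every candidate
  flat_trainer <- function(train_seqs, spec) random_block_hmm(1, 1, seed = 1)
  sel1 <- select_states(seqs, g1, k = 2, seed = 1, trainer = flat_trainer)
  expect_equal(sel1$spec, state_spec(1, 1))

  # a flat curve returns the smallest spec; enlarging the margin never
  # selects a larger one
  grid <- list(state_spec(2, 2), state_spec(2, 3), state_spec(3, 3))
  sel_flat <- select_states(seqs, grid, k = 2, seed = 1,
                            trainer = flat_trainer)
  expect_equal(sel_flat$spec, state_spec(2, 2))
  for (m in c(0.02, 0.1, 0.5)) {
    sel_m <- select_states(seqs, grid, k = 2, seed = 1, margin = m,
                           trainer = flat_trainer)
    expect_lte(sel_m$spec$n_lfrr + sel_m$spec$n_rflr,
               sel_flat$spec$n_lfrr + sel_flat$spec$n_rflr + 0)
  }
  expect_error(select_states(seqs, list()), "non-empty")
})

test_that("majority voting keeps the simpler model unless the evidence is significant", {
  s33 <- state_spec(3, 3)
  s34 <- state_spec(3, 4)
  same <- rep(0.7, 8)
  tie <- majority_vote_selection(same, same, s33, s34)
  expect_equal(tie$spec, s33)
  expect_equal(tie$p_value, 1)

  # 14 of 15 participants favour the complex spec by about +0.1
  a <- seq(0.60, 0.74, by = 0.01)
  b <- a + 0.1 + 0.001 * seq_len(15)  # unique gaps keep the exact path
  b[15] <- a[15] - 0.05
  mv <- majority_vote_selection(a, b, s33, s34)
  expect_equal(mv$n_favour_complex, 14)
  expect_equal(mv$spec, s34)
  expect_equal(mv$p_value, oracle_signed_rank_p(b - a), tolerance = 1e-10)

  # only 5 of 20 favour the larger spec and the difference is tiny
  set.seed(8)
  base <- runif(20, 0.6, 0.8)
  other <- base - 0.01
  other[1:5] <- base[1:5] + 0.002
  mv2 <- majority_vote_selection(base, other, s33, s34)
  expect_equal(mv2$n_favour_complex, 5)
  expect_equal(mv2$spec, s33)
})

test_that("rank-sum p-values are exact for tiny samples and sensible in the limits", {
  x <- c(1.2, 3.4, 5.6)
  y <- c(2.1, 4.3, 6.5)
  got <- wilcoxon_rank_sum(x, y)
  expect_equal(got$p_value, oracle_rank_sum_p(x, y), tolerance = 1e-12)

  same <- rep(c(1, 2, 3), 2)
  expect_gte(wilcoxon_rank_sum(same, same)$p_value, 0.99)

  set.seed(3)
  a <- rnorm(50)
  b <- rnorm(50, mean = 5)
  expect_lt(wilcoxon_rank_sum(a, b)$p_value, 1e-6)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  g1 <- c(1, 2, 3)
  g2 <- c(2, 3, 4)
  # hand arithmetic: grand mean 2.5, SSB = 3*(2-2.5)^2 + 3*(3-2.5)^2 = 1.5,
  # SSW = 2 + 2 = 4, F = (1.5/1) / (4/4) = 1.5
  got <- oneway_anova(list(g1, g2))
  expect_equal(got$F, 1.5)
  expect_equal(got$p_value, stats::pf(1.5, 1, 4, lower.tail = FALSE))

  ident <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p_value, 1)

  far <- oneway_anova(list(rnorm(20, 0, 0.01), rnorm(20, 100, 0.01)))
  expect_lt(far$p_value, 1e-12)

  expect_error(oneway_anova(list(c(2, 2), c(2, 2))), "undefined")
})

test_that("the OLS angle-effect slope matches the closed-form normal equations", {
  tab <- data.frame(angle = rep(seq(0, 180, 30), each = 2))
  tab$rt_ms <- 500 + 10 * tab$angle
  fit <- angle_effect_slope(tab)
  expect_equal(fit$slope, 10, tolerance = 1e-10)
  expect_equal(fit$intercept, 500, tolerance = 1e-8)

  set.seed(17)
  tab$rt_ms <- tab$rt_ms + rnorm(nrow(tab), 0, 120)
  fit2 <- angle_effect_slope(tab)
  sxy <- sum((tab$angle - mean(tab$angle)) * (tab$rt_ms - mean(tab$rt_ms)))
  sxx <- sum((tab$angle - mean(tab$angle))^2)
  expect_equal(fit2$slope, sxy / sxx, tolerance = 1e-10)

  expect_error(angle_effect_slope(data.frame(angle = c(30, 30),
                                             rt_ms = c(1, 2))),
               "two distinct angles")
})
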