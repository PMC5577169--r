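seq_from_model <- function(params, class, T, seed) {
  set.seed(seed)
  sample_sequence(params, class, T)
}

test_that("forward log-likelihood equals brute-force path enumeration on small models", {
  for (case in 1:8) {
    n1 <- 1 + case %% 2
    n2 <- 1 + (case %/% 2) %% 2
    p <- random_block_hmm(n1, n2, seed = 100 + case)
    for (T in c(1, 2, 3, 5)) {
      s <- seq_from_model(p, "LFRR", T, seed = 200 + case + T)
      got <- log_forward(s, p)
      # oracle: enumerate paths separately inside each block
      masses <- vapply(c("LFRR", "RFLR"), function(cl) {
        blk <- block_states(p, cl)
        oracle_forward(p$pi[blk], p$A[blk, blk, drop = FALSE],
                       oracle_logB(p, blk, s$events))$loglik
      }, numeric(1))
      expect_equal(got$class_logmass, masses, tolerance = 1e-10)
      expect_equal(got$loglik, log(sum(exp(masses))), tolerance = 1e-10)
    }
  }
})

test_that("a single-state, single-fixation model reduces to the emission log-density", {
  p <- random_block_hmm(1, 1, seed = 7)
  s <- make_seq(5.1, 2L)
  e <- p$emissions[[1]]
  expect_equal(log_forward(s, p)$class_logmass[["LFRR"]],
               log(p$pi[1]) + dnorm(5.1, e$mu_fd, e$sigma_fd, log = TRUE) +
                 log(e$p_aoi[2]))
})

test_that("the likelihood is invariant to rescaling the unnormalized initial mass", {
  p <- random_block_hmm(2, 2, seed = 3)
  p2 <- block_hmm(p$pi * 2, p$A, p$emissions, p$class_of_state)
  s <- seq_from_model(p, "RFLR", 4, seed = 11)
  expect_equal(log_forward(s, p), log_forward(s, p2))
})

test_that("Viterbi matches enumeration, stays within a block, and never exceeds the forward likelihood", {
  for (case in 1:6) {
    p <- random_block_hmm(2, 2, seed = 300 + case)
    s <- seq_from_model(p, "LFRR", 3, seed = 400 + case)
    v <- viterbi(s, p)
    cls <- unique(p$class_of_state[v$path])
    expect_length(cls, 1)
    blk <- block_states(p, cls)
    o <- oracle_forward(p$pi[blk], p$A[blk, blk, drop = FALSE],
                        oracle_logB(p, blk, s$events))
    other <- setdiff(c("LFRR", "RFLR"), cls)
    blk2 <- block_states(p, other)
    o2 <- oracle_forward(p$pi[blk2], p$A[blk2, blk2, drop = FALSE],
                         oracle_logB(p, blk2, s$events))
    expect_equal(v$logprob, max(o$best_logprob, o2$best_logprob),
                 tolerance = 1e-10)
    if (o$best_logprob > o2$best_logprob)
      expect_equal(v$path, blk[o$best_path])
    expect_lte(v$logprob, log_forward(s, p)$loglik + 1e-10)
  }
})

test_that("Viterbi ties break toward the lowest state index", {
  # two indistinguishable LFRR states: every path has equal probability
  e <- list(mu_fd = 5, sigma_fd = 0.5, mu_sl = 4, sigma_sl = 0.5,
            p_aoi = rep(0.25, 4), p_sd = rep(0.25, 4))
  p <- block_hmm(pi = c(0.5, 0.5, 1e-9),
                 A = rbind(c(.5, .5, 0), c(.5, .5, 0), c(0, 0, 1)),
                 emissions = list(e, e, e),
                 class_of_state = c("LFRR", "LFRR", "RFLR"))
  s <- make_seq(c(5, 5, 5), c(1, 1, 1), c(4, 4, 4), c(1, 1, 1))
  expect_equal(viterbi(s, p)$path, c(1, 1, 1))
})

test_that("a deterministic chain is recovered exactly", {
  eps <- 1e-9
  mk_e <- function(mu) list(mu_fd = mu, sigma_fd = 0.1, mu_sl = 4,
                            sigma_sl = 0.5, p_aoi = rep(0.25, 4),
                            p_sd = rep(0.25, 4))
  p <- block_hmm(pi = c(1 - eps, eps, eps),
                 A = rbind(c(eps, 1 - eps, 0), c(1 - eps, eps, 0), c(0, 0, 1)),
                 emissions = list(mk_e(3), mk_e(8), mk_e(5)),
                 class_of_state = c("LFRR", "LFRR", "RFLR"))
  s <- make_seq(c(3, 8, 3, 8), c(1, 1, 1, 1), rep(4, 4), rep(1L, 4))
  expect_equal(viterbi(s, p)$path, c(1, 2, 1, 2))
})

test_that("one state per class yields closed-form Gaussian MLEs after one EM pass", {
  set.seed(21)
  seqs <- c(lapply(1:6, function(i) make_seq(rnorm(5, 4.5, 0.4), sample(1:4, 5, TRUE),
                                             rnorm(5, 4, .3), sample(1:4, 5, TRUE))),
            lapply(1:6, function(i) make_seq(rnorm(5, 5.5, 0.4), sample(1:4, 5, TRUE),
                                             rnorm(5, 4, .3), sample(1:4, 5, TRUE),
                                             strategy = "RFLR")))
  fit <- baum_welch(seqs, state_spec(1, 1), max_iter = 3, seed = 5)
  lab <- vapply(seqs, function(s) s$strategy, character(1))
  for (cl in c("LFRR", "RFLR")) {
    x <- unlist(lapply(seqs[lab == cl], function(s) s$events$log_fd))
    i <- block_states(fit, cl)
    expect_equal(fit$emissions[[i]]$mu_fd, mean(x), tolerance = 1e-8)
  }
  # pi carries the class prior: balanced labels -> half the mass per block
  expect_equal(sum(fit$pi[block_states(fit, "LFRR")]), 0.5, tolerance = 1e-8)
})

test_that("EM never decreases the labelled joint log-likelihood", {
  seqs <- sim_corpus(60, seed = 31)$sequences
  for (sd in 1:3) {
    fit <- baum_welch(seqs, state_spec(3, 3), seed = sd, max_iter = 40)
    expect_true(all(diff(attr(fit, "loglik_trace")) > -1e-8))
  }
})

test_that("length-1 sequences are handled and leave transition rows untouched", {
  seqs <- sim_corpus(20, seed = 8)$sequences
  seqs[[1]] <- make_seq(5.2, 3L)
  seqs[[21]] <- make_seq(4.9, 1L, strategy = "RFLR")
  init <- init_params(seqs, state_spec(2, 2), seed = 2)
  expect_no_error(fit <- baum_welch(seqs, init = init, max_iter = 10))
  only_singletons <- list(make_seq(5.2, 3L),
                          make_seq(4.9, 1L, strategy = "RFLR"))
  fit1 <- baum_welch(only_singletons, init = init, max_iter = 5)
  expect_equal(fit1$A, init$A)  # no transitions observed anywhere
})

test_that("conditional log-likelihood is N log(1/2) under exact block symmetry", {
  p <- random_block_hmm(2, 2, seed = 17)
  # mirror the LFRR block onto the RFLR block
  em <- p$emissions
  em[[3]] <- em[[1]]; em[[4]] <- em[[2]]
  A <- p$A
  A[3:4, 3:4] <- A[1:2, 1:2]
  pi <- c(p$pi[1:2], p$pi[1:2])
  sym <- block_hmm(pi, A, em, p$class_of_state)
  seqs <- lapply(1:7, function(i) seq_from_model(sym, "LFRR", 4, seed = i))
  expect_equal(conditional_log_likelihood(seqs, sym), 7 * log(0.5),
               tolerance = 1e-9)
})

test_that("a two-state toy posterior equals the enumeration-based Bayes computation", {
  p <- random_block_hmm(1, 1, seed = 23)
  s <- seq_from_model(p, "LFRR", 3, seed = 5)
  post <- classify(s, p)
  masses <- vapply(c("LFRR", "RFLR"), function(cl) {
    blk <- block_states(p, cl)
    oracle_forward(p$pi[blk], p$A[blk, blk, drop = FALSE],
                   oracle_logB(p, blk, s$events))$loglik
  }, numeric(1))
  expect_equal(post$p_lfrr, unname(exp(masses[1]) / sum(exp(masses))),
               tolerance = 1e-10)
  expect_equal(post$p_lfrr + post$p_rflr, 1, tolerance = 1e-9)
})

test_that("classification is symmetric under identical blocks and follows pi mass", {
  p <- random_block_hmm(2, 2, seed = 29)
  em <- p$emissions; em[[3]] <- em[[1]]; em[[4]] <- em[[2]]
  A <- p$A; A[3:4, 3:4] <- A[1:2, 1:2]
  sym <- block_hmm(c(p$pi[1:2], p$pi[1:2]), A, em, p$class_of_state)
  s <- seq_from_model(sym, "LFRR", 5, seed = 77)
  post <- classify(s, sym)
  expect_equal(post$p_lfrr, 0.5, tolerance = 1e-9)
  expect_identical(post$label, "LFRR")  # tie rule
  # all the initial mass in the LFRR block forces p_lfrr = 1
  skew <- block_hmm(c(p$pi[1:2], 1e-12, 1e-12), A, em, p$class_of_state)
  expect_equal(classify(s, skew)$p_lfrr, 1, tolerance = 1e-6)
})

test_that("the analytic conditional-likelihood gradient matches central finite differences", {
  p <- random_block_hmm(2, 2, seed = 41)
  seqs <- c(lapply(1:3, function(i) seq_from_model(p, "LFRR", 4, seed = i)),
            lapply(4:6, function(i) seq_from_model(p, "RFLR", 3, seed = i)))
  cg <- rotscan:::.cll_and_grad(seqs, p)
  N <- length(seqs)
  h <- 1e-5
  nudge <- function(params, what, i, k, eps) {
    em <- params$emissions; A <- params$A; pi <- params$pi
    soft <- function(pr, j, e) {
      th <- log(pr); th[j] <- th[j] + e
      exp(th) / sum(exp(th))
    }
    if (what == "pi") pi <- soft(pi, k, eps)
    if (what == "A") {
      blk <- which(params$class_of_state == params$class_of_state[i])
      A[i, blk] <- soft(A[i, blk], which(blk == k), eps)
    }
    if (what == "p_aoi") em[[i]]$p_aoi <- soft(em[[i]]$p_aoi, k, eps)
    if (what == "p_sd") em[[i]]$p_sd <- soft(em[[i]]$p_sd, k, eps)
    if (what == "mu_fd") em[[i]]$mu_fd <- em[[i]]$mu_fd + eps
    if (what == "lsig_fd") em[[i]]$sigma_fd <- em[[i]]$sigma_fd * exp(eps)
    if (what == "mu_sl") em[[i]]$mu_sl <- em[[i]]$mu_sl + eps
    if (what == "lsig_sl") em[[i]]$sigma_sl <- em[[i]]$sigma_sl * exp(eps)
    block_hmm(pi, A, em, params$class_of_state)
  }
  fd <- function(what, i, k = NA) {
    up <- conditional_log_likelihood(seqs, nudge(p, what, i, k, h))
    dn <- conditional_log_likelihood(seqs, nudge(p, what, i, k, -h))
    (up - dn) / (2 * h) / N
  }
  for (i in 1:4) {
    expect_equal(fd("mu_fd", i), cg$grad$mu_fd[i], tolerance = 1e-5)
    expect_equal(fd("lsig_fd", i), cg$grad$lsig_fd[i], tolerance = 1e-5)
    expect_equal(fd("mu_sl", i), cg$grad$mu_sl[i], tolerance = 1e-5)
    expect_equal(fd("lsig_sl", i), cg$grad$lsig_sl[i], tolerance = 1e-5)
    expect_equal(fd("pi", 1, i), cg$grad$pi[i], tolerance = 1e-5)
    for (k in 1:4) {
      expect_equal(fd("p_aoi", i, k), cg$grad$p_aoi[i, k], tolerance = 1e-5)
      expect_equal(fd("p_sd", i, k), cg$grad$p_sd[i, k], tolerance = 1e-5)
    }
    blk <- which(p$class_of_state == p$class_of_state[i])
    for (k in blk)
      expect_equal(fd("A", i, k), cg$grad$A[i, k], tolerance = 1e-5)
  }
})

test_that("discriminative training is monotone in the conditional likelihood and a fixed point on separable data", {
  seqs <- sim_corpus(50, seed = 13)$sequences
  bw <- baum_welch(seqs, state_spec(2, 2), seed = 1, max_iter = 30)
  ref <- discriminative_train(seqs, bw, max_iter = 15)
  expect_true(all(diff(attr(ref, "cll_trace")) > -1e-9))

  # widely separated single-state blocks: posteriors already ~ 1
  e1 <- list(mu_fd = 0, sigma_fd = 0.2, mu_sl = 4, sigma_sl = 0.5,
             p_aoi = rep(.25, 4), p_sd = rep(.25, 4))
  e2 <- e1; e2$mu_fd <- 20
  p <- block_hmm(c(.5, .5), diag(2), list(e1, e2), c("LFRR", "RFLR"))
  set.seed(2)
  sep <- c(lapply(1:5, function(i) sample_sequence(p, "LFRR", 4)),
           lapply(1:5, function(i) sample_sequence(p, "RFLR", 4)))
  cll0 <- conditional_log_likelihood(sep, p)
  expect_gt(cll0, -1e-6)  # perfectly separated: objective near 0 from below
  ref2 <- discriminative_train(sep, p, max_iter = 5)
  expect_lt(abs(conditional_log_likelihood(sep, ref2) - cll0), 1e-6)
})

test_that("discriminative refinement does not hurt held-out accuracy on synthetic data", {
  corp <- sim_corpus(150, seed = 19)
  train <- corp$sequences[corp$is_train]
  test <- corp$sequences[!corp$is_train]
  bw <- fit_dhmm(train, state_spec(3, 3), restarts = 3, seed = 2,
                 refine = FALSE, tol = 1e-7, max_iter = 300)
  ref <- discriminative_train(train, bw, max_iter = 30)
  acc <- function(p) {
    pr <- classify_sequences(test, p)
    mean(pr$label == pr$actual)
  }
  expect_gte(acc(ref), acc(bw))
})

test_that("sampling is reproducible and matches configured emission frequencies in the long run", {
  p <- default_params()
  set.seed(10); a <- sample_sequence(p, "LFRR", 30)
  set.seed(10); b <- sample_sequence(p, "LFRR", 30)
  expect_identical(a, b)
  s1 <- sample_sequence(p, "RFLR", 1)
  expect_equal(nrow(s1$events), 1L)
  expect_true(is.na(s1$events$sd))

  # single-state model: law of large numbers on the SD categorical
  e <- p$emissions[[1]]  # LFRR encoding state, SD-1 mass 0.89
  single <- block_hmm(c(.5, .5), diag(2), list(e, e), c("LFRR", "RFLR"))
  set.seed(123)
  s <- sample_sequence(single, "LFRR", 1e5 + 1)
  freq <- tabulate(s$events$sd[!is.na(s$events$sd)], 4) / 1e5
  expect_true(all(abs(freq - e$p_sd) <= 0.01))
})

test_that("parameters round-trip exactly through JSON", {
  p <- random_block_hmm(3, 2, seed = 55)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_params(p, path)
  q <- read_hmm_params(path)
  expect_equal(q$pi, p$pi)
  expect_equal(q$A, p$A)
  expect_equal(q$emissions, p$emissions)
  expect_identical(q$class_of_state, p$class_of_state)
})

test_that("invalid parameter sets are rejected", {
  p <- random_block_hmm(2, 2, seed = 61)
  A_bad <- p$A
  A_bad[1, 3] <- 0.1
  expect_error(block_hmm(p$pi, A_bad, p$emissions, p$class_of_state),
               "between blocks")
  expect_error(block_hmm(p$pi, p$A, p$emissions,
                         c("LFRR", "LFRR", "LFRR", "LFRR")),
               "at least one state")
  em_bad <- p$emissions
  em_bad[[2]]$sigma_fd <- -1
  expect_error(block_hmm(p$pi, p$A, em_bad, p$class_of_state), "sigmas")
})
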