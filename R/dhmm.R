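#' @useDynLib rotscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif sd
NULL

.CLASSES <- c("LFRR", "RFLR")

# Stack a list of obs_sequence into flat arrays for the compiled routines.
# sd is 0 where absent; sl_ok flags events with an outgoing saccade.
.stack_seqs <- function(seqs) {
  lens <- vapply(seqs, function(s) nrow(s$events), integer(1))
  ev <- do.call(rbind, lapply(seqs, `[[`, "events"))
  sl_ok <- as.integer(!is.na(ev$sd))
  list(xfd = ev$log_fd,
       xsl = ifelse(sl_ok == 1L, ev$log_sl, 0),
       aoi = as.integer(ev$aoi),
       sd = ifelse(sl_ok == 1L, as.integer(ev$sd), 0L),
       sl_ok = sl_ok, lens = lens,
       labels = vapply(seqs, function(s) s$strategy, character(1)))
}

# Emission log-densities for the given states: rows = stacked events,
# columns = states. The saccade factors are dropped (not imputed) for final
# fixations.
.logB <- function(params, states, st) {
  out <- matrix(0, length(st$xfd), length(states))
  for (k in seq_along(states)) {
    e <- params$emissions[[states[k]]]
    v <- dnorm(st$xfd, e$mu_fd, e$sigma_fd, log = TRUE) +
      log(e$p_aoi)[st$aoi]
    w <- dnorm(st$xsl, e$mu_sl, e$sigma_sl, log = TRUE) +
      log(e$p_sd)[pmax(st$sd, 1L)]
    out[, k] <- v + ifelse(st$sl_ok == 1L, w, 0)
  }
  out
}

.block_logpi <- function(params, class) {
  blk <- block_states(params, class)
  log(pmax(params$pi[blk], .PROB_FLOOR))
}

.block_logA <- function(params, class) {
  blk <- block_states(params, class)
  log(pmax(params$A[blk, blk, drop = FALSE], .PROB_FLOOR))
}

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

#' Forward log-likelihood of one observation sequence
#'
#' Computes `log P(X | lambda)` of the joint block HMM in log space, together
#' with the terminal log mass accumulated inside each class block (paths never
#' cross blocks, so the total is the log-sum of the two block masses).
#'
#' @param seq an `obs_sequence`.
#' @param params a [block_hmm()].
#' @return list with `loglik` and `class_logmass` (named, one entry per class).
#' @export
log_forward <- function(seq, params) {
  stopifnot(inherits(seq, "obs_sequence"), inherits(params, "block_hmm"))
  st <- .stack_seqs(list(seq))
  mass <- vapply(.CLASSES, function(cl) {
    blk <- block_states(params, cl)
    cpp_forward(.block_logpi(params, cl), .block_logA(params, cl),
                .logB(params, blk, st))$loglik
  }, numeric(1))
  list(loglik = .logsumexp(mass), class_logmass = mass)
}

# Per-sequence class log-masses for a batch: one column per class.
.class_logmass_batch <- function(seqs, params, st = .stack_seqs(seqs)) {
  vapply(.CLASSES, function(cl) {
    blk <- block_states(params, cl)
    cpp_forward_batch(.block_logpi(params, cl), .block_logA(params, cl),
                      .logB(params, blk, st), st$lens)
  }, numeric(length(seqs)))
}

#' Most probable hidden-state path
#'
#' Block-diagonal transitions confine every path to one class block, so the
#' global optimum is the better of the two per-block Viterbi paths. Ties are
#' broken toward the lowest state index (and toward the LFRR block).
#'
#' @inheritParams log_forward
#' @return list with `path` (global state indices), `logprob` and `class`.
#' @export
viterbi <- function(seq, params) {
  stopifnot(inherits(seq, "obs_sequence"), inherits(params, "block_hmm"))
  st <- .stack_seqs(list(seq))
  best <- NULL
  for (cl in .CLASSES) {
    blk <- block_states(params, cl)
    v <- cpp_viterbi(.block_logpi(params, cl), .block_logA(params, cl),
                     .logB(params, blk, st))
    if (is.null(best) || v$logprob > best$logprob)
      best <- list(path = blk[v$path], logprob = v$logprob, class = cl)
  }
  best
}

#' Posterior strategy probabilities for one sequence
#'
#' Bayes inversion of the joint model: the posterior of each class is its
#' block's terminal forward mass divided by the total; the class prior is
#' implicit in the initial-distribution mass of each block. Ties classify as
#' LFRR.
#'
#' @inheritParams log_forward
#' @return object of class `class_posterior` with `p_lfrr`, `p_rflr`, `label`.
#' @export
classify <- function(seq, params) {
  m <- log_forward(seq, params)$class_logmass
  p <- exp(m - .logsumexp(m))
  p <- p / sum(p)
  structure(list(p_lfrr = p[["LFRR"]], p_rflr = p[["RFLR"]],
                 label = if (p[["LFRR"]] >= p[["RFLR"]]) "LFRR" else "RFLR"),
            class = "class_posterior")
}

#' @export
print.class_posterior <- function(x, ...) {
  cat(sprintf("P(LFRR) = %.4f, P(RFLR) = %.4f -> %s\n",
              x$p_lfrr, x$p_rflr, x$label))
  invisible(x)
}

#' Classify a batch of sequences
#'
#' @param seqs list of `obs_sequence`.
#' @param params a `block_hmm`.
#' @return data.frame with `p_lfrr`, `p_rflr`, `label` and (if present)
#'   `actual` strategy labels.
#' @export
classify_sequences <- function(seqs, params) {
  m <- .class_logmass_batch(seqs, params)
  tot <- apply(m, 1, .logsumexp)
  p <- exp(m - tot)
  p <- p / rowSums(p)
  data.frame(p_lfrr = p[, "LFRR"], p_rflr = p[, "RFLR"],
             label = ifelse(p[, "LFRR"] >= p[, "RFLR"], "LFRR", "RFLR"),
             actual = vapply(seqs, function(s) s$strategy, character(1)))
}

#' Conditional log-likelihood of the labels given the sequences
#'
#' `sum_n log [ mass of the labelled block / total mass ]` -- the objective of
#' discriminative training.
#'
#' @param seqs list of labelled `obs_sequence`.
#' @param params a `block_hmm`.
#' @return scalar (finite unless some sequence has zero total mass, in which
#'   case `-Inf` with a warning).
#' @export
conditional_log_likelihood <- function(seqs, params) {
  st <- .stack_seqs(seqs)
  if (any(!st$labels %in% .CLASSES)) stop("all sequences must be labelled")
  m <- .class_logmass_batch(seqs, params, st)
  tot <- apply(m, 1, .logsumexp)
  if (any(!is.finite(tot))) {
    warning("zero total mass for some sequence; returning -Inf")
    return(-Inf)
  }
  num <- m[cbind(seq_along(seqs), match(st$labels, .CLASSES))]
  sum(num - tot)
}

# ---- Baum-Welch (generative, labelled) --------------------------------------

# Expected-sufficient-statistics pass for one class block over a weighted set
# of sequences (weights on whole sequences).
.estep_block <- function(params, class, st, idx, w) {
  blk <- block_states(params, class)
  sub <- .subset_stack(st, idx)
  stats <- cpp_estep_batch(.block_logpi(params, class),
                           .block_logA(params, class),
                           .logB(params, blk, sub), sub$lens, w,
                           sub$xfd, sub$xsl, sub$aoi, sub$sd, sub$sl_ok)
  stats$states <- blk
  stats
}

.subset_stack <- function(st, idx) {
  if (length(idx) == length(st$lens) && all(idx == seq_along(st$lens)))
    return(st)
  ends <- cumsum(st$lens)
  starts <- ends - st$lens + 1L
  rows <- unlist(lapply(idx, function(i) starts[i]:ends[i]))
  list(xfd = st$xfd[rows], xsl = st$xsl[rows], aoi = st$aoi[rows],
       sd = st$sd[rows], sl_ok = st$sl_ok[rows], lens = st$lens[idx],
       labels = st$labels[idx])
}

# Global moment summaries used for initialization and for re-seeding starved
# states.
.global_moments <- function(st) {
  sl <- st$xsl[st$sl_ok == 1L]
  sdv <- st$sd[st$sl_ok == 1L]
  list(m_fd = mean(st$xfd), s_fd = max(sd(st$xfd), 0.1),
       m_sl = if (length(sl)) mean(sl) else log(50),
       s_sl = if (length(sl) > 1) max(sd(sl), 0.1) else 0.5,
       p_aoi = .floor_norm(tabulate(st$aoi, 4) + 0.5),
       p_sd = .floor_norm(tabulate(sdv, 4) + 0.5))
}

.perturbed_emission <- function(gm) {
  list(mu_fd = gm$m_fd + rnorm(1, 0, 0.5) * gm$s_fd,
       sigma_fd = gm$s_fd * runif(1, 0.7, 1.3),
       mu_sl = gm$m_sl + rnorm(1, 0, 0.5) * gm$s_sl,
       sigma_sl = gm$s_sl * runif(1, 0.7, 1.3),
       p_aoi = .floor_norm(gm$p_aoi * exp(rnorm(4, 0, 0.4))),
       p_sd = .floor_norm(gm$p_sd * exp(rnorm(4, 0, 0.4))))
}

#' Seeded random initialization for Baum-Welch
#'
#' Per-state emissions are perturbations of global moment estimates of the
#' training data; the initial distribution and within-block transition rows
#' are jittered uniform distributions. No clustering is involved, so restarts
#' explore genuinely different basins.
#'
#' @param seqs list of labelled `obs_sequence`.
#' @param spec a [state_spec()].
#' @param seed integer seed.
#' @return a `block_hmm`.
#' @export
init_params <- function(seqs, spec, seed = 1L) {
  stopifnot(inherits(spec, "state_spec"))
  set.seed(seed)
  st <- .stack_seqs(seqs)
  gm <- .global_moments(st)
  n <- spec$n_lfrr + spec$n_rflr
  cls <- rep(.CLASSES, c(spec$n_lfrr, spec$n_rflr))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    blk <- which(cls == cls[i])
    A[i, blk] <- .floor_norm(runif(length(blk), 0.5, 1.5))
  }
  block_hmm(pi = .floor_norm(runif(n, 0.5, 1.5)), A = A,
            emissions = replicate(n, .perturbed_emission(gm), simplify = FALSE),
            class_of_state = cls)
}

#' Baum-Welch estimation of the block HMM from labelled sequences
#'
#' EM for the joint model in which each sequence's block membership is
#' observed: forward-backward responsibilities are confined to the labelled
#' block, the shared initial distribution is re-estimated across both blocks
#' (so it keeps encoding the class prior), and per-state emissions are
#' weighted maximum-likelihood updates. The maximized objective -- the joint
#' log-likelihood `sum_n log P(X_n, C_n | lambda)` -- is non-decreasing across
#' iterations.
#'
#' @param seqs list of labelled `obs_sequence`.
#' @param spec a [state_spec()] (used when `init` is `NULL`).
#' @param init optional starting `block_hmm`; defaults to [init_params()].
#' @param tol relative convergence tolerance on the objective.
#' @param max_iter maximum EM iterations.
#' @param seed seed for the default initialization.
#' @return fitted `block_hmm` with attribute `loglik_trace`.
#' @export
baum_welch <- function(seqs, spec = NULL, init = NULL, tol = 1e-6,
                       max_iter = 100L, seed = 1L) {
  if (is.null(init)) init <- init_params(seqs, spec, seed = seed)
  params <- init
  st <- .stack_seqs(seqs)
  if (any(!st$labels %in% .CLASSES)) stop("all sequences must be labelled")
  gm <- .global_moments(st)
  n <- length(params$pi)
  N <- length(seqs)
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    pi_counts <- numeric(n)
    swt <- sfd <- sfd2 <- swl <- ssl <- ssl2 <- numeric(n)
    aoi_counts <- sd_counts <- matrix(0, n, 4)
    trans <- matrix(0, n, n)
    ll <- 0
    for (cl in .CLASSES) {
      idx <- which(st$labels == cl)
      stats <- .estep_block(params, cl, st, idx, rep(1, length(idx)))
      blk <- stats$states
      ll <- ll + stats$loglik
      pi_counts[blk] <- pi_counts[blk] + stats$pi_counts
      trans[blk, blk] <- trans[blk, blk] + stats$trans
      swt[blk] <- stats$swt; sfd[blk] <- stats$sfd; sfd2[blk] <- stats$sfd2
      swl[blk] <- stats$swl; ssl[blk] <- stats$ssl; ssl2[blk] <- stats$ssl2
      aoi_counts[blk, ] <- stats$aoi_counts
      sd_counts[blk, ] <- stats$sd_counts
    }
    trace <- c(trace, ll)
    # M-step
    pi_new <- .floor_norm(pi_counts / N)
    A_new <- params$A
    em_new <- params$emissions
    for (i in seq_len(n)) {
      blk <- which(params$class_of_state == params$class_of_state[i])
      if (sum(trans[i, blk]) > 1e-10)
        A_new[i, blk] <- .floor_norm(trans[i, blk])
      if (swt[i] < 1e-8) {
        warning("state ", i, " starved; re-seeding its emissions")
        em_new[[i]] <- .perturbed_emission(gm)
        next
      }
      mu <- sfd[i] / swt[i]
      em_new[[i]]$mu_fd <- mu
      em_new[[i]]$sigma_fd <-
        sqrt(max(sfd2[i] / swt[i] - mu^2, 1e-6))
      if (swl[i] > 1e-8) {
        mus <- ssl[i] / swl[i]
        em_new[[i]]$mu_sl <- mus
        em_new[[i]]$sigma_sl <-
          sqrt(max(ssl2[i] / swl[i] - mus^2, 1e-6))
        em_new[[i]]$p_sd <- .floor_norm(sd_counts[i, ])
      }
      em_new[[i]]$p_aoi <- .floor_norm(aoi_counts[i, ])
    }
    params <- block_hmm(pi_new, A_new, em_new, params$class_of_state,
                        params$state_names)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
    ll_prev <- ll
  }
  attr(params, "loglik_trace") <- trace
  params
}

# ---- Discriminative (conditional-likelihood) training -----------------------

# Value and gradient of the mean conditional log-likelihood in the
# unconstrained parametrization (softmax logits for pi / transition rows /
# categorical emissions, identity for Gaussian means, log for sigmas).
# Numerator statistics come from forward-backward restricted to each
# sequence's labelled block; denominator statistics are the posterior-weighted
# mix of both blocks' statistics.
.cll_and_grad <- function(seqs, params, st = .stack_seqs(seqs)) {
  n <- length(params$pi)
  N <- length(seqs)
  m <- .class_logmass_batch(seqs, params, st)
  tot <- apply(m, 1, .logsumexp)
  w <- exp(m - tot)
  cll <- sum(m[cbind(seq_len(N), match(st$labels, .CLASSES))] - tot)

  zero_stats <- function() list(
    pi = numeric(n), trans = matrix(0, n, n), swt = numeric(n),
    sfd = numeric(n), sfd2 = numeric(n), swl = numeric(n), ssl = numeric(n),
    ssl2 = numeric(n), aoi = matrix(0, n, 4), sdc = matrix(0, n, 4))
  acc <- function(tot, stats) {
    blk <- stats$states
    tot$pi[blk] <- tot$pi[blk] + stats$pi_counts
    tot$trans[blk, blk] <- tot$trans[blk, blk] + stats$trans
    tot$swt[blk] <- tot$swt[blk] + stats$swt
    tot$sfd[blk] <- tot$sfd[blk] + stats$sfd
    tot$sfd2[blk] <- tot$sfd2[blk] + stats$sfd2
    tot$swl[blk] <- tot$swl[blk] + stats$swl
    tot$ssl[blk] <- tot$ssl[blk] + stats$ssl
    tot$ssl2[blk] <- tot$ssl2[blk] + stats$ssl2
    tot$aoi[blk, ] <- tot$aoi[blk, ] + stats$aoi_counts
    tot$sdc[blk, ] <- tot$sdc[blk, ] + stats$sd_counts
    tot
  }
  num <- den <- zero_stats()
  all_idx <- seq_len(N)
  for (cl in .CLASSES) {
    idx <- which(st$labels == cl)
    if (length(idx))
      num <- acc(num, .estep_block(params, cl, st, idx, rep(1, length(idx))))
    den <- acc(den, .estep_block(params, cl, st, all_idx, w[, cl]))
  }
  softmax_grad <- function(p, cnum, cden) {
    (cnum - p * sum(cnum)) - (cden - p * sum(cden))
  }
  g <- list(pi = (num$pi - den$pi) / N, A = matrix(0, n, n),
            mu_fd = numeric(n), lsig_fd = numeric(n),
            mu_sl = numeric(n), lsig_sl = numeric(n),
            p_aoi = matrix(0, n, 4), p_sd = matrix(0, n, 4))
  for (i in seq_len(n)) {
    blk <- which(params$class_of_state == params$class_of_state[i])
    g$A[i, blk] <- softmax_grad(params$A[i, blk],
                                num$trans[i, blk], den$trans[i, blk]) / N
    e <- params$emissions[[i]]
    gmu <- function(s, sw, mu, sig) (s - mu * sw) / sig^2
    gls <- function(s2, s, sw, mu, sig)
      (s2 - 2 * mu * s + mu^2 * sw) / sig^2 - sw
    g$mu_fd[i] <- (gmu(num$sfd[i], num$swt[i], e$mu_fd, e$sigma_fd) -
                   gmu(den$sfd[i], den$swt[i], e$mu_fd, e$sigma_fd)) / N
    g$lsig_fd[i] <- (gls(num$sfd2[i], num$sfd[i], num$swt[i], e$mu_fd, e$sigma_fd) -
                     gls(den$sfd2[i], den$sfd[i], den$swt[i], e$mu_fd, e$sigma_fd)) / N
    g$mu_sl[i] <- (gmu(num$ssl[i], num$swl[i], e$mu_sl, e$sigma_sl) -
                   gmu(den$ssl[i], den$swl[i], e$mu_sl, e$sigma_sl)) / N
    g$lsig_sl[i] <- (gls(num$ssl2[i], num$ssl[i], num$swl[i], e$mu_sl, e$sigma_sl) -
                     gls(den$ssl2[i], den$ssl[i], den$swl[i], e$mu_sl, e$sigma_sl)) / N
    g$p_aoi[i, ] <- softmax_grad(e$p_aoi, num$aoi[i, ], den$aoi[i, ]) / N
    g$p_sd[i, ] <- softmax_grad(e$p_sd, num$sdc[i, ], den$sdc[i, ]) / N
  }
  list(cll = cll, grad = g)
}

.apply_step <- function(params, g, lr) {
  n <- length(params$pi)
  softstep <- function(p, gv) .floor_norm(exp(log(pmax(p, .PROB_FLOOR)) + lr * gv))
  pi_new <- softstep(params$pi, g$pi)
  A_new <- params$A
  em_new <- params$emissions
  for (i in seq_len(n)) {
    blk <- which(params$class_of_state == params$class_of_state[i])
    A_new[i, blk] <- softstep(params$A[i, blk], g$A[i, blk])
    e <- em_new[[i]]
    e$mu_fd <- e$mu_fd + lr * g$mu_fd[i]
    e$sigma_fd <- min(max(e$sigma_fd * exp(lr * g$lsig_fd[i]), 1e-3), 10)
    e$mu_sl <- e$mu_sl + lr * g$mu_sl[i]
    e$sigma_sl <- min(max(e$sigma_sl * exp(lr * g$lsig_sl[i]), 1e-3), 10)
    e$p_aoi <- softstep(e$p_aoi, g$p_aoi[i, ])
    e$p_sd <- softstep(e$p_sd, g$p_sd[i, ])
    em_new[[i]] <- e
  }
  block_hmm(pi_new, A_new, em_new, params$class_of_state, params$state_names)
}

#' Discriminative refinement of a fitted block HMM
#'
#' Gradient ascent on the conditional log-likelihood `sum_n log P(C_n | X_n,
#' lambda)` in an unconstrained reparametrization (softmax logits for all
#' probability vectors, log scale for the Gaussian sigmas), so parameters stay
#' valid at every step. The analytic gradient is the difference between
#' expected sufficient statistics under the labelled block (numerator) and
#' under the full model (denominator). Steps that would decrease the
#' objective are rejected and the learning rate halved, so the objective is
#' non-decreasing across accepted steps; on repeated failure the best
#' parameters so far are returned with a warning.
#'
#' @param seqs list of labelled `obs_sequence`.
#' @param init starting `block_hmm`, typically the [baum_welch()] fit.
#' @param tol absolute convergence tolerance on the mean conditional
#'   log-likelihood improvement.
#' @param max_iter maximum accepted ascent steps.
#' @param lr initial learning rate.
#' @return refined `block_hmm` with attribute `cll_trace`.
#' @export
discriminative_train <- function(seqs, init, tol = 1e-7, max_iter = 100L,
                                 lr = 0.2) {
  params <- init
  st <- .stack_seqs(seqs)
  N <- length(seqs)
  cg <- .cll_and_grad(seqs, params, st)
  trace <- cg$cll
  for (it in seq_len(max_iter)) {
    accepted <- FALSE
    for (try in 1:30) {
      cand <- .apply_step(params, cg$grad, lr)
      cll_new <- conditional_log_likelihood(seqs, cand)
      if (is.finite(cll_new) && cll_new >= cg$cll - 1e-12) {
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    if (!accepted) {
      warning("discriminative_train: no ascent step found; returning best so far")
      break
    }
    improvement <- (cll_new - cg$cll) / N
    params <- cand
    cg <- .cll_and_grad(seqs, params, st)
    trace <- c(trace, cg$cll)
    lr <- min(lr * 1.2, 2)
    if (improvement < tol) break
  }
  attr(params, "cll_trace") <- trace
  attr(params, "loglik_trace") <- attr(init, "loglik_trace")
  params
}

#' Fit the discriminative HMM with restarts
#'
#' Convenience wrapper: multiple seeded Baum-Welch restarts (short screening
#' runs, then the best restart is run to convergence), followed by optional
#' discriminative refinement.
#'
#' @param seqs list of labelled `obs_sequence`.
#' @param spec a [state_spec()].
#' @param restarts number of random restarts (default 10).
#' @param seed integer; restart seeds are derived from it.
#' @param screen_iter EM iterations used to screen restarts.
#' @param max_iter EM iterations for the final run.
#' @param tol EM convergence tolerance.
#' @param refine run [discriminative_train()] after Baum-Welch?
#' @param disc_max_iter,disc_tol,lr settings passed to
#'   [discriminative_train()].
#' @return fitted `block_hmm`.
#' @export
fit_dhmm <- function(seqs, spec, restarts = 10L, seed = 1L, screen_iter = 25L,
                     max_iter = 1000L, tol = 1e-8, refine = TRUE,
                     disc_max_iter = 60L, disc_tol = 1e-7, lr = 0.2) {
  best <- NULL
  best_ll <- -Inf
  for (r in seq_len(restarts)) {
    fit <- baum_welch(seqs, spec, tol = tol, max_iter = screen_iter,
                      seed = seed + 1000L * (r - 1L))
    ll <- utils::tail(attr(fit, "loglik_trace"), 1)
    if (ll > best_ll) {
      best_ll <- ll
      best <- fit
    }
  }
  fit <- baum_welch(seqs, init = best, tol = tol, max_iter = max_iter)
  if (refine)
    fit <- discriminative_train(seqs, fit, tol = disc_tol,
                                max_iter = disc_max_iter, lr = lr)
  fit
}

#' Match fitted states to a reference model by emission profile
#'
#' Hidden states are only identified up to permutation within their class
#' block; before comparing a fit with a reference parameterization the states
#' must be aligned. The permutation minimizing the summed L1 distance between
#' saccade-direction rows (plus a scaled log-duration-mean term to break
#' near-ties) is returned.
#'
#' @param fit,ref `block_hmm` objects with equally sized blocks.
#' @param class `"LFRR"` or `"RFLR"`.
#' @return integer vector: for each state of `ref`'s block (in order), the
#'   index of the matched state of `fit`.
#' @export
match_states <- function(fit, ref, class = "LFRR") {
  blk_f <- block_states(fit, class)
  blk_r <- block_states(ref, class)
  k <- length(blk_r)
  if (length(blk_f) != k) stop("blocks differ in size")
  perms <- .perms(k)
  best <- Inf
  out <- NULL
  for (pm in perms) {
    d <- sum(vapply(seq_len(k), function(i) {
      ef <- fit$emissions[[blk_f[pm[i]]]]
      er <- ref$emissions[[blk_r[i]]]
      sum(abs(ef$p_sd - er$p_sd)) + 0.5 * abs(ef$mu_fd - er$mu_fd)
    }, numeric(1)))
    if (d < best) { best <- d; out <- blk_f[pm] }
  }
  out
}

.perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k))
    for (rest in .perms(k - 1))
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[rest])
  out
}

# ---- Generative sampling ----------------------------------------------------

#' Sample one observation sequence from a block HMM
#'
#' The state path is drawn from the class block (initial distribution
#' renormalized within the block); each state emits log fixation duration and
#' log saccade length from its Gaussians and a saccade direction from its
#' categorical. Two AOI regimes are available. Under `aoi_mode =
#' "independent"` (the default) every fixation's AOI is drawn from its
#' state's occupancy distribution, exactly matching the model's conditional
#' independence assumption -- the regime to use when validating estimators,
#' since the generating parameters are then the maximum-likelihood target.
#' Under `aoi_mode = "chained"` only the first AOI is drawn and every
#' subsequent AOI is the one implied by the sampled saccade-direction code,
#' yielding a geometrically self-consistent scanpath (re-coding it recovers
#' the same SD stream exactly) at the cost of AOI serial dependence the model
#' does not describe.
#'
#' @param params a `block_hmm`.
#' @param class `"LFRR"` or `"RFLR"`.
#' @param length number of fixations (>= 1).
#' @param subject_id,trial_id identifiers attached to the sequence.
#' @param aoi_mode `"independent"` or `"chained"` (see Details).
#' @return an `obs_sequence` with the hidden path in attribute `states`.
#' @export
sample_sequence <- function(params, class, length, subject_id = "sim",
                            trial_id = "t1",
                            aoi_mode = c("independent", "chained")) {
  aoi_mode <- match.arg(aoi_mode)
  stopifnot(inherits(params, "block_hmm"), length >= 1, class %in% .CLASSES)
  blk <- block_states(params, class)
  pi_b <- params$pi[blk] / sum(params$pi[blk])
  states <- integer(length)
  states[1] <- blk[sample.int(length(blk), 1L, prob = pi_b)]
  if (length > 1)
    for (t in 2:length)
      states[t] <- blk[sample.int(length(blk), 1L,
                                  prob = params$A[states[t - 1], blk])]
  log_fd <- log_sl <- numeric(length)
  aoi <- sdc <- integer(length)
  for (t in seq_len(length)) {
    e <- params$emissions[[states[t]]]
    log_fd[t] <- rnorm(1, e$mu_fd, e$sigma_fd)
    if (t == 1 || aoi_mode == "independent")
      aoi[t] <- sample(1:4, 1, prob = e$p_aoi)
    if (t < length) {
      log_sl[t] <- rnorm(1, e$mu_sl, e$sigma_sl)
      sdc[t] <- sample(1:4, 1, prob = e$p_sd)
      if (aoi_mode == "chained") aoi[t + 1] <- sd_target_aoi(aoi[t], sdc[t])
    }
  }
  ev <- data.frame(log_fd = log_fd,
                   log_sl = c(if (length > 1) log_sl[-length], NA_real_),
                   aoi = aoi,
                   sd = c(if (length > 1) sdc[-length], NA_integer_))
  out <- obs_sequence(ev, strategy = class, subject_id = subject_id,
                      trial_id = trial_id)
  attr(out, "states") <- states
  out
}
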