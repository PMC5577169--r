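# Small model builders shared across test files.

# tiny Dirichlet(1,..,1) draw
rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# A valid random block HMM with n1 + n2 states.
random_block_hmm <- function(n1 = 2, n2 = 2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  cls <- rep(c("LFRR", "RFLR"), c(n1, n2))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    blk <- which(cls == cls[i])
    A[i, blk] <- as.numeric(stats::rgamma(length(blk), 2))
    A[i, blk] <- A[i, blk] / sum(A[i, blk])
  }
  em <- lapply(seq_len(n), function(i) list(
    mu_fd = rnorm(1, 5, 1), sigma_fd = runif(1, 0.3, 0.8),
    mu_sl = rnorm(1, 4, 1), sigma_sl = runif(1, 0.3, 0.8),
    p_aoi = rdirichlet1(4),
    p_sd = rdirichlet1(4)))
  pi <- as.numeric(stats::rgamma(n, 2))
  block_hmm(pi / sum(pi), A, em, cls)
}

# A sequence with given feature columns (last event sd/log_sl NA'd).
make_seq <- function(log_fd, aoi, log_sl = NULL, sd = NULL,
                     strategy = "LFRR") {
  T <- length(log_fd)
  if (is.null(log_sl)) log_sl <- rep(0.5, T)
  if (is.null(sd)) sd <- rep(1L, T)
  log_sl[T] <- NA_real_
  sd[T] <- NA_integer_
  if (T == 1) { log_sl <- NA_real_; sd <- NA_integer_ }
  obs_sequence(data.frame(log_fd = log_fd, log_sl = log_sl,
                          aoi = as.integer(aoi), sd = as.integer(sd)),
               strategy = strategy)
}

# Simulated labelled corpus from the default model (independent AOI mode).
sim_corpus <- function(n_per_class, seed, ...) {
  simulate_corpus(generator_config(n_per_class = n_per_class, seed = seed,
                                   ...))
}

# Match the states of one class block of a fit to a reference model by
# saccade-direction profile; returns fitted indices ordered like the
# reference block.
match_block_states <- function(fit, ref, class = "LFRR") {
  blk_f <- block_states(fit, class)
  blk_r <- block_states(ref, class)
  k <- length(blk_r)
  stopifnot(length(blk_f) == k)
  perms <- .permutations(k)
  best <- Inf; out <- NULL
  for (pm in perms) {
    d <- sum(vapply(seq_len(k), function(i)
      sum(abs(fit$emissions[[blk_f[pm[i]]]]$p_sd -
              ref$emissions[[blk_r[i]]]$p_sd)), numeric(1)))
    if (d < best) { best <- d; out <- blk_f[pm] }
  }
  out
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k))
    for (rest in .permutations(k - 1))
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[rest])
  out
}
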