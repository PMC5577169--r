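# Independent oracles: deliberately naive implementations used only to check
# the package's fast paths.

# Ray-casting point-in-polygon (even-odd rule), written independently of the
# package's containment code.
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Hand-written saccade-direction lookup over all 16 ordered AOI pairs
# (1 = L1, 2 = L2, 3 = R1, 4 = R2).
oracle_sd_table <- matrix(c(
  # to: L1 L2 R1 R2      from:
        1L, 2L, 3L, 4L,    # L1
        2L, 1L, 4L, 3L,    # L2
        3L, 4L, 1L, 2L,    # R1
        4L, 3L, 2L, 1L),   # R2
  nrow = 4, byrow = TRUE)

# Brute-force HMM likelihood by explicit enumeration of all state paths.
# logB: T x n matrix of emission log-densities; pi may be unnormalized mass.
oracle_forward <- function(pi, A, logB) {
  T <- nrow(logB); n <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  total <- 0
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    lp <- log(pi[s[1]]) + logB[1, s[1]]
    if (T > 1) for (t in 2:T) lp <- lp + log(A[s[t - 1], s[t]]) + logB[t, s[t]]
    total <- total + exp(lp)
    if (lp > best) { best <- lp; best_path <- s }
  }
  list(loglik = log(total), best_logprob = best, best_path = best_path)
}

# Emission log-density for a single sequence, recomputed naively from the
# parameter list (final event: duration and AOI factors only).
oracle_logB <- function(params, states, events) {
  T <- nrow(events)
  out <- matrix(0, T, length(states))
  for (k in seq_along(states)) {
    e <- params$emissions[[states[k]]]
    for (t in seq_len(T)) {
      v <- dnorm(events$log_fd[t], e$mu_fd, e$sigma_fd, log = TRUE) +
        log(e$p_aoi[events$aoi[t]])
      if (!is.na(events$sd[t]))
        v <- v + dnorm(events$log_sl[t], e$mu_sl, e$sigma_sl, log = TRUE) +
          log(e$p_sd[events$sd[t]])
      out[t, k] <- v
    }
  }
  out
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating all group
# assignments (tiny samples, no ties).
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Exact one-sided-to-two-sided signed-rank p by enumeration of sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}
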