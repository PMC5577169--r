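#' Hidden-state configuration of the block HMM
#'
#' @param n_lfrr,n_rflr number of hidden states in the LFRR and RFLR
#'   sub-models (each >= 1).
#' @return object of class `state_spec`.
#' @export
state_spec <- function(n_lfrr, n_rflr) {
  stopifnot(n_lfrr >= 1, n_rflr >= 1)
  structure(list(n_lfrr = as.integer(n_lfrr), n_rflr = as.integer(n_rflr)),
            class = "state_spec")
}

#' @export
print.state_spec <- function(x, ...) {
  cat(sprintf("state spec {%d-%d} (%d states total)\n",
              x$n_lfrr, x$n_rflr, x$n_lfrr + x$n_rflr))
  invisible(x)
}

#' The state-count grid used for model selection
#'
#' @return list of [state_spec()] objects:
#'   `{2-2, 2-3, 3-3, 3-4, 4-4, 4-5, 5-5}`.
#' @export
default_state_grid <- function() {
  lapply(list(c(2, 2), c(2, 3), c(3, 3), c(3, 4), c(4, 4), c(4, 5), c(5, 5)),
         function(p) state_spec(p[1], p[2]))
}

.PROB_FLOOR <- 1e-12

.floor_norm <- function(p, floor = .PROB_FLOOR) {
  p <- pmax(p, floor)
  p / sum(p)
}

#' Parameters of the block-structured (discriminative) HMM
#'
#' One joint HMM whose hidden states are partitioned into an LFRR block and an
#' RFLR block. The initial distribution `pi` spans both blocks and therefore
#' encodes the class prior; the transition matrix is block-diagonal, so a
#' state path never crosses between classes. Each state emits, conditionally
#' independently: log fixation duration (Gaussian), log saccade length
#' (Gaussian), an AOI category and a saccade-direction category (two
#' 4-category distributions). The final fixation of a trial has no outgoing
#' saccade, so its saccade-length and saccade-direction factors are omitted
#' from the likelihood.
#'
#' @param pi initial distribution over all states (normalized internally).
#' @param A full transition matrix; mass between states of different blocks
#'   must be zero. Rows are normalized internally.
#' @param emissions list (one element per state) with fields `mu_fd`,
#'   `sigma_fd`, `mu_sl`, `sigma_sl`, `p_aoi` (4-vector), `p_sd` (4-vector).
#' @param class_of_state character vector mapping each state to `"LFRR"` or
#'   `"RFLR"`; LFRR states must come first.
#' @param state_names optional labels (e.g. `"e"`, `"c"`, `"s"`).
#' @return object of class `block_hmm`.
#' @export
block_hmm <- function(pi, A, emissions, class_of_state, state_names = NULL) {
  n <- length(pi)
  stopifnot(nrow(A) == n, ncol(A) == n, length(emissions) == n,
            length(class_of_state) == n)
  if (!all(class_of_state %in% c("LFRR", "RFLR")))
    stop("class_of_state entries must be LFRR or RFLR")
  if (is.unsorted(match(class_of_state, c("LFRR", "RFLR"))))
    stop("LFRR states must precede RFLR states")
  if (!any(class_of_state == "LFRR") || !any(class_of_state == "RFLR"))
    stop("each class needs at least one state")
  for (i in seq_len(n)) for (j in seq_len(n))
    if (class_of_state[i] != class_of_state[j] && A[i, j] != 0)
      stop("validation error: transition mass between blocks must be zero")
  if (any(pi < 0) || sum(pi) <= 0) stop("validation error: invalid pi")
  em <- lapply(emissions, function(e) {
    stopifnot(all(c("mu_fd", "sigma_fd", "mu_sl", "sigma_sl",
                    "p_aoi", "p_sd") %in% names(e)))
    if (e$sigma_fd <= 0 || e$sigma_sl <= 0)
      stop("validation error: sigmas must be positive")
    e$p_aoi <- .floor_norm(as.numeric(e$p_aoi))
    e$p_sd <- .floor_norm(as.numeric(e$p_sd))
    e[c("mu_fd", "sigma_fd", "mu_sl", "sigma_sl", "p_aoi", "p_sd")]
  })
  Anorm <- A
  for (i in seq_len(n)) {
    blk <- which(class_of_state == class_of_state[i])
    Anorm[i, blk] <- .floor_norm(A[i, blk])
  }
  structure(list(pi = pi / sum(pi), A = Anorm, emissions = em,
                 class_of_state = class_of_state,
                 state_names = state_names %||% as.character(seq_len(n))),
            class = "block_hmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.block_hmm <- function(x, digits = 3, ...) {
  n <- length(x$pi)
  cat(sprintf("block HMM: %d LFRR + %d RFLR states\n",
              sum(x$class_of_state == "LFRR"), sum(x$class_of_state == "RFLR")))
  cat("pi:", round(x$pi, digits), "\n")
  for (i in seq_len(n)) {
    e <- x$emissions[[i]]
    cat(sprintf("  state %s (%s): FD med %.0f ms, SL med %.0f px, p_sd = %s\n",
                x$state_names[i], x$class_of_state[i], exp(e$mu_fd),
                exp(e$mu_sl), paste(round(e$p_sd, 2), collapse = " ")))
  }
  invisible(x)
}

#' Indices of the states belonging to one class block
#' @param params a `block_hmm`.
#' @param class `"LFRR"` or `"RFLR"`.
#' @return integer vector of state indices.
#' @export
block_states <- function(params, class) {
  which(params$class_of_state == class)
}

#' Read / write block-HMM parameters as JSON
#'
#' The JSON object stores `pi`, the full transition matrix `A` (row-major
#' list of rows), per-state emissions and the state-to-class map; reading a
#' written file reproduces the parameters exactly.
#'
#' @param path file path.
#' @export
read_hmm_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  block_hmm(pi = j$pi, A = do.call(rbind, lapply(seq_along(j$pi), function(i)
              as.numeric(j$A[i, ]))),
            emissions = lapply(seq_along(j$pi), function(i) {
              e <- j$emissions[i, ]
              list(mu_fd = e$mu_fd, sigma_fd = e$sigma_fd, mu_sl = e$mu_sl,
                   sigma_sl = e$sigma_sl, p_aoi = as.numeric(e$p_aoi[[1]]),
                   p_sd = as.numeric(e$p_sd[[1]]))
            }),
            class_of_state = j$class_of_state, state_names = j$state_names)
}

#' @rdname read_hmm_params
#' @param params a `block_hmm`.
#' @export
write_hmm_params <- function(params, path) {
  stopifnot(inherits(params, "block_hmm"))
  j <- list(pi = params$pi, A = params$A,
            emissions = do.call(rbind, lapply(params$emissions, function(e)
              data.frame(mu_fd = e$mu_fd, sigma_fd = e$sigma_fd,
                         mu_sl = e$mu_sl, sigma_sl = e$sigma_sl,
                         p_aoi = I(list(e$p_aoi)), p_sd = I(list(e$p_sd))))),
            class_of_state = params$class_of_state,
            state_names = params$state_names)
  jsonlite::write_json(j, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
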