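#' Default block-HMM parameters from the published model estimates
#'
#' Three hidden states per strategy -- encoding-and-searching (`e`),
#' comparison (`c`) and searching-on-one-side (`s`) -- with the reported
#' initial probabilities, per-state AOI-occupancy and saccade-direction
#' distributions, and log-normal fixation-duration / saccade-length emissions
#' whose medians are the reported per-state values. The printed initial
#' probabilities sum to 99% over the six states and are renormalized to 1, so
#' the joint initial distribution doubles as the class prior. Only the four
#' reported leave-probabilities of the `e` and `s` states pin down the
#' transition rows; leave mass is split equally between the two other states
#' of the block, and the `c` rows are uniform over their block. The reported
#' dispersion notation for durations and lengths does not identify the
#' log-scale spread, so both log-sigmas default to 0.5 and are configurable.
#'
#' @param fd_log_sigma,sl_log_sigma log-scale standard deviations of the
#'   fixation-duration and saccade-length emissions.
#' @param zero_floor floor applied to zero cells of the reported categorical
#'   rows before renormalization (exact zeros would make the generator
#'   degenerate).
#' @return a [block_hmm()] with state names `e`, `c`, `s` per block.
#' @export
default_params <- function(fd_log_sigma = 0.5, sl_log_sigma = 0.5,
                           zero_floor = 1e-3) {
  pi_raw <- c(0.09, 0.05, 0.35, 0.15, 0.04, 0.31)  # e, c, s per block
  fd_med <- c(96, 170, 179, 108, 162, 172)   # ms
  sl_med <- c(37, 67, 52, 33, 69, 59)        # px
  p_aoi <- list(c(.44, .14, .29, .13), c(.28, .21, .31, .20),
                c(.18, .18, .39, .26),
                c(.57, .14, .21, .08), c(.32, .21, .30, .17),
                c(.46, .22, .18, .14))
  p_sd <- list(c(.89, .04, .05, .02), c(.00, .01, .68, .31),
               c(.56, .43, .00, .01),
               c(.94, .03, .02, .01), c(.02, .01, .66, .31),
               c(.43, .49, .05, .03))
  # transition rows (e, c, s order): leave-probability from e is .68 (LFRR) /
  # .60 (RFLR) and from s .71 / .78, split equally over the two other states;
  # comparison rows are uniform.
  blk <- function(leave_e, leave_s) {
    rbind(c(1 - leave_e, leave_e / 2, leave_e / 2),
          rep(1 / 3, 3),
          c(leave_s / 2, leave_s / 2, 1 - leave_s))
  }
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- blk(0.68, 0.71)
  A[4:6, 4:6] <- blk(0.60, 0.78)
  em <- lapply(1:6, function(i) list(
    mu_fd = log(fd_med[i]), sigma_fd = fd_log_sigma,
    mu_sl = log(sl_med[i]), sigma_sl = sl_log_sigma,
    p_aoi = .floor_norm(p_aoi[[i]], zero_floor),
    p_sd = .floor_norm(p_sd[[i]], zero_floor)))
  block_hmm(pi = pi_raw / sum(pi_raw), A = A, emissions = em,
            class_of_state = rep(c("LFRR", "RFLR"), each = 3),
            state_names = rep(c("e", "c", "s"), 2))
}

#' Generator configuration for synthetic corpora
#'
#' @param params generating [block_hmm()]; defaults to [default_params()].
#' @param n_per_class sequences per strategy (default 840, for a corpus of
#'   1680 emulating 15 subjects x 2 sessions x 56 trials).
#' @param length_mean,length_size negative-binomial mean and dispersion of
#'   sequence length (minimum 1; the defaults allow the one-or-two-fixation
#'   trials seen at small angular disparities).
#' @param n_subjects subject identifiers attached round-robin.
#' @param layout AOI layout used when raw coordinate tables are emitted.
#' @param train_frac training fraction of the stratified split (default 0.8,
#'   i.e. 1344/336 at the default corpus size).
#' @param rt_intercept,rt_slope,rt_noise_sd reaction-time model: intercept
#'   (ms), angle-effect slope (ms/degree) and Gaussian noise SD (ms).
#' @param aoi_mode AOI sampling regime, see [sample_sequence()]:
#'   `"independent"` (default; generator matches the model's emission
#'   assumptions, appropriate for parameter-recovery studies) or `"chained"`
#'   (geometrically self-consistent scanpaths; required when emitting raw
#'   coordinate tables).
#' @param seed mandatory integer seed; corpora are exactly reproducible from
#'   the configuration.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(params = default_params(), n_per_class = 840L,
                             length_mean = 20, length_size = 5,
                             n_subjects = 15L, layout = default_aoi_layout(),
                             train_frac = 0.8, rt_intercept = 1500,
                             rt_slope = 13.340, rt_noise_sd = 300,
                             aoi_mode = c("independent", "chained"), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(params, "block_hmm"), n_per_class >= 1,
            train_frac > 0, train_frac < 1)
  structure(list(params = params, n_per_class = as.integer(n_per_class),
                 length_mean = length_mean, length_size = length_size,
                 n_subjects = as.integer(n_subjects), layout = layout,
                 train_frac = train_frac, rt_intercept = rt_intercept,
                 rt_slope = rt_slope, rt_noise_sd = rt_noise_sd,
                 aoi_mode = match.arg(aoi_mode), seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate one trial
#'
#' Wraps [sample_sequence()] with the configured generating model and,
#' optionally, emits a raw fixation-table block whose coordinates are placed
#' uniformly inside each fixation's AOI region; under `aoi_mode = "chained"`
#' re-extracting the raw rows reproduces the generated AOI and
#' saccade-direction streams exactly, so raw emission requires that mode.
#' Uses the current RNG state; seed outside.
#'
#' @param config a [generator_config()].
#' @param class `"LFRR"` or `"RFLR"`.
#' @param length number of fixations; drawn from the configured length
#'   distribution when `NULL`.
#' @param raw also return raw fixation rows?
#' @param subject_id,trial_id identifiers.
#' @return an `obs_sequence`; with `raw = TRUE`, a list with elements `seq`
#'   and `raw`.
#' @export
simulate_trial <- function(config, class, length = NULL, raw = FALSE,
                           subject_id = "S01", trial_id = "t1") {
  stopifnot(inherits(config, "generator_config"))
  if (raw && config$aoi_mode != "chained")
    stop("raw coordinate tables require aoi_mode = \"chained\" ",
         "(otherwise the emitted scanpath would contradict its own sd codes)")
  if (is.null(length))
    length <- max(1L, stats::rnbinom(1, mu = config$length_mean,
                                     size = config$length_size))
  s <- sample_sequence(config$params, class, length, subject_id, trial_id,
                       aoi_mode = config$aoi_mode)
  if (!raw) return(s)
  xy <- t(vapply(s$events$aoi, function(a) {
    r <- config$layout$regions[[a]]
    if (r$type == "rect")
      c(runif(1, r$rect[1], r$rect[3]), runif(1, r$rect[2], r$rect[4]))
    else {
      repeat {
        bb <- .region_bbox(r)
        p <- c(runif(1, bb[1], bb[3]), runif(1, bb[2], bb[4]))
        if (.point_in_region(p[1], p[2], r)) return(p)
      }
    }
  }, numeric(2)))
  dur <- exp(s$events$log_fd)
  raw_tab <- data.frame(
    subject_id = subject_id, strategy = class, trial_id = trial_id,
    fixation_index = seq_len(length) - 1L,
    onset_ms = cumsum(c(0, utils::head(dur, -1) + 20)),  # 20 ms saccade gap
    duration_ms = dur, x_px = xy[, 1], y_px = xy[, 2])
  list(seq = s, raw = raw_tab)
}

#' Simulate a labelled corpus with a stratified train/test split
#'
#' Balanced classes; sequence lengths negative-binomial (minimum 1); subject
#' identifiers attached round-robin; a seeded stratified split into training
#' and test sets (80/20 by default: 1344/336 sequences at the default corpus
#' size of 1680).
#'
#' @param config a [generator_config()].
#' @param raw also emit the raw fixation table?
#' @return list with `sequences`, logical `is_train`, and (with `raw = TRUE`)
#'   a `raw` data.frame.
#' @export
simulate_corpus <- function(config, raw = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_per_class
  classes <- rep(.CLASSES, each = n)
  subjects <- sprintf("S%02d", (seq_along(classes) - 1L) %% config$n_subjects + 1L)
  seqs <- vector("list", length(classes))
  raws <- if (raw) vector("list", length(classes))
  for (i in seq_along(classes)) {
    tr <- simulate_trial(config, classes[i], raw = raw,
                         subject_id = subjects[i],
                         trial_id = sprintf("%s_%04d", classes[i], i))
    if (raw) {
      seqs[[i]] <- tr$seq
      raws[[i]] <- tr$raw
    } else seqs[[i]] <- tr
  }
  n_train <- round(config$train_frac * n)
  is_train <- logical(length(classes))
  for (cl in .CLASSES) {
    idx <- which(classes == cl)
    is_train[sample(idx, n_train)] <- TRUE
  }
  out <- list(sequences = seqs, is_train = is_train)
  if (raw) out$raw <- do.call(rbind, raws)
  out
}

#' The 56-condition stimulus design
#'
#' @param angles angular disparities in degrees.
#' @param axes rotation axes.
#' @param identities identical versus mirrored pairs.
#' @param symmetries left- versus right-shifted placements (controls for
#'   object location).
#' @return object of class `stimulus_design` holding the factor levels:
#'   7 angular disparities x 2 rotation axes x 2 identities x 2 symmetries.
#' @export
stimulus_design <- function(angles = seq(0, 180, by = 30),
                            axes = c("x", "z"),
                            identities = c("identical", "mirrored"),
                            symmetries = c("left-shift", "right-shift")) {
  structure(list(angles = angles, axes = axes, identities = identities,
                 symmetries = symmetries), class = "stimulus_design")
}

#' Enumerate the full-factorial stimulus conditions
#'
#' @param design a [stimulus_design()].
#' @return data.frame with one row per condition (56 for the default design),
#'   in stable column-major factorial order.
#' @export
enumerate_stimuli <- function(design = stimulus_design()) {
  stopifnot(inherits(design, "stimulus_design"))
  g <- expand.grid(angle = design$angles, axis = design$axes,
                   identity = design$identities, symmetry = design$symmetries,
                   stringsAsFactors = FALSE)
  out <- g[order(g$angle, g$axis, g$identity, g$symmetry),
           c("angle", "axis", "identity", "symmetry")]
  rownames(out) <- NULL
  out
}

#' Simulate reaction times with a linear angle effect
#'
#' `RT = intercept + slope * angle + N(0, noise_sd)`, truncated at the 8000 ms
#' response deadline. Uses the current RNG state; seed outside.
#'
#' @param design a [stimulus_design()] supplying the angles.
#' @param slope angle-effect slope in ms/degree (>= 0).
#' @param intercept intercept in ms.
#' @param noise_sd Gaussian noise SD in ms (>= 0).
#' @param n_subjects subjects.
#' @param trials_per_angle trials per subject per angle.
#' @return data.frame with `subject`, `angle`, `rt_ms`.
#' @export
simulate_rt <- function(design = stimulus_design(), slope, intercept = 1500,
                        noise_sd = 300, n_subjects = 15L,
                        trials_per_angle = 8L) {
  stopifnot(slope >= 0, noise_sd >= 0)
  g <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   angle = design$angles,
                   trial = seq_len(trials_per_angle),
                   stringsAsFactors = FALSE)
  rt <- intercept + slope * g$angle + rnorm(nrow(g), 0, noise_sd)
  data.frame(subject = g$subject, angle = g$angle,
             rt_ms = pmin(rt, 8000))
}
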