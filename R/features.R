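#' Four-category saccade-direction code
#'
#' Each saccade between two AOI-assigned fixations is coded by the relation
#' between source and target region: SD-1 stays within the same AOI, SD-2
#' moves to the other AOI of the same figure, SD-3 moves to the corresponding
#' AOI of the other figure (L1-R1, L2-R2), and SD-4 moves to the transformed
#' AOI of the other figure (L1-R2, L2-R1).
#'
#' @param aoi_from,aoi_to integer AOI categories in 1..4 (vectorized).
#' @return integer vector of SD codes in 1..4.
#' @export
code_saccade_direction <- function(aoi_from, aoi_to) {
  if (any(!aoi_from %in% 1:4) || any(!aoi_to %in% 1:4))
    stop("coding error: AOI categories must be in 1..4 (filter OUTSIDE first)")
  same_fig <- (aoi_from <= 2) == (aoi_to <= 2)
  out <- ifelse(aoi_from == aoi_to, 1L,
         ifelse(same_fig, 2L,
         ifelse(abs(aoi_from - aoi_to) == 2L, 3L, 4L)))
  as.integer(out)
}

#' Target AOI implied by a saccade-direction code
#'
#' Inverse of [code_saccade_direction()]: for a fixed source AOI the four SD
#' codes map one-to-one onto the four target AOIs.
#'
#' @param aoi_from integer AOI in 1..4 (vectorized).
#' @param sd integer SD code in 1..4 (vectorized).
#' @return integer target AOI.
#' @export
sd_target_aoi <- function(aoi_from, sd) {
  if (any(!aoi_from %in% 1:4) || any(!sd %in% 1:4))
    stop("coding error: inputs must be in 1..4")
  within_other <- ifelse(aoi_from %% 2L == 1L, aoi_from + 1L, aoi_from - 1L)
  corresponding <- ifelse(aoi_from <= 2L, aoi_from + 2L, aoi_from - 2L)
  out <- ifelse(sd == 1L, aoi_from,
         ifelse(sd == 2L, within_other,
         ifelse(sd == 3L, corresponding, 5L - aoi_from)))
  as.integer(out)
}

#' Construct an observation sequence
#'
#' One trial's ordered per-fixation feature vectors: natural-log fixation
#' duration (ms), natural-log outgoing saccade length (px), AOI category and
#' outgoing saccade-direction code. The final fixation has no outgoing
#' saccade, so its `log_sl` and `sd` are `NA`.
#'
#' @param events data.frame with columns `log_fd`, `log_sl`, `aoi`, `sd`.
#' @param strategy class label, `"LFRR"` or `"RFLR"` (or `NA` for unlabelled).
#' @param subject_id,trial_id identifiers.
#' @return an object of class `obs_sequence`.
#' @export
obs_sequence <- function(events, strategy = NA_character_,
                         subject_id = NA_character_, trial_id = NA_character_) {
  stopifnot(is.data.frame(events),
            all(c("log_fd", "log_sl", "aoi", "sd") %in% names(events)))
  T <- nrow(events)
  if (T < 1L) stop("empty-sequence error: a trial needs at least one fixation")
  if (!is.na(strategy) && !strategy %in% c("LFRR", "RFLR"))
    stop("strategy must be LFRR or RFLR")
  if (any(is.na(events$log_fd)) || any(!events$aoi %in% 1:4))
    stop("log_fd must be finite and aoi in 1..4 for every event")
  if (T > 1L && (any(is.na(events$sd[-T])) || any(is.na(events$log_sl[-T]))))
    stop("only the final event may lack sd/log_sl")
  if (!is.na(events$sd[T]) || !is.na(events$log_sl[T]))
    stop("the final event must lack sd and log_sl")
  structure(list(subject_id = subject_id, strategy = strategy,
                 trial_id = trial_id, events = events),
            class = "obs_sequence")
}

#' @export
print.obs_sequence <- function(x, ...) {
  cat(sprintf("obs_sequence: subject %s, trial %s, strategy %s, T = %d\n",
              x$subject_id, x$trial_id, x$strategy, nrow(x$events)))
  invisible(x)
}

#' Extract an observation sequence from one trial's fixation table
#'
#' Fixations are assigned to AOIs; those outside every region are dropped
#' (default) or snapped to the nearest region within `snap_px`. Saccade length
#' is the Euclidean distance between consecutive retained fixation
#' coordinates; durations and lengths enter the model on the natural-log
#' scale.
#'
#' @param fixations data.frame for a single trial with columns `onset_ms`,
#'   `duration_ms`, `x_px`, `y_px` (plus optional `subject_id`, `strategy`,
#'   `trial_id`).
#' @param layout an [aoi_layout()].
#' @param outside `"drop"` or `"snap"`.
#' @param snap_px maximum snapping distance (px) when `outside = "snap"`.
#' @return an `obs_sequence`.
#' @export
extract_sequence <- function(fixations, layout, outside = c("drop", "snap"),
                             snap_px = 50) {
  outside <- match.arg(outside)
  stopifnot(is.data.frame(fixations),
            all(c("onset_ms", "duration_ms", "x_px", "y_px") %in% names(fixations)))
  if (any(fixations$duration_ms <= 0)) stop("durations must be positive")
  if (is.unsorted(fixations$onset_ms, strictly = TRUE))
    stop("fixations must be strictly ordered by onset")
  aoi <- assign_aoi(fixations$x_px, fixations$y_px, layout)
  if (outside == "snap" && any(aoi == AOI_OUTSIDE)) {
    for (i in which(aoi == AOI_OUTSIDE)) {
      d <- vapply(layout$regions, function(r) {
        bb <- .region_bbox(r)
        dx <- pmax(bb[1] - fixations$x_px[i], 0, fixations$x_px[i] - bb[3])
        dy <- pmax(bb[2] - fixations$y_px[i], 0, fixations$y_px[i] - bb[4])
        sqrt(dx^2 + dy^2)
      }, numeric(1))
      if (min(d) <= snap_px) aoi[i] <- which.min(d)
    }
  }
  keep <- aoi != AOI_OUTSIDE
  if (!any(keep))
    stop("empty-sequence error: every fixation fell outside the AOIs")
  f <- fixations[keep, , drop = FALSE]
  aoi <- aoi[keep]
  T <- nrow(f)
  log_sl <- sd <- rep(NA_real_, T)
  if (T > 1L) {
    dx <- diff(f$x_px); dy <- diff(f$y_px)
    log_sl[-T] <- log(sqrt(dx^2 + dy^2))
    sd[-T] <- code_saccade_direction(aoi[-T], aoi[-1])
  }
  obs_sequence(
    data.frame(log_fd = log(f$duration_ms), log_sl = log_sl,
               aoi = as.integer(aoi), sd = as.integer(sd)),
    strategy = if ("strategy" %in% names(f)) f$strategy[1] else NA_character_,
    subject_id = if ("subject_id" %in% names(f)) as.character(f$subject_id[1]) else NA_character_,
    trial_id = if ("trial_id" %in% names(f)) as.character(f$trial_id[1]) else NA_character_)
}

#' Extract all trials of a fixation table
#'
#' @param fixation_table data.frame in the raw-table format (see
#'   [read_fixation_table()]).
#' @inheritParams extract_sequence
#' @return list of `obs_sequence`, one per (subject, trial).
#' @export
extract_sequences <- function(fixation_table, layout, outside = "drop",
                              snap_px = 50) {
  key <- paste(fixation_table$subject_id, fixation_table$trial_id, sep = "\r")
  parts <- split(fixation_table, factor(key, levels = unique(key)))
  out <- lapply(parts, extract_sequence, layout = layout, outside = outside,
                snap_px = snap_px)
  names(out) <- NULL
  out
}

#' Read / write raw fixation tables
#'
#' Tab-separated with header `subject_id, strategy, trial_id, fixation_index,
#' onset_ms, duration_ms, x_px, y_px`.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_fixation_table <- function(path) {
  cols <- c("subject_id", "strategy", "trial_id", "fixation_index",
            "onset_ms", "duration_ms", "x_px", "y_px")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(tab)))
    stop("fixation table must have columns: ", paste(cols, collapse = ", "))
  tab
}

#' @rdname read_fixation_table
#' @param tab data.frame of fixations.
#' @export
write_fixation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write extracted sequences as a per-fixation TSV
#'
#' One row per retained fixation with columns `subject_id, strategy, trial_id,
#' fixation_index, aoi, sd, log_fd, log_sl`.
#'
#' @param seqs list of `obs_sequence`.
#' @param path file path.
#' @export
write_sequences_tsv <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    cbind(data.frame(subject_id = s$subject_id, strategy = s$strategy,
                     trial_id = s$trial_id,
                     fixation_index = seq_len(nrow(s$events)) - 1L),
          s$events)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sequences written by [write_sequences_tsv()]
#' @param path file path.
#' @return list of `obs_sequence`.
#' @export
read_sequences_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(tab$subject_id, tab$trial_id, sep = "\r")
  parts <- split(tab, factor(key, levels = unique(key)))
  out <- lapply(parts, function(p) {
    ev <- p[, c("log_fd", "log_sl", "aoi", "sd")]
    rownames(ev) <- NULL
    obs_sequence(ev, strategy = p$strategy[1],
                 subject_id = as.character(p$subject_id[1]),
                 trial_id = as.character(p$trial_id[1]))
  })
  names(out) <- NULL
  out
}

#' Per-trial summary features for the baseline classifiers
#'
#' Five aggregates on the untransformed scales: number of fixations, mean and
#' sample standard deviation of fixation duration (ms), mean and sample
#' standard deviation of saccade length (px). With fewer than two saccades the
#' saccade SD (and with none, the mean) is 0 by convention.
#'
#' @param seq an `obs_sequence`.
#' @return data.frame with one row: `n_fix, mean_fd, sd_fd, mean_sl, sd_sl`.
#' @export
summary_features <- function(seq) {
  stopifnot(inherits(seq, "obs_sequence"))
  fd <- exp(seq$events$log_fd)
  sl <- exp(seq$events$log_sl)
  sl <- sl[!is.na(sl)]
  data.frame(
    n_fix = length(fd),
    mean_fd = mean(fd),
    sd_fd = if (length(fd) > 1) stats::sd(fd) else 0,
    mean_sl = if (length(sl) >= 1) mean(sl) else 0,
    sd_sl = if (length(sl) > 1) stats::sd(sl) else 0)
}

#' Feature matrix over a set of sequences
#'
#' @param seqs list of `obs_sequence` (labelled).
#' @return data.frame of the five summary features plus a `strategy` column.
#' @export
feature_matrix <- function(seqs) {
  X <- do.call(rbind, lapply(seqs, summary_features))
  X$strategy <- vapply(seqs, function(s) s$strategy, character(1))
  X
}

#' Read / write a feature matrix as TSV
#' @param path file path.
#' @export
read_feature_matrix <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_feature_matrix
#' @param X feature matrix data.frame.
#' @export
write_feature_matrix <- function(X, path) {
  utils::write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pooled AOI-occupancy and saccade-direction distributions per strategy
#'
#' Empirical frequencies of the four AOI categories (over all fixations) and
#' of the four SD codes (over all saccades), pooled within each class.
#'
#' @param seqs list of labelled `obs_sequence`.
#' @return named list per class, each with unit-sum 4-vectors `p_aoi`, `p_sd`.
#' @export
pooled_distributions <- function(seqs) {
  labs <- vapply(seqs, function(s) s$strategy, character(1))
  out <- lapply(c(LFRR = "LFRR", RFLR = "RFLR"), function(cl) {
    sub <- seqs[labs == cl]
    if (length(sub) == 0L) stop("empty class: ", cl)
    aoi <- unlist(lapply(sub, function(s) s$events$aoi))
    sd <- unlist(lapply(sub, function(s) s$events$sd))
    sd <- sd[!is.na(sd)]
    list(p_aoi = tabulate(aoi, 4) / length(aoi),
         p_sd = if (length(sd)) tabulate(sd, 4) / length(sd) else rep(NA_real_, 4))
  })
  out
}
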