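.FEATURE_COLS <- c("n_fix", "mean_fd", "sd_fd", "mean_sl", "sd_sl")

.check_features <- function(X) {
  stopifnot(is.data.frame(X), all(.FEATURE_COLS %in% names(X)),
            "strategy" %in% names(X))
  if (anyNA(X[, c(.FEATURE_COLS, "strategy")])) stop("missing values in features")
  if (length(unique(X$strategy)) < 2L)
    stop("single-class input: both strategies are required for fitting")
  invisible(X)
}

.standardize <- function(M, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(M, 2, center), 2, scale, "/")
}

#' Logistic-regression baseline on the summary features
#'
#' Unpenalized logistic regression of strategy on the five per-trial summary
#' features, standardized internally (so predictions are invariant to affine
#' rescaling of any input feature). Decision threshold 0.5.
#'
#' @param X feature matrix from [feature_matrix()] (five features plus a
#'   `strategy` column).
#' @return object of class `rotscan_logistic`.
#' @export
fit_logistic <- function(X) {
  .check_features(X)
  M <- as.matrix(X[, .FEATURE_COLS])
  center <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  Z <- as.data.frame(.standardize(M, center, scl))
  Z$y <- as.integer(X$strategy == "RFLR")
  fit <- suppressWarnings(stats::glm(y ~ ., data = Z, family = stats::binomial()))
  structure(list(fit = fit, center = center, scale = scl),
            class = "rotscan_logistic")
}

#' @rdname fit_logistic
#' @param model a fitted `rotscan_logistic`.
#' @param newdata feature matrix (the `strategy` column is ignored).
#' @return `predict_logistic`: list with `label` and `p_rflr`.
#' @export
predict_logistic <- function(model, newdata) {
  M <- as.matrix(newdata[, .FEATURE_COLS])
  Z <- as.data.frame(.standardize(M, model$center, model$scale))
  p <- suppressWarnings(
    stats::predict(model$fit, newdata = Z, type = "response"))
  list(label = ifelse(p > 0.5, "RFLR", "LFRR"), p_rflr = as.numeric(p))
}

#' Support-vector baseline on the summary features
#'
#' RBF-kernel SVM (cost 1 by default) on the standardized summary features;
#' kernel and regularization are exposed because the comparison design does
#' not pin them down.
#'
#' @inheritParams fit_logistic
#' @param kernel kernel name passed to [e1071::svm()].
#' @param cost regularization constant.
#' @param gamma kernel width; `NULL` uses the [e1071::svm()] default
#'   (1 / n-features).
#' @return object of class `rotscan_svm`.
#' @export
fit_svm <- function(X, kernel = "radial", cost = 1, gamma = NULL) {
  .check_features(X)
  M <- as.matrix(X[, .FEATURE_COLS])
  center <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  Z <- .standardize(M, center, scl)
  y <- factor(X$strategy, levels = c("LFRR", "RFLR"))
  args <- list(x = Z, y = y, kernel = kernel, cost = cost, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit, center = center, scale = scl),
            class = "rotscan_svm")
}

#' @rdname fit_svm
#' @param model a fitted `rotscan_svm`.
#' @param newdata feature matrix.
#' @return `predict_svm`: list with `label`.
#' @export
predict_svm <- function(model, newdata) {
  M <- as.matrix(newdata[, .FEATURE_COLS])
  Z <- .standardize(M, model$center, model$scale)
  list(label = as.character(stats::predict(model$fit, Z)))
}
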