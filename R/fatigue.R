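#' Threshold rule for fatigue detection
#'
#' The rule-based detector: the subject is flagged as fatigued as soon as
#' the heart rhythm becomes regular enough that the R-R variation
#' (max - min) of `k` consecutive measurements falls below `epsilon`
#' milliseconds. Defaults k = 10 beats and epsilon = 5 ms.
#'
#' @param stats an `hrv_windows` data.frame computed with window size `k`.
#' @param k window size the rule expects (default 10).
#' @param epsilon variation threshold in ms (default 5).
#' @return List with `flag` (TRUE if any window fired) and
#'   `first_trigger_index` (row index of the earliest firing window, or
#'   `NA` if none).
#' @examples
#' h <- hrv_windows(rr_series(rep(900, 11)), k = 10)
#' rule_fatigue(h)$flag  # TRUE: variation 0 < 5 ms
#' @export
rule_fatigue <- function(stats, k = 10, epsilon = 5) {
  stopifnot(inherits(stats, "hrv_windows"))
  if (!is_count(k, min = 2L) || !is_scalar_num(epsilon) || epsilon <= 0) {
    stop_invalid_parameter("k must be an integer >= 2 and epsilon > 0")
  }
  ws <- attr(stats, "window_size")
  if (is.null(ws) || ws != k) {
    stop_invalid_parameter(sprintf(
      "stats computed with window size %s but rule expects k = %d",
      ifelse(is.null(ws), "unknown", ws), k))
  }
  hit <- which(stats$variation < epsilon)
  list(flag = length(hit) > 0L,
       first_trigger_index = if (length(hit)) hit[1L] else NA_integer_)
}

#' HRV feature matrix for status classification
#'
#' Builds the feature matrix the SVM classifier consumes: windows of
#' `window` consecutive R-R intervals advanced by `stride`, each summarized
#' by mean R-R, SDNN, RMSSD and variation (max - min).
#'
#' @param rr an `rr_series`.
#' @param window window size in beats (default 10).
#' @param stride step between window starts (default 5).
#' @return Numeric matrix with columns `mean_rr`, `sdnn`, `rmssd`,
#'   `variation`; one row per window.
#' @export
extract_features <- function(rr, window = 10, stride = 5) {
  stopifnot(inherits(rr, "rr_series"))
  if (!is_count(window, 2L) || !is_count(stride, 1L)) {
    stop_invalid_parameter("window >= 2 and stride >= 1 required")
  }
  v <- rr$intervals
  n <- length(v)
  if (n < window) {
    stop_insufficient_data(sprintf("need >= %d intervals, got %d", window, n))
  }
  starts <- seq(1L, n - window + 1L, by = stride)
  feat <- t(vapply(starts, function(i) {
    w <- v[i:(i + window - 1L)]
    c(mean_rr = mean(w), sdnn = stats::sd(w),
      rmssd = sqrt(mean(diff(w)^2)), variation = max(w) - min(w))
  }, numeric(4)))
  rownames(feat) <- NULL
  feat
}

status_levels <- c("excited", "fatigue")

#' Train the excited/fatigue SVM classifier
#'
#' Fits a linear support vector machine on HRV features. The feature
#' standardization (per-feature mean and SD) is estimated on the training
#' windows — the per-individual learning phase — and stored in the model,
#' so later windows are scored on the same scale.
#'
#' @param features numeric matrix from [extract_features()].
#' @param labels character/factor vector of `"excited"`/`"fatigue"`, one
#'   per row; both classes must be present.
#' @param cost SVM cost parameter (default 1).
#' @param kernel kernel type (default `"linear"`).
#' @return Object of class `status_svm` with elements `model` (the fitted
#'   SVM), `center`, `scale`, `levels`, `n_train`.
#' @export
train_svm <- function(features, labels, cost = 1, kernel = "linear") {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop_invalid_parameter("features rows and labels length differ")
  }
  if (!all(labels %in% status_levels)) {
    stop_invalid_parameter("labels must be 'excited' or 'fatigue'")
  }
  if (length(unique(labels)) < 2L) {
    abort_rehabsig("training set must contain both classes",
                   "invalid_training_set")
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  if (any(scl <= 0)) {
    abort_rehabsig("a feature is constant in the learning phase; cannot scale",
                   "invalid_training_set")
  }
  z <- scale(features, center = ctr, scale = scl)
  y <- factor(labels, levels = status_levels)
  fit <- e1071::svm(x = z, y = y, kernel = kernel, cost = cost,
                    scale = FALSE)
  structure(list(model = fit, center = ctr, scale = scl,
                 levels = status_levels, n_train = nrow(features)),
            class = "status_svm")
}

#' @export
print.status_svm <- function(x, ...) {
  cat(sprintf("<status_svm> linear SVM on %d training windows, %d support vectors\n",
              x$n_train, x$model$tot.nSV))
  cat(sprintf("  features: %s\n", paste(names(x$center), collapse = ", ")))
  invisible(x)
}

#' @param object a `status_svm` model.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return Factor of predicted labels with attribute `decision_values`.
#' @rdname train_svm
#' @export
predict.status_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    stop_invalid_input("feature dimension does not match the trained model")
  }
  z <- scale(newdata, center = object$center, scale = object$scale)
  p <- stats::predict(object$model, z, decision.values = TRUE)
  attr(p, "decision_values") <- as.numeric(attr(p, "decision.values"))
  attr(p, "decision.values") <- NULL
  p
}

#' Classify a stream of HRV windows and emit fatigue alerts
#'
#' Scores each feature window with the trained SVM, smooths the label
#' sequence by a centered rolling majority over `smoothing` windows (to
#' prevent alert chatter), and records an alert event at every
#' excited-to-fatigue transition.
#'
#' @param model a `status_svm`.
#' @param features feature matrix from [extract_features()].
#' @param smoothing odd number of windows for the rolling majority
#'   (default 3; 1 disables smoothing).
#' @return List with `labels` (character vector), `alerts` (integer indices
#'   of windows where fatigue onsets), `decision_values`.
#' @export
classify_status <- function(model, features, smoothing = 3) {
  stopifnot(inherits(model, "status_svm"))
  if (!is_count(smoothing, 1L) || smoothing %% 2 == 0) {
    stop_invalid_parameter("smoothing must be a positive odd integer")
  }
  p <- predict(model, features)
  lab <- as.character(p)
  if (smoothing > 1L && length(lab) >= smoothing) {
    half <- (smoothing - 1L) %/% 2L
    sm <- lab
    for (i in seq_along(lab)) {
      w <- lab[max(1L, i - half):min(length(lab), i + half)]
      nf <- sum(w == "fatigue")
      sm[i] <- if (nf > length(w) / 2) "fatigue"
               else if (nf < length(w) / 2) "excited"
               else lab[i]  # tie: keep the raw label
    }
    lab <- sm
  }
  prev <- c("excited", lab[-length(lab)])
  alerts <- which(lab == "fatigue" & prev == "excited")
  list(labels = lab, alerts = alerts,
       decision_values = attr(p, "decision_values"))
}

#' Persist / restore a status_svm model as JSON
#'
#' Stores the support vectors, dual coefficients, intercept and feature
#' scaling so a trained per-individual model can be reloaded later.
#'
#' @param model a `status_svm`.
#' @param path output JSON path.
#' @return `path` invisibly; `load_svm_json` returns a `status_svm`.
#' @export
save_svm_json <- function(model, path) {
  stopifnot(inherits(model, "status_svm"))
  doc <- list(
    type = "status_svm", kernel = "linear",
    center = as.list(model$center), scale = as.list(model$scale),
    levels = model$levels, n_train = model$n_train,
    SV = model$model$SV, coefs = as.numeric(model$model$coefs),
    rho = model$model$rho)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path JSON path written by `save_svm_json`.
#' @rdname save_svm_json
#' @export
load_svm_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$type) || doc$type != "status_svm") {
    stop_format_error("not a status_svm JSON document")
  }
  sv <- as.matrix(doc$SV)
  w <- drop(t(sv) %*% doc$coefs)  # linear kernel: collapse to a weight vector
  structure(list(
    model = NULL,
    linear_weights = w, rho = doc$rho,
    center = unlist(doc$center), scale = unlist(doc$scale),
    levels = doc$levels, n_train = doc$n_train),
    class = c("status_svm_linear", "status_svm"))
}

#' @export
predict.status_svm_linear <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  z <- scale(newdata, center = object$center, scale = object$scale)
  dec <- drop(z %*% object$linear_weights) - object$rho
  lab <- ifelse(dec >= 0, object$levels[1L], object$levels[2L])
  p <- factor(lab, levels = object$levels)
  attr(p, "decision_values") <- dec
  p
}
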