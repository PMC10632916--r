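#' Align two hypnograms by cross-correlation lag search
#'
#' Devices can carry a clock offset relative to the reference recorder.
#' For every integer lag in `[-max_lag, max_lag]` the test series is
#' shifted by that many 30-s epochs, valid pairs are formed and the
#' exact-label concordance fraction is computed; the lag maximizing
#' concordance wins. A positive lag means the test stream is delayed
#' relative to the reference (its content belongs `lag` epochs earlier).
#' Ties are broken toward the smaller absolute lag, then the negative
#' one.
#'
#' @param ref reference `hypnogram` at 30-s resolution.
#' @param test test `hypnogram` at 30-s resolution, same vocabulary as
#'   `ref` (map stages first so concordance is at the finest common
#'   resolution).
#' @param max_lag maximum absolute lag in epochs (default 10).
#' @return A list of class `lag_result`: `lag_epochs`,
#'   `concordance_at_lag`, `aligned_pairs` (an `epoch_pairs` object at
#'   the winning lag), and `concordance_by_lag` (named vector).
#' @export
align_by_lag <- function(ref, test, max_lag = 10) {
  stopifnot(inherits(ref, "hypnogram"), inherits(test, "hypnogram"))
  lags <- -max_lag:max_lag
  shift0 <- round(as.numeric(difftime(test$start, ref$start,
                                      units = "secs")) / 30)
  n_overlap <- min(length(ref), shift0 + length(test)) - max(0, shift0)
  if (n_overlap < 2 * max_lag + 1) {
    stop("overlap too short for a ", max_lag, "-epoch lag search",
         call. = FALSE)
  }
  shifted <- function(L) {
    t2 <- test
    t2$start <- test$start - L * 30
    t2
  }
  conc <- vapply(lags, function(L) {
    p <- tryCatch(pair_epochs(ref, shifted(L)), error = function(e) NULL)
    if (is.null(p) || nrow(p) == 0) return(NA_real_)
    mean(p$ref == p$test)
  }, numeric(1))
  names(conc) <- lags
  ord <- order(-conc, abs(lags), lags)
  best <- ord[1]
  structure(list(
    lag_epochs = lags[best],
    concordance_at_lag = conc[[best]],
    aligned_pairs = pair_epochs(ref, shifted(lags[best])),
    concordance_by_lag = conc
  ), class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> lag %+d epochs, concordance %.3f over %d pairs\n",
              x$lag_epochs, x$concordance_at_lag, nrow(x$aligned_pairs)))
  invisible(x)
}

.resolution_classes <- list(
  TWO = c("W", "SLEEP"),
  THREE = c("W", "NREM", "REM"),
  FOUR = c("W", "LS", "DS", "REM")
)

#' Cross-tabulate epoch pairs into a confusion matrix
#'
#' Maps both sides of each pair to the requested stage resolution and
#' counts reference (rows) against test (columns) labels.
#'
#' @param pairs an `epoch_pairs` object (see [pair_epochs()]), or any
#'   data frame with `ref` and `test` label columns.
#' @param resolution `"TWO"`, `"THREE"` or `"FOUR"`.
#' @param scheme four-stage collapse for five-stage reference labels.
#' @return An object of class `confusion_matrix`: an integer matrix with
#'   attributes `resolution` and `scope` (`"per_participant"`).
#' @export
confusion_matrix <- function(pairs, resolution = c("FOUR", "THREE", "TWO"),
                             scheme = c("FOUR_DEFAULT", "FOUR_ALT")) {
  resolution <- match.arg(resolution)
  scheme <- match.arg(scheme)
  classes <- .resolution_classes[[resolution]]
  r <- collapse_labels(pairs$ref, resolution, scheme = scheme)
  t <- collapse_labels(pairs$test, resolution, scheme = scheme)
  bad <- !(r %in% classes) | !(t %in% classes)
  if (any(bad)) {
    stop("labels not expressible at resolution ", resolution, ": ",
         paste(unique(c(r[bad], t[bad])), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(r, levels = classes), factor(t, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(reference = classes, test = classes))
  structure(m, resolution = resolution, scope = "per_participant",
            class = c("confusion_matrix", "matrix", "array"))
}

#' Pool per-participant confusion matrices
#'
#' Element-wise sum of matrices sharing classes and resolution; the
#' result is flagged as pooled.
#'
#' @param ms list of `confusion_matrix` objects.
#' @return A pooled `confusion_matrix`.
#' @export
pool_matrices <- function(ms) {
  stopifnot(length(ms) >= 1)
  ref <- ms[[1]]
  for (m in ms[-1]) {
    if (!identical(dimnames(m), dimnames(ref)) ||
        !identical(attr(m, "resolution"), attr(ref, "resolution"))) {
      stop("confusion matrices have mismatched classes or resolution",
           call. = FALSE)
    }
  }
  out <- Reduce(`+`, lapply(ms, unclass))
  structure(out, resolution = attr(ref, "resolution"), scope = "pooled",
            class = c("confusion_matrix", "matrix", "array"))
}

#' Binary classification metrics from a 2x2 confusion matrix
#'
#' With sleep as the positive class: sensitivity is the sleep prediction
#' accuracy `TP / (TP + FN)`, specificity the wake prediction accuracy
#' `TN / (TN + FP)`; accuracy, F1 and the Matthews correlation
#' coefficient (MCC) complete the set. MCC is robust to the strong
#' sleep/wake class imbalance of overnight recordings; it is `NA` when
#' any marginal is zero.
#'
#' @param cm 2x2 `confusion_matrix` (rows reference, columns test).
#' @param positive the positive class label (default `"SLEEP"`).
#' @return A one-row [tibble::tibble] with `sensitivity`, `specificity`,
#'   `accuracy`, `f1`, `mcc`, `n`.
#' @export
binary_metrics <- function(cm, positive = "SLEEP") {
  if (!all(dim(cm) == c(2, 2))) stop("need a 2x2 confusion matrix",
                                     call. = FALSE)
  classes <- rownames(cm)
  if (!positive %in% classes) stop("positive class not in matrix",
                                   call. = FALSE)
  neg <- setdiff(classes, positive)
  tp <- as.numeric(cm[positive, positive]); fn <- as.numeric(cm[positive, neg])
  fp <- as.numeric(cm[neg, positive]); tn <- as.numeric(cm[neg, neg])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / sum(cm)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  tibble::tibble(sensitivity = sens, specificity = spec, accuracy = acc,
                 f1 = f1, mcc = mcc, n = sum(cm))
}

#' One-vs-rest metrics for a single stage
#'
#' Collapses a multi-class confusion matrix to target-vs-rest and applies
#' [binary_metrics()] with the target as the positive class. This yields
#' the per-stage rows of an epoch-by-epoch agreement table (REM, NREM,
#' LS, DS).
#'
#' @param cm a `confusion_matrix`.
#' @param target_class class to treat as positive.
#' @return A one-row [tibble::tibble] as in [binary_metrics()].
#' @export
one_vs_rest_metrics <- function(cm, target_class) {
  classes <- rownames(cm)
  if (!target_class %in% classes) {
    stop("class ", target_class, " not present in matrix", call. = FALSE)
  }
  rest <- setdiff(classes, target_class)
  m2 <- matrix(c(sum(cm[rest, rest]), sum(cm[rest, target_class]),
                 sum(cm[target_class, rest]), sum(cm[target_class, target_class])),
               nrow = 2, byrow = TRUE,
               dimnames = list(reference = c("REST", target_class),
                               test = c("REST", target_class)))
  cm2 <- structure(m2, resolution = "TWO", scope = attr(cm, "scope"),
                   class = c("confusion_matrix", "matrix", "array"))
  binary_metrics(cm2, positive = target_class)
}

#' Aggregate a per-participant metric across the cohort
#'
#' Mean, sample SD and the normal-approximation 95% CI
#' `mean +/- 1.96 * SD / sqrt(n)`, each CI end clamped to the metric's
#' natural bounds for display. Missing values (undefined metrics, e.g.
#' zero-marginal MCC) are excluded with their count reported.
#'
#' @param values numeric vector, one value per participant.
#' @param bounds length-2 clamp for the CI (default `c(-Inf, Inf)`).
#' @return List with `n`, `n_missing`, `mean`, `sd`, `ci` (length 2).
#' @export
aggregate_participants <- function(values, bounds = c(-Inf, Inf)) {
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 2) stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(v)
  s <- stats::sd(v)
  ci <- m + c(-1, 1) * 1.96 * s / sqrt(n)
  ci <- pmin(pmax(ci, bounds[1]), bounds[2])
  list(n = n, n_missing = n_missing, mean = m, sd = s, ci = ci)
}

# interrater kappa-equivalent thresholds for satisfactory EBE concordance
.ebe_mcc_thresholds <- c(SLEEP_WAKE = 0.70, REM = 0.69, NREM = 0.48,
                         LS = 0.40, DS = 0.57)

#' Satisfactory-agreement flag for epoch-by-epoch concordance
#'
#' Compares an MCC to the interrater-reliability threshold for the stage
#' (sleep/wake 0.70, REM 0.69, NREM 0.48, LS 0.40, DS 0.57); concordance
#' is satisfactory when the MCC strictly exceeds the threshold.
#'
#' @param stage one of `"SLEEP_WAKE"`, `"REM"`, `"NREM"`, `"LS"`, `"DS"`.
#' @param mcc Matthews correlation coefficient.
#' @return Logical.
#' @export
is_satisfactory_ebe <- function(stage, mcc) {
  if (!stage %in% names(.ebe_mcc_thresholds)) {
    stop("no EBE threshold for stage ", stage, call. = FALSE)
  }
  mcc > .ebe_mcc_thresholds[[stage]]
}
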