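#' Construct an EEG signal object
#'
#' Single-channel EEG for slow-wave-activity quantification; amplitudes
#' in microvolts.
#'
#' @param samples numeric amplitude vector (µV).
#' @param fs sampling rate in Hz (>= 64).
#' @param start clock time of the first sample.
#' @param channel derivation tag, e.g. `"F3-M2"` (with `"F4-M1"` as the
#'   conventional fallback on poor signal quality).
#' @return An object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs, start = "2021-06-01T22:00:00",
                       channel = "F3-M2") {
  if (fs < 64) stop("fs must be >= 64 Hz", call. = FALSE)
  if (length(samples) < 4 * fs) stop("signal shorter than one 4-s window",
                                     call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 start = .as_clock(start), channel = channel),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %s, %.0f Hz, %.1f min from %s\n", x$channel,
              x$fs, length(x$samples) / x$fs / 60, .fmt_clock(x$start)))
  invisible(x)
}

#' Delta-band power per 4-second window
#'
#' Splits the signal into non-overlapping 4-s windows, tapers each with a
#' Hamming window, and integrates the one-sided periodogram over the
#' slow-wave band (0.75-4.5 Hz inclusive; 0.25 Hz bin spacing). The
#' periodogram uses energy (power) normalization,
#' `2 |X_k|^2 / (N * sum(w^2))`, so an in-band sinusoid of amplitude A
#' returns its full power A^2/2 regardless of taper leakage across
#' neighbouring bins. A trailing partial window is dropped.
#'
#' @param sig an `eeg_signal` (or plain numeric vector with `fs` given).
#' @param fs sampling rate, required when `sig` is a bare vector.
#' @param band band edges in Hz, inclusive (default `c(0.75, 4.5)`).
#' @return Numeric vector of band power (µV²) per 4-s window.
#' @export
band_power_4s <- function(sig, fs = NULL, band = c(0.75, 4.5)) {
  if (inherits(sig, "eeg_signal")) {
    x <- sig$samples; fs <- sig$fs
  } else {
    if (is.null(fs)) stop("fs required for a bare sample vector",
                          call. = FALSE)
    x <- as.numeric(sig)
  }
  nwin <- 4 * fs
  if (nwin != round(nwin)) stop("fs * 4 s must be an integer window length",
                                call. = FALSE)
  nw <- length(x) %/% nwin
  if (nw < 1) stop("signal shorter than one 4-s window", call. = FALSE)
  m <- matrix(x[seq_len(nw * nwin)], nrow = nwin)
  w <- as.numeric(signal::hamming(nwin))
  X <- stats::mvfft(m * w)
  freqs <- (seq_len(nwin) - 1) / 4  # bin spacing 1/4 Hz
  bins <- which(freqs >= band[1] & freqs <= band[2])
  p <- 2 * abs(X[bins, , drop = FALSE])^2 / (nwin * sum(w^2))
  colSums(p)
}

#' Aggregate 4-second band powers into 30-second epoch SWA
#'
#' Window j (0-based) starts at `4 * j` seconds and is assigned to the
#' 30-s epoch containing its start; epochs therefore average 8 or 7
#' windows alternately. Only complete 30-s epochs are kept
#' (`floor(4 * n_windows / 30)`); trailing windows are dropped and their
#' count reported.
#'
#' @param powers numeric vector of per-4-s band powers.
#' @param start clock time of the first window.
#' @return An object of class `swa_series`: list with `values` (µV² per
#'   30-s epoch), `epoch_len = 30`, `start`, `n_dropped_windows`.
#' @export
swa_per_30s <- function(powers, start = "2021-06-01T22:00:00") {
  if (length(powers) == 0) stop("empty power sequence", call. = FALSE)
  starts_s <- 4 * (seq_along(powers) - 1)
  n_epochs <- (4 * length(powers)) %/% 30
  if (n_epochs < 1) stop("fewer windows than one 30-s epoch", call. = FALSE)
  epoch <- starts_s %/% 30
  keep <- epoch < n_epochs
  values <- as.numeric(tapply(powers[keep], epoch[keep], mean))
  structure(list(values = values, epoch_len = 30, start = .as_clock(start),
                 n_dropped_windows = sum(!keep)),
            class = "swa_series")
}

#' Mean slow-wave activity over NREM epochs
#'
#' Averages per-epoch SWA over the epochs the hypnogram labels as NREM
#' (N1/N2/N3 in five-stage, LS/DS in four-stage, NREM in three-stage
#' vocabulary). The SWA series and hypnogram must share their 30-s grid;
#' lengths are truncated to the shorter of the two.
#'
#' @param swa an `swa_series`.
#' @param h a `hypnogram` at 30-s resolution.
#' @return Mean NREM SWA in µV², or `NA` with a warning when the night
#'   contains no NREM epoch.
#' @export
mean_swa_nrem <- function(swa, h) {
  stopifnot(inherits(swa, "swa_series"), inherits(h, "hypnogram"))
  if (h$epoch_len != 30) stop("hypnogram must be at 30-s resolution",
                              call. = FALSE)
  off <- as.numeric(difftime(h$start, swa$start, units = "secs"))
  if (abs(off - round(off / 30) * 30) > 1e-6) {
    stop("SWA series and hypnogram are not on the same 30-s grid",
         call. = FALSE)
  }
  shift <- round(off / 30)  # hypnogram epoch i sits at SWA epoch i + shift
  i_lo <- max(0L, -shift)
  i_hi <- min(length(h$labels) - 1L, length(swa$values) - 1L - shift)
  if (i_hi < i_lo) stop("SWA series and hypnogram do not overlap",
                        call. = FALSE)
  idx <- i_lo:i_hi
  lab <- h$labels[idx + 1L]
  vals <- swa$values[idx + shift + 1L]
  nrem <- lab %in% c("N1", "N2", "N3", "LS", "DS", "NREM")
  if (!any(nrem)) {
    warning("no NREM epoch: mean SWA undefined")
    return(NA_real_)
  }
  mean(vals[nrem])
}

#' Regression of deep-sleep duration on mean NREM slow-wave activity
#'
#' Ordinary least squares of per-participant device DS duration on
#' per-participant mean NREM SWA, with the squared Pearson correlation
#' and the two-sided p-value for zero slope. This quantifies whether a
#' device's deep-sleep estimate tracks the physiological intensity
#' measure (SWA) rather than the scored N3 duration alone.
#'
#' @param ds_min numeric vector of device DS durations (minutes).
#' @param swa numeric vector of mean NREM SWA (µV²), same length.
#' @return List with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
ds_swa_regression <- function(ds_min, swa) {
  ok <- stats::complete.cases(ds_min, swa)
  ds_min <- ds_min[ok]; swa <- swa[ok]
  if (length(ds_min) < 3) stop("need at least 3 participants", call. = FALSE)
  if (stats::sd(swa) == 0) stop("constant predictor: regression undefined",
                                call. = FALSE)
  fit <- stats::lm(ds_min ~ swa)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(ds_min))
}
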