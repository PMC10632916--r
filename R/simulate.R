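#' Cohort configuration for the synthetic generator
#'
#' Defaults emulate the pooled sleep architecture of an older-adult
#' laboratory cohort under mild (first-night) sleep disturbance: a 600
#' min recording containing a lights-off analysis period of 543 (SD 36)
#' min, subject-level sleep efficiency 0.71 (SD 0.10, truncated to
#' 0.45-0.95), stage proportions of total sleep time N3 20%, N2 47.5%,
#' N1 18%, REM 14.4%, mean sleep-onset latency 15 min, and about 1% of
#' epochs scored as artifact.
#'
#' @param n_subjects number of nights to simulate.
#' @param trt_min total recording time, minutes.
#' @param ap_min_mean,ap_min_sd lights-off period duration distribution,
#'   minutes.
#' @param seff_mean,seff_sd subject-level sleep-efficiency distribution
#'   (fractions); draws are truncated to `[0.45, 0.95]`.
#' @param stage_props named fractions of TST for N3, N2, N1, REM
#'   (normalized to sum to 1).
#' @param sol_mean_min mean sleep-onset latency, minutes.
#' @param sleep_stickiness per-epoch probability of staying in the
#'   current sleep stage, conditional on not waking; controls stage bout
#'   length (0.85 gives mean bouts of ~3 min).
#' @param p_art per-epoch probability of an artifact-scored epoch in the
#'   reference hypnogram.
#' @param start_clock ISO-8601 recording start time.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 35, trt_min = 600,
                          ap_min_mean = 543, ap_min_sd = 36,
                          seff_mean = 0.71, seff_sd = 0.10,
                          stage_props = c(N3 = 0.20, N2 = 0.475,
                                          N1 = 0.18, REM = 0.144),
                          sol_mean_min = 15, sleep_stickiness = 0.85,
                          p_art = 0.01,
                          start_clock = "2021-06-01T21:30:00") {
  stopifnot(all(c("N3", "N2", "N1", "REM") %in% names(stage_props)),
            all(stage_props >= 0), sum(stage_props) > 0,
            trt_min >= ap_min_mean, seff_sd >= 0,
            sleep_stickiness >= 0, sleep_stickiness < 1,
            p_art >= 0, p_art < 1)
  stage_props <- stage_props / sum(stage_props)
  structure(list(
    n_subjects = n_subjects, trt_min = trt_min,
    ap_min_mean = ap_min_mean, ap_min_sd = ap_min_sd,
    seff_mean = seff_mean, seff_sd = seff_sd,
    stage_props = stage_props, sol_mean_min = sol_mean_min,
    sleep_stickiness = sleep_stickiness, p_art = p_art,
    start_clock = start_clock
  ), class = "cohort_config")
}

#' Per-epoch stage transition matrix hitting a target sleep efficiency
#'
#' First-order Markov chain over W, N1, N2, N3, REM on 30-s epochs. The
#' wake row exits at rate `q = 1 / (2 * sol_mean_min)` (geometric runs
#' with the configured mean latency); sleep rows return to wake at the
#' flow-balance rate `r = q * (1 - seff) / seff`, which makes the
#' stationary sleep fraction exactly `seff`. Conditional on staying
#' asleep, the stage kernel is `a * I + (1 - a) * 1 pi'` with `pi` the
#' configured stage proportions, whose stationary distribution is `pi`
#' for any stickiness `a`.
#'
#' @param seff target stationary sleep fraction in (0, 1).
#' @param stage_props named stage proportions of sleep (N3, N2, N1, REM).
#' @param sol_mean_min mean sleep-onset latency, minutes.
#' @param stickiness within-sleep stage persistence `a`.
#' @return 5x5 row-stochastic matrix with rows/cols W, N1, N2, N3, REM.
#' @export
transition_matrix <- function(seff, stage_props, sol_mean_min = 15,
                              stickiness = 0.85) {
  stopifnot(seff > 0, seff < 1)
  pi_s <- stage_props[c("N1", "N2", "N3", "REM")]
  pi_s <- pi_s / sum(pi_s)
  q <- 1 / (2 * sol_mean_min)  # per-30-s-epoch wake-exit probability
  r <- q * (1 - seff) / seff   # sleep-to-wake return rate (flow balance)
  if (r >= 1) stop("infeasible SEFF target: sleep-to-wake rate >= 1",
                   call. = FALSE)
  states <- c("W", "N1", "N2", "N3", "REM")
  P <- matrix(0, 5, 5, dimnames = list(states, states))
  P["W", ] <- c(1 - q, q * pi_s)
  S <- stickiness * diag(4) + (1 - stickiness) *
    matrix(pi_s, 4, 4, byrow = TRUE)
  P[2:5, 1] <- r
  P[2:5, 2:5] <- (1 - r) * S
  P
}

# sample a Markov chain path of length n from transition matrix P,
# starting in state `init` (the first label IS `init`)
.markov_path <- function(P, n, init = "W") {
  states <- rownames(P)
  cum <- t(apply(P, 1, cumsum))
  path <- integer(n)
  path[1] <- match(init, states)
  u <- stats::runif(n)
  for (i in seq_len(n - 1)) {
    path[i + 1] <- findInterval(u[i + 1], cum[path[i], ]) + 1L
  }
  states[path]
}

#' Simulate one reference (PSG-like) night
#'
#' Draws the lights-off period duration and a subject-level sleep
#' efficiency target, simulates the five-stage Markov chain within the
#' lights-off period (initialized in wake), sprinkles artifact epochs,
#' and embeds the period in a full recording padded with wake. The
#' lights-off offset within the recording is drawn uniformly.
#'
#' @param config a [cohort_config()].
#' @param subject_seed integer seed; the night is reproducible under it.
#' @param subject_id identifier stored on the hypnogram.
#' @return List with `psg` (a `FIVE`-vocabulary 30-s `hypnogram` spanning
#'   the full recording), `ap_manual` (lights-off `analysis_period`), and
#'   `truth` (drawn SEFF target and AP epochs).
#' @export
simulate_psg_hypnogram <- function(config, subject_seed,
                                   subject_id = NA_character_) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(subject_seed)
  trt_ep <- round(config$trt_min * 2)
  ap_ep <- round(stats::rnorm(1, config$ap_min_mean, config$ap_min_sd) * 2)
  ap_ep <- max(60L, min(ap_ep, trt_ep))
  # the realized night-level SEFF is the drawn subject target plus
  # within-night Markov sampling noise; deflate the draw SD so the
  # realized cohort SD matches the configured dispersion
  q0 <- 1 / (2 * config$sol_mean_min)
  fs0 <- config$seff_mean
  lam <- 1 - q0 - q0 * (1 - fs0) / fs0
  sw2 <- fs0 * (1 - fs0) * (1 + lam) /
    ((1 - lam) * config$ap_min_mean * 2)
  sd_t <- sqrt(max(config$seff_sd^2 - sw2, (config$seff_sd / 4)^2))
  seff <- stats::rnorm(1, config$seff_mean, sd_t)
  for (i in 1:100) {
    if (seff >= 0.45 && seff <= 0.95) break
    seff <- stats::rnorm(1, config$seff_mean, sd_t)
  }
  if (seff < 0.45 || seff > 0.95) {
    stop("could not draw a feasible SEFF target", call. = FALSE)
  }
  # the chain starts in wake, so the finite night under-samples sleep by
  # roughly fs * tau epochs (tau = relaxation time), and artifact
  # relabelling removes a further p_art fraction of sleep; inflate the
  # stationary target so the realized SEFF hits the drawn value
  q <- 1 / (2 * config$sol_mean_min)
  tau <- 1 / (q + q * (1 - seff) / seff)
  fs_adj <- min(0.97, seff / ((1 - tau / ap_ep) * (1 - config$p_art)))
  P <- transition_matrix(fs_adj, config$stage_props, config$sol_mean_min,
                         config$sleep_stickiness)
  lab <- .markov_path(P, ap_ep, init = "W")
  if (config$p_art > 0) {
    art <- stats::runif(ap_ep) < config$p_art
    lab[art] <- "ART"
  }
  off_ep <- floor(stats::runif(1, 0, trt_ep - ap_ep + 1))
  off_ep <- min(off_ep, trt_ep - ap_ep)
  full <- c(rep("W", off_ep), lab, rep("W", trt_ep - ap_ep - off_ep))
  start <- .as_clock(config$start_clock)
  psg <- hypnogram(full, start, 30, vocabulary = "FIVE",
                   subject_id = subject_id, source = "reference")
  ap <- analysis_period(start + off_ep * 30, start + (off_ep + ap_ep) * 30,
                        kind = "manual")
  list(psg = psg, ap_manual = ap,
       truth = list(seff_target = seff, ap_epochs = ap_ep,
                    offset_epochs = off_ep))
}

#' Device error profile for the synthetic generator
#'
#' Parametrizes how a device corrupts the reference hypnogram: a
#' per-stage confusion table (rows: true four-stage labels W, LS, DS,
#' REM; columns: the device's emitted vocabulary — four-stage, or W/SLEEP
#' for binary actigraphy-like devices), a clock lag, analysis-period
#' detection errors, missing-data (ABSENT) runs, and an output minimum
#' run length (label smoothing).
#'
#' @param name device tag.
#' @param epoch_len emitted epoch length, 30 or 60 s.
#' @param confusion row-stochastic matrix, rows named W, LS, DS, REM.
#' @param lag_epochs signed clock lag in 30-s epochs, `|lag| <= 10`.
#' @param ap_start_error_min,ap_end_error_min signed minutes added to the
#'   lights-off start/end to form the device-detected period (negative
#'   start error starts earlier).
#' @param p_absent per-epoch probability of starting an ABSENT run.
#' @param absent_run_epochs mean ABSENT run length in epochs.
#' @param smoothing_run minimum run length enforced on emitted labels
#'   (1 = no smoothing).
#' @return A list of class `device_profile`.
#' @export
device_profile <- function(name, epoch_len = 30, confusion,
                           lag_epochs = 0, ap_start_error_min = 0,
                           ap_end_error_min = 0, p_absent = 0,
                           absent_run_epochs = 10, smoothing_run = 1) {
  stopifnot(epoch_len %in% c(30, 60), abs(lag_epochs) <= 10,
            is.matrix(confusion))
  if (!identical(rownames(confusion), c("W", "LS", "DS", "REM"))) {
    stop("confusion rows must be W, LS, DS, REM", call. = FALSE)
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-8) || any(confusion < 0)) {
    stop("confusion rows must be non-negative and sum to 1", call. = FALSE)
  }
  if (!identical(colnames(confusion), c("W", "LS", "DS", "REM")) &&
      !identical(colnames(confusion), c("W", "SLEEP"))) {
    stop("confusion columns must be W,LS,DS,REM or W,SLEEP", call. = FALSE)
  }
  structure(list(name = name, epoch_len = epoch_len, confusion = confusion,
                 lag_epochs = as.integer(lag_epochs),
                 ap_start_error_min = ap_start_error_min,
                 ap_end_error_min = ap_end_error_min,
                 p_absent = p_absent, absent_run_epochs = absent_run_epochs,
                 smoothing_run = as.integer(smoothing_run)),
            class = "device_profile")
}

#' Built-in device profiles
#'
#' Presets loosely emulating the error structure of four device families
#' evaluated against PSG in older adults: two undermattress sensors
#' (`wsa`-like, 60-s epochs, long automatic period, high sleep
#' sensitivity 0.95 / wake specificity 0.37; `emfit`-like, 30-s epochs,
#' very high sensitivity 0.99 / low specificity 0.22), a bedside radar
#' (`somnofy`-like, 30-s, sensitivity 0.97 / specificity 0.58), and a
#' binary actigraphy watch (`aws`-like, 60-s, sensitivity 0.95 /
#' specificity 0.34). Each confusion row's sleep mass is calibrated to
#' the published overall sensitivity and the wake row to the published
#' specificity; the within-sleep splits are assumptions chosen to give
#' the published per-stage sensitivities, not published facts.
#'
#' @return Named list of [device_profile()] objects.
#' @export
device_profile_presets <- function() {
  m4 <- function(...) {
    m <- matrix(c(...), nrow = 4, byrow = TRUE,
                dimnames = list(c("W", "LS", "DS", "REM"),
                                c("W", "LS", "DS", "REM")))
    m
  }
  m2 <- function(...) {
    matrix(c(...), nrow = 4, byrow = TRUE,
           dimnames = list(c("W", "LS", "DS", "REM"), c("W", "SLEEP")))
  }
  list(
    wsa = device_profile(
      name = "wsa", epoch_len = 60,
      confusion = m4(0.37, 0.45, 0.08, 0.10,
                     0.05, 0.54, 0.21, 0.20,
                     0.05, 0.12, 0.79, 0.04,
                     0.05, 0.45, 0.10, 0.40),
      lag_epochs = 1, ap_start_error_min = -35, ap_end_error_min = 35,
      p_absent = 0.002, smoothing_run = 2),
    emfit = device_profile(
      name = "emfit", epoch_len = 30,
      confusion = m4(0.22, 0.60, 0.08, 0.10,
                     0.01, 0.63, 0.16, 0.20,
                     0.01, 0.50, 0.39, 0.10,
                     0.01, 0.60, 0.14, 0.25),
      lag_epochs = 2, ap_start_error_min = -70, ap_end_error_min = 65,
      p_absent = 0.003, smoothing_run = 1),
    somnofy = device_profile(
      name = "somnofy", epoch_len = 30,
      confusion = m4(0.58, 0.30, 0.04, 0.08,
                     0.03, 0.67, 0.13, 0.17,
                     0.03, 0.38, 0.54, 0.05,
                     0.03, 0.30, 0.05, 0.62),
      lag_epochs = 0, ap_start_error_min = -6, ap_end_error_min = 7,
      p_absent = 0.002, smoothing_run = 1),
    aws = device_profile(
      name = "aws", epoch_len = 60,
      confusion = m2(0.34, 0.66,
                     0.05, 0.95,
                     0.05, 0.95,
                     0.05, 0.95),
      lag_epochs = 0, ap_start_error_min = 3, ap_end_error_min = -3,
      p_absent = 0, smoothing_run = 1)
  )
}

#' Device profile for the deep-sleep/SWA coupling study
#'
#' A bedside-radar-like profile whose deep-sleep row is highly faithful
#' (DS sensitivity 0.90 with little DS leakage from other stages), so
#' that the device DS duration tracks the true N3 duration closely and
#' the configured subject-level SWA coupling is the dominant attenuation
#' in a DS-vs-SWA regression. Used to verify that a generator coupling
#' of r yields a recovered regression r-squared near r^2.
#'
#' @return A [device_profile()].
#' @export
ds_coupling_profile <- function() {
  device_profile(
    name = "ds_faithful", epoch_len = 30,
    confusion = matrix(c(0.58, 0.33, 0.01, 0.08,
                         0.03, 0.75, 0.05, 0.17,
                         0.02, 0.06, 0.90, 0.02,
                         0.03, 0.33, 0.02, 0.62),
                       nrow = 4, byrow = TRUE,
                       dimnames = list(c("W", "LS", "DS", "REM"),
                                       c("W", "LS", "DS", "REM"))))
}

# enforce a minimum run length by merging short runs into the previous
# (or for a leading run, the next) run's label
.enforce_min_run <- function(lab, k) {
  if (k <= 1) return(lab)
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1 || all(r$lengths >= k)) break
    i <- which(r$lengths < k)[1]
    r$values[i] <- if (i == 1) r$values[i + 1] else r$values[i - 1]
    lab <- inverse.rle(r)
  }
  lab
}

#' Simulate a device observation of a reference night
#'
#' Maps the reference to the four-stage vocabulary, samples each emitted
#' epoch from the profile's confusion row of the true stage (artifact
#' reference epochs behave as wake), applies run-length smoothing,
#' overlays ABSENT (no-presence) runs, shifts the claimed clock by the
#' profile lag, and re-grids to 60-s epochs when the device reports
#' minutes (majority of the two halves, ties to the first half). The
#' device stream spans the device-detected analysis period, i.e. the
#' lights-off period perturbed by the profile's start/end errors.
#'
#' @param ref reference `hypnogram` (FIVE or FOUR vocabulary, 30 s).
#' @param ap_manual the reference lights-off `analysis_period`.
#' @param profile a [device_profile()].
#' @param seed integer seed.
#' @return List with `hypnogram` (the device stream; vocabulary FOUR, or
#'   TWO for binary profiles) and `ap_auto` (device-detected
#'   `analysis_period`).
#' @export
simulate_device_hypnogram <- function(ref, ap_manual, profile, seed) {
  stopifnot(inherits(ref, "hypnogram"), inherits(profile, "device_profile"))
  set.seed(seed)
  ref4 <- if (ref$vocabulary == "FIVE") map_stages(ref, "FOUR_DEFAULT") else ref
  # device-detected period: lights-off shifted by the AP errors, snapped
  # to the reference grid and clamped to the recording span
  t0 <- ap_manual$t_start + round(profile$ap_start_error_min * 2) * 30
  t1 <- ap_manual$t_end + round(profile$ap_end_error_min * 2) * 30
  t0 <- max(t0, ref4$start)
  t1 <- min(t1, hypnogram_end(ref4))
  ap_a <- analysis_period(t0, t1, kind = "automatic")
  base <- crop_to_period(ref4, ap_a)
  n <- length(base)
  truth <- base$labels
  truth[truth %in% .excluded_tokens] <- "W"
  cols <- colnames(profile$confusion)
  lab <- character(n)
  for (s in rownames(profile$confusion)) {
    idx <- which(truth == s)
    if (length(idx)) {
      lab[idx] <- sample(cols, length(idx), replace = TRUE,
                         prob = profile$confusion[s, ])
    }
  }
  lab <- .enforce_min_run(lab, profile$smoothing_run)
  if (profile$p_absent > 0) {
    starts <- which(stats::runif(n) < profile$p_absent)
    for (s in starts) {
      len <- stats::rgeom(1, 1 / profile$absent_run_epochs) + 1L
      lab[s:min(n, s + len - 1L)] <- "ABSENT"
    }
  }
  claimed_start <- base$start + profile$lag_epochs * 30
  vocab <- if (identical(cols, c("W", "SLEEP"))) "TWO" else "FOUR"
  src <- if (vocab == "TWO") "actigraphy" else "device"
  if (profile$epoch_len == 60) {
    # majority of the two 30-s halves; a 1-1 tie keeps the first half,
    # so with two halves the minute takes the first half's label
    n60 <- n %/% 2
    lab <- lab[2 * seq_len(n60) - 1]
  }
  el <- profile$epoch_len
  dev <- hypnogram(lab, claimed_start, el, vocabulary = vocab,
                   subject_id = ref$subject_id, source = src)
  ap_auto <- analysis_period(claimed_start,
                             claimed_start + length(lab) * el,
                             kind = "automatic")
  list(hypnogram = dev, ap_auto = ap_auto)
}

#' Simulate a single-channel EEG consistent with a hypnogram
#'
#' Generates band-limited (0.75-4.5 Hz) noise whose per-30-s-epoch
#' variance follows the stage sequence: each epoch's slow-wave power is
#' the stage's configured mean scaled by a subject-level multiplier, on
#' top of a broadband background. Used to exercise the spectral pipeline
#' and the deep-sleep/SWA coupling analysis; it makes no claim to
#' morphological realism (no spindles, no 1/f background shape).
#'
#' @param h `hypnogram` at 30-s resolution covering the wanted span
#'   (typically the lights-off period).
#' @param swa_by_stage named per-stage mean band power (µV²); must order
#'   N3 above N2 above REM/W.
#' @param multiplier subject-level SWA scale factor (> 0).
#' @param fs sampling rate (default 64 Hz).
#' @param seed integer seed.
#' @param background_sd SD of the additive broadband noise (µV).
#' @return An `eeg_signal` aligned with `h`.
#' @export
simulate_eeg <- function(h, swa_by_stage = c(W = 15, N1 = 30, N2 = 80,
                                             N3 = 250, REM = 20),
                         multiplier = 1, fs = 64, seed = 1,
                         background_sd = 2) {
  stopifnot(inherits(h, "hypnogram"), h$epoch_len == 30, multiplier > 0)
  if (!(swa_by_stage["N3"] > swa_by_stage["N2"] &&
        swa_by_stage["N2"] > max(swa_by_stage["REM"], swa_by_stage["W"]))) {
    stop("stage SWA means must order N3 > N2 > REM/W", call. = FALSE)
  }
  set.seed(seed)
  n_ep <- length(h)
  spe <- 30 * fs  # samples per epoch
  lab <- h$labels
  lab[!lab %in% names(swa_by_stage)] <- "W"
  target <- swa_by_stage[lab] * multiplier
  white <- stats::rnorm(n_ep * spe)
  bf <- signal::butter(4, c(0.75, 4.5) / (fs / 2), type = "pass")
  band <- signal::filtfilt(bf, white)
  m <- matrix(band, nrow = spe)
  sds <- sqrt(colMeans(m^2) - colMeans(m)^2)
  sds[sds == 0] <- 1
  scaled <- sweep(m, 2, sqrt(target) / sds, `*`)
  x <- as.numeric(scaled)
  if (background_sd > 0) x <- x + stats::rnorm(length(x), 0, background_sd)
  eeg_signal(x, fs, start = h$start, channel = "F3-M2")
}

#' Simulate a full synthetic validation cohort
#'
#' Generates `config$n_subjects` reference nights, one device stream per
#' profile, the manual and automatic analysis periods, and (optionally)
#' per-night EEG summarized into a 30-s SWA series over the lights-off
#' period. Subject-level SWA multipliers are correlated with each
#' subject's N3 duration at the configured coupling, enabling recovery
#' of a deep-sleep/SWA association from the generated data. All
#' randomness derives from the master seed.
#'
#' @param config a [cohort_config()].
#' @param profiles named list of [device_profile()]s.
#' @param seed master integer seed.
#' @param eeg simulate EEG and SWA? (slower; default `FALSE`).
#' @param swa_by_stage,eeg_fs passed to [simulate_eeg()].
#' @param swa_coupling correlation between the subject SWA multiplier
#'   and standardized N3 duration (default 0.77).
#' @param swa_cv coefficient of variation of the subject multiplier.
#' @return A list of class `synthetic_cohort`: one element per subject
#'   with `subject_id`, `psg`, `ap_manual`, `devices` (named list of
#'   `hypnogram` + `ap_auto`), and when `eeg = TRUE` also `swa`
#'   (`swa_series`), `mean_swa_nrem` and `swa_multiplier`.
#' @export
simulate_cohort <- function(config, profiles, seed = 1, eeg = FALSE,
                            swa_by_stage = c(W = 15, N1 = 30, N2 = 80,
                                             N3 = 250, REM = 20),
                            eeg_fs = 64, swa_coupling = 0.77,
                            swa_cv = 0.4) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(profiles, `[[`, "", "name")
  }
  n <- config$n_subjects
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, n * (2 + length(profiles))),
                  nrow = n)
  eps <- stats::rnorm(n)
  nights <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%02d", i)
    ref <- simulate_psg_hypnogram(config, seeds[i, 1], subject_id = sid)
    devs <- list()
    for (j in seq_along(profiles)) {
      devs[[names(profiles)[j]]] <- simulate_device_hypnogram(
        ref$psg, ref$ap_manual, profiles[[j]], seeds[i, 2 + j])
    }
    nights[[i]] <- list(subject_id = sid, psg = ref$psg,
                        ap_manual = ref$ap_manual, truth = ref$truth,
                        devices = devs)
  }
  if (eeg) {
    n3_min <- vapply(nights, function(nt) {
      hc <- crop_to_period(nt$psg, nt$ap_manual)
      sum(hc$labels == "N3") / 2
    }, numeric(1))
    z <- as.numeric(scale(n3_min))
    if (any(!is.finite(z))) z <- rep(0, n)
    mult <- pmax(0.2, 1 + swa_cv * (swa_coupling * z +
                                      sqrt(1 - swa_coupling^2) * eps))
    for (i in seq_len(n)) {
      hc <- crop_to_period(nights[[i]]$psg, nights[[i]]$ap_manual)
      sig <- simulate_eeg(hc, swa_by_stage, multiplier = mult[i],
                          fs = eeg_fs, seed = seeds[i, 2])
      swa <- swa_per_30s(band_power_4s(sig), start = hc$start)
      nights[[i]]$swa <- swa
      nights[[i]]$swa_multiplier <- mult[i]
      nights[[i]]$mean_swa_nrem <- mean_swa_nrem(swa, hc)
    }
  }
  structure(nights, class = "synthetic_cohort",
            seed = seed, profiles = names(profiles))
}
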