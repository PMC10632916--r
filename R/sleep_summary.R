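#' All-night sleep summary measures
#'
#' Computes the standard all-night summary of a hypnogram within an
#' analysis period (AP):
#'
#' * TST — total sleep time, minutes in any sleep stage;
#' * SOL — sleep onset latency, minutes from the start of the AP to the
#'   first sleep-labelled epoch;
#' * WASO — wake after sleep onset, wake minutes from sleep onset to the
#'   end of the AP (terminal wake included), so that
#'   wake = SOL + WASO;
#' * SEFF — sleep efficiency, `100 * TST / AP` by default, or
#'   `100 * TST / TRT` with `seff_denominator = "TRT"`;
#' * stage durations LS, DS, REM (and N-stage durations collapsed to
#'   LS/DS for five-stage input), NREM = LS + DS, and wake.
#'
#' ART and ABSENT epochs inside the AP count toward neither sleep nor
#' wake; their minutes are reported as `artifact_min`, so that
#' `sol + tst + waso + artifact = ap` exactly.
#'
#' @param h a `hypnogram` (vocabulary `FIVE` or `FOUR`; `THREE`/`TWO`
#'   inputs are accepted, with unavailable stage durations reported `NA`).
#' @param ap an `analysis_period`; `h` is cropped to it.
#' @param seff_denominator `"AP"` (default) or `"TRT"`.
#' @param trt_min total recording time in minutes; required when
#'   `seff_denominator = "TRT"`, otherwise defaults to the AP duration.
#' @return A list of class `sleep_summary` with fields `ap_min`,
#'   `trt_min`, `tst_min`, `sol_min`, `waso_min`, `seff_pct`, `ls_min`,
#'   `ds_min`, `rem_min`, `nrem_min`, `wake_min`, `artifact_min`,
#'   `no_sleep` (flag).
#' @export
compute_summary <- function(h, ap, seff_denominator = c("AP", "TRT"),
                            trt_min = NULL) {
  seff_denominator <- match.arg(seff_denominator)
  hc <- crop_to_period(h, ap)
  epm <- hc$epoch_len / 60  # minutes per epoch
  lab <- hc$labels
  ap_min <- ap_minutes(ap)
  if (is.null(trt_min)) trt_min <- ap_min
  sleep <- .is_sleep(lab)
  excl <- .is_excluded(lab)
  artifact_min <- sum(excl) * epm
  tst_min <- sum(sleep) * epm
  # clock time from AP start to the first retained epoch (cropping may
  # trim a partial leading epoch)
  lead_min <- as.numeric(difftime(hc$start, ap$t_start, units = "mins"))
  no_sleep <- !any(sleep)
  if (no_sleep) {
    tst_min <- 0
    waso_min <- 0
    sol_min <- ap_min - artifact_min
  } else {
    onset <- which(sleep)[1]
    # clock latency to onset; artifact time before onset is accounted
    # in artifact_min, not in SOL
    sol_min <- lead_min + (onset - 1) * epm -
      sum(excl[seq_len(onset - 1)]) * epm
    after <- seq(onset, length(lab))
    # trailing clock time lost to boundary cropping counts as wake
    trail_min <- ap_min - lead_min - length(lab) * epm
    waso_min <- sum(!sleep[after] & !excl[after]) * epm + trail_min
  }
  seff_den <- if (seff_denominator == "AP") ap_min else trt_min
  seff_pct <- if (no_sleep) 0 else 100 * tst_min / seff_den
  ls <- ds <- rem <- NA_real_
  if (hc$vocabulary %in% c("FIVE", "FOUR")) {
    l4 <- collapse_labels(lab, "FOUR")
    ls <- sum(l4 == "LS") * epm
    ds <- sum(l4 == "DS") * epm
    rem <- sum(l4 == "REM") * epm
  } else if (hc$vocabulary == "THREE") {
    rem <- sum(lab == "REM") * epm
  }
  nrem <- if (!is.na(ls)) ls + ds else if (hc$vocabulary == "THREE")
    sum(lab == "NREM") * epm else NA_real_
  structure(list(
    ap_min = ap_min, trt_min = trt_min, tst_min = tst_min,
    sol_min = sol_min, waso_min = waso_min, seff_pct = seff_pct,
    ls_min = ls, ds_min = ds, rem_min = rem, nrem_min = nrem,
    wake_min = sol_min + waso_min, artifact_min = artifact_min,
    no_sleep = no_sleep
  ), class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf(paste0("<sleep_summary> AP %.1f min | TST %.1f | SOL %.1f | ",
                     "WASO %.1f | SEFF %.1f%%\n"),
              x$ap_min, x$tst_min, x$sol_min, x$waso_min, x$seff_pct))
  if (!is.na(x$ls_min)) {
    cat(sprintf("  LS %.1f | DS %.1f | REM %.1f | NREM %.1f | artifact %.1f\n",
                x$ls_min, x$ds_min, x$rem_min, x$nrem_min, x$artifact_min))
  }
  invisible(x)
}

#' Flatten a sleep summary to a one-row tibble
#'
#' Row vocabulary matches the reporting tables: AP, TST, SOL, WASO, SEFF,
#' REM, NREM, LS, DS.
#'
#' @param s a `sleep_summary`.
#' @return A one-row [tibble::tibble].
#' @export
summary_row <- function(s) {
  tibble::tibble(AP = s$ap_min, TST = s$tst_min, SOL = s$sol_min,
                 WASO = s$waso_min, SEFF = s$seff_pct, REM = s$rem_min,
                 NREM = s$nrem_min, LS = s$ls_min, DS = s$ds_min)
}

#' Infer the automatic analysis period of a device stream
#'
#' Devices detect the in-bed period themselves; in this data model that
#' is the interval from the first to one-past-the-last non-ABSENT epoch.
#'
#' @param h_device a device `hypnogram` with at least one non-ABSENT
#'   epoch.
#' @return An `analysis_period` with `kind = "automatic"`.
#' @export
infer_ap_auto <- function(h_device) {
  stopifnot(inherits(h_device, "hypnogram"))
  occ <- which(h_device$labels != "ABSENT")
  if (length(occ) == 0) stop("all epochs are ABSENT", call. = FALSE)
  analysis_period(
    h_device$start + (occ[1] - 1) * h_device$epoch_len,
    h_device$start + occ[length(occ)] * h_device$epoch_len,
    kind = "automatic")
}
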