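#' Run the full device-evaluation pipeline on a cohort
#'
#' For every device stream in the cohort this computes, per analysis-period
#' mode, the all-night summary-agreement table (bias, limits of agreement,
#' MDC, Pearson rho, consistency ICC, Cohen's d, SMAPE, SAD,
#' satisfactory-agreement flags) and, per analysis window, the
#' epoch-by-epoch concordance tables (per-participant sensitivity,
#' specificity, accuracy, F1 and MCC aggregated as mean, SD and 95% CI)
#' together with pooled confusion matrices at each stage resolution.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()], or any
#'   list of nights with the same fields.
#' @param ap_modes subset of `c("AP_A", "AP_M")`: evaluate summaries
#'   against the device-detected and/or the lights-off period.
#' @param windows subset of `c("TRT", "LIGHTS_OFF")`: epoch-by-epoch
#'   window, full reference recording or lights-off only.
#' @param stage_scheme `"FOUR_DEFAULT"` or `"FOUR_ALT"` collapse for the
#'   five-stage reference.
#' @param seff_denominator `"AP"` or `"TRT"` (see [compute_summary()]).
#' @param max_lag lag-search half-window in epochs.
#' @return A list of class `evaluation_bundle`: `summary_table`,
#'   `ebe_table`, `pooled_confusions` (nested list device/window/
#'   resolution), `smape_matrix`, `sad_matrix`, `mcc_matrix`, `flags`,
#'   `run_log`.
#' @export
evaluate_cohort <- function(cohort,
                            ap_modes = c("AP_A", "AP_M"),
                            windows = c("TRT", "LIGHTS_OFF"),
                            stage_scheme = c("FOUR_DEFAULT", "FOUR_ALT"),
                            seff_denominator = c("AP", "TRT"),
                            max_lag = 10) {
  stage_scheme <- match.arg(stage_scheme)
  seff_denominator <- match.arg(seff_denominator)
  ap_modes <- match.arg(ap_modes, c("AP_A", "AP_M"), several.ok = TRUE)
  windows <- match.arg(windows, c("TRT", "LIGHTS_OFF"), several.ok = TRUE)
  devices <- unique(unlist(lapply(cohort, function(nt) names(nt$devices))))
  measures <- c("AP", "TST", "SOL", "WASO", "SEFF", "REM", "NREM", "LS", "DS")

  # ---- per-night sleep summaries ---------------------------------------
  summary_rows <- list()
  for (dev in devices) {
    for (mode in ap_modes) {
      xs <- ys <- list()
      for (nt in cohort) {
        if (is.null(nt$devices[[dev]])) next
        trt <- length(nt$psg) * nt$psg$epoch_len / 60
        ps <- compute_summary(nt$psg, nt$ap_manual,
                              seff_denominator = seff_denominator,
                              trt_min = trt)
        dv <- nt$devices[[dev]]
        ap <- if (mode == "AP_A") dv$ap_auto else nt$ap_manual
        ds <- tryCatch(
          compute_summary(dv$hypnogram, ap,
                          seff_denominator = seff_denominator,
                          trt_min = trt),
          error = function(e) NULL)
        if (is.null(ds)) next
        xs[[length(xs) + 1]] <- summary_row(ps)
        ys[[length(ys) + 1]] <- summary_row(ds)
      }
      if (length(xs) < 3) next
      X <- do.call(rbind, xs); Y <- do.call(rbind, ys)
      for (msr in measures) {
        if (msr == "AP" && mode == "AP_M") next  # identical by construction
        x <- X[[msr]]; y <- Y[[msr]]
        if (all(is.na(y)) || all(is.na(x))) next
        rep <- agreement_report(x, y, measure_name = msr)
        rep$device <- dev
        rep$ap_mode <- mode
        summary_rows[[length(summary_rows) + 1]] <- rep
      }
    }
  }
  summary_table <- do.call(rbind, summary_rows)

  # ---- epoch-by-epoch concordance --------------------------------------
  ebe_rows <- list()
  pooled <- list()
  for (dev in devices) {
    pooled[[dev]] <- list()
    for (win in windows) {
      per_night <- list()
      cms <- list(TWO = list(), THREE = list(), FOUR = list())
      for (nt in cohort) {
        if (is.null(nt$devices[[dev]])) next
        dv <- nt$devices[[dev]]$hypnogram
        if (dv$epoch_len == 60) dv <- upsample_to_30s(dv)
        target_res <- if (dv$vocabulary == "TWO") "TWO" else "FOUR"
        ref <- map_stages(nt$psg,
                          if (target_res == "TWO") "TWO" else stage_scheme)
        if (win == "LIGHTS_OFF") {
          ref <- tryCatch(crop_to_period(ref, nt$ap_manual),
                          error = function(e) NULL)
          if (is.null(ref)) next
        }
        al <- tryCatch(align_by_lag(ref, dv, max_lag = max_lag),
                       error = function(e) NULL)
        if (is.null(al) || nrow(al$aligned_pairs) == 0) next
        pr <- al$aligned_pairs
        cm2 <- confusion_matrix(pr, "TWO")
        cms$TWO[[length(cms$TWO) + 1]] <- cm2
        night <- list(SLEEP_WAKE = binary_metrics(cm2))
        if (target_res == "FOUR") {
          cm3 <- confusion_matrix(pr, "THREE")
          cm4 <- confusion_matrix(pr, "FOUR")
          cms$THREE[[length(cms$THREE) + 1]] <- cm3
          cms$FOUR[[length(cms$FOUR) + 1]] <- cm4
          night$REM <- one_vs_rest_metrics(cm4, "REM")
          night$LS <- one_vs_rest_metrics(cm4, "LS")
          night$DS <- one_vs_rest_metrics(cm4, "DS")
          night$NREM <- one_vs_rest_metrics(cm3, "NREM")
        }
        per_night[[length(per_night) + 1]] <- night
      }
      if (length(per_night) < 2) next
      stages <- names(per_night[[1]])
      for (st in stages) {
        vals <- lapply(per_night, `[[`, st)
        row <- list(device = dev, window = win, stage = st,
                    n = length(vals))
        for (metric in c("sensitivity", "specificity", "accuracy",
                         "f1", "mcc")) {
          v <- vapply(vals, function(z) z[[metric]], numeric(1))
          bounds <- if (metric == "mcc") c(-1, 1) else c(0, 1)
          ag <- tryCatch(aggregate_participants(v, bounds),
                         error = function(e) NULL)
          if (is.null(ag)) {
            row[paste0(metric, c("_mean", "_sd", "_ci_low", "_ci_high"))] <-
              NA_real_
          } else {
            row[[paste0(metric, "_mean")]] <- ag$mean
            row[[paste0(metric, "_sd")]] <- ag$sd
            row[[paste0(metric, "_ci_low")]] <- ag$ci[1]
            row[[paste0(metric, "_ci_high")]] <- ag$ci[2]
          }
        }
        row$satisfactory <- if (st %in% names(.ebe_mcc_thresholds) &&
                                !is.na(row$mcc_mean)) {
          is_satisfactory_ebe(st, row$mcc_mean)
        } else NA
        ebe_rows[[length(ebe_rows) + 1]] <- tibble::as_tibble(row)
      }
      pooled[[dev]][[win]] <- lapply(Filter(length, cms), pool_matrices)
    }
  }
  ebe_table <- do.call(rbind, ebe_rows)

  # ---- agreement matrices (device x measure / stage) -------------------
  fill_matrix <- function(sub, rowcol, colcol, valcol) {
    if (is.null(sub) || nrow(sub) == 0) return(NULL)
    rows <- unique(sub[[rowcol]]); cols <- unique(sub[[colcol]])
    m <- matrix(NA_real_, length(rows), length(cols),
                dimnames = stats::setNames(list(rows, cols),
                                           c(rowcol, colcol)))
    for (i in seq_len(nrow(sub))) {
      m[sub[[rowcol]][i], sub[[colcol]][i]] <- sub[[valcol]][i]
    }
    m
  }
  mode0 <- ap_modes[1]
  sub_s <- if (is.null(summary_table)) NULL else
    summary_table[summary_table$ap_mode == mode0, , drop = FALSE]
  smape_matrix <- fill_matrix(sub_s, "device", "measure", "smape")
  sad_matrix <- fill_matrix(sub_s, "device", "measure", "sad")
  sub_e <- if (is.null(ebe_table)) NULL else
    ebe_table[ebe_table$window == windows[1], , drop = FALSE]
  mcc_matrix <- fill_matrix(sub_e, "device", "stage", "mcc_mean")

  flags <- NULL
  if (!is.null(summary_table)) {
    flags <- summary_table[!is.na(summary_table$satisfactory),
                           c("device", "ap_mode", "measure", "icc",
                             "satisfactory")]
  }

  run_log <- list(
    devices = devices, ap_modes = ap_modes, windows = windows,
    stage_scheme = stage_scheme, seff_denominator = seff_denominator,
    max_lag = max_lag, n_nights = length(cohort),
    cohort_seed = attr(cohort, "seed"),
    package_version = as.character(utils::packageVersion("sleepconcord")))

  structure(list(summary_table = summary_table, ebe_table = ebe_table,
                 pooled_confusions = pooled, smape_matrix = smape_matrix,
                 sad_matrix = sad_matrix, mcc_matrix = mcc_matrix,
                 flags = flags, run_log = run_log),
            class = "evaluation_bundle")
}

#' Rank devices by standardized agreement metrics
#'
#' Per summary measure, devices are ranked by SMAPE (ascending) and SAD
#' (ascending); per stage, by MCC (descending). Ties share the smaller
#' rank.
#'
#' @param bundle an `evaluation_bundle` from [evaluate_cohort()] with at
#'   least two devices.
#' @return A [tibble::tibble] with columns `metric`, `item` (measure or
#'   stage), `device`, `value`, `rank`.
#' @export
rank_devices <- function(bundle) {
  stopifnot(inherits(bundle, "evaluation_bundle"))
  out <- list()
  add <- function(mat, metric, decreasing) {
    if (is.null(mat)) return()
    for (item in colnames(mat)) {
      v <- mat[, item]
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      rk <- if (decreasing) rank(-v, ties.method = "min")
            else rank(v, ties.method = "min")
      out[[length(out) + 1]] <<- tibble::tibble(
        metric = metric, item = item, device = names(v),
        value = as.numeric(v), rank = as.integer(rk))
    }
  }
  add(bundle$smape_matrix, "SMAPE", decreasing = FALSE)
  add(bundle$sad_matrix, "SAD", decreasing = FALSE)
  add(bundle$mcc_matrix, "MCC", decreasing = TRUE)
  if (length(out) == 0) stop("need at least 2 devices to rank", call. = FALSE)
  do.call(rbind, out)
}

#' Write an evaluation bundle to CSV and JSON
#'
#' Emits `summary_agreement.csv`, `ebe_metrics.csv`, labelled pooled
#' confusion matrices (`confusion_<device>_<window>_<resolution>.csv`),
#' the SMAPE/SAD/MCC agreement matrices, the satisfactory-flag table and
#' a JSON run log. Outputs are plain UTF-8 CSV with a header row and are
#' byte-stable under a fixed seed.
#'
#' @param bundle an `evaluation_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(bundle, dir) {
  stopifnot(inherits(bundle, "evaluation_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    if (!is.null(x)) utils::write.csv(x, file.path(dir, name),
                                      row.names = FALSE)
  }
  wcsv(bundle$summary_table, "summary_agreement.csv")
  wcsv(bundle$ebe_table, "ebe_metrics.csv")
  wcsv(bundle$flags, "satisfactory_flags.csv")
  wmat <- function(m, name) {
    if (!is.null(m)) utils::write.csv(as.data.frame.matrix(m),
                                      file.path(dir, name))
  }
  wmat(bundle$smape_matrix, "smape_matrix.csv")
  wmat(bundle$sad_matrix, "sad_matrix.csv")
  wmat(bundle$mcc_matrix, "mcc_matrix.csv")
  for (dev in names(bundle$pooled_confusions)) {
    for (win in names(bundle$pooled_confusions[[dev]])) {
      for (res in names(bundle$pooled_confusions[[dev]][[win]])) {
        wmat(bundle$pooled_confusions[[dev]][[win]][[res]],
             sprintf("confusion_%s_%s_%s.csv", dev, win, res))
      }
    }
  }
  jsonlite::write_json(bundle$run_log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
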