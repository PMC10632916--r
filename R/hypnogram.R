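#' Construct a hypnogram
#'
#' A hypnogram is an epoch-labelled sleep-stage time series. Epoch `i`
#' (0-based) covers the half-open clock interval
#' `[start + i * epoch_len, start + (i + 1) * epoch_len)`.
#'
#' @param labels character vector of stage tokens.
#' @param start clock time of the first epoch; `POSIXct` or an ISO-8601
#'   string (interpreted as UTC).
#' @param epoch_len epoch length in seconds, 30 or 60.
#' @param vocabulary vocabulary tag (`"FIVE"`, `"FOUR"`, `"THREE"`,
#'   `"TWO"`); inferred from the labels when `NULL`.
#' @param subject_id opaque subject identifier.
#' @param source `"reference"`, `"device"` or `"actigraphy"`.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, start, epoch_len = 30, vocabulary = NULL,
                      subject_id = NA_character_, source = "reference") {
  if (!epoch_len %in% c(30, 60)) {
    stop("epoch_len must be 30 or 60 seconds", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) == 0) stop("hypnogram needs at least one epoch", call. = FALSE)
  start <- .as_clock(start)
  if (is.null(vocabulary)) vocabulary <- .infer_vocabulary(labels)
  vocabulary <- match.arg(vocabulary, names(stage_vocabularies))
  bad <- !labels %in% stage_vocabularies[[vocabulary]]
  if (any(bad)) {
    stop(sprintf("label '%s' at epoch %d is not in the %s vocabulary",
                 labels[which(bad)[1]], which(bad)[1] - 1L, vocabulary),
         call. = FALSE)
  }
  source <- match.arg(source, c("reference", "device", "actigraphy"))
  structure(
    list(labels = labels, start = start, epoch_len = as.numeric(epoch_len),
         vocabulary = vocabulary, subject_id = subject_id, source = source),
    class = "hypnogram"
  )
}

.as_clock <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(out)) out <- as.POSIXct(x, tz = "UTC")
  if (is.na(out)) stop("cannot parse clock time: ", x, call. = FALSE)
  out
}

.fmt_clock <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' @export
length.hypnogram <- function(x) length(x$labels)

#' End of the hypnogram's clock span (one past the last epoch)
#' @param h a `hypnogram`.
#' @return `POSIXct`.
#' @export
hypnogram_end <- function(h) h$start + length(h) * h$epoch_len

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x %ds epochs (%.1f min), vocabulary %s, %s\n",
              length(x), as.integer(x$epoch_len),
              length(x) * x$epoch_len / 60, x$vocabulary, x$source))
  cat(sprintf("  %s -- %s", .fmt_clock(x$start), .fmt_clock(hypnogram_end(x))))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id)
  cat("\n")
  tb <- table(x$labels)
  cat("  ", paste(sprintf("%s:%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' Construct an analysis period
#'
#' An analysis period (AP) is the half-open clock interval
#' `[t_start, t_end)` over which sleep summary measures are computed:
#' either the manually set lights-off to lights-on period (AP-M) or the
#' device's automatically detected in-bed period (AP-A).
#'
#' @param t_start,t_end interval bounds, `POSIXct` or ISO-8601 strings.
#' @param kind `"manual"` or `"automatic"`.
#' @return An object of class `analysis_period`.
#' @export
analysis_period <- function(t_start, t_end, kind = c("manual", "automatic")) {
  kind <- match.arg(kind)
  t_start <- .as_clock(t_start)
  t_end <- .as_clock(t_end)
  if (!(t_start < t_end)) stop("t_start must precede t_end", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end, kind = kind),
            class = "analysis_period")
}

#' @export
print.analysis_period <- function(x, ...) {
  cat(sprintf("<analysis_period %s> %s -- %s (%.1f min)\n", x$kind,
              .fmt_clock(x$t_start), .fmt_clock(x$t_end),
              as.numeric(difftime(x$t_end, x$t_start, units = "mins"))))
  invisible(x)
}

#' Duration of an analysis period in minutes
#' @param ap an `analysis_period`.
#' @return minutes.
#' @export
ap_minutes <- function(ap) {
  as.numeric(difftime(ap$t_end, ap$t_start, units = "mins"))
}

# ---- I/O ----------------------------------------------------------------

#' Read a hypnogram from the CSV or JSON dialect
#'
#' The CSV dialect carries two header comment lines `#start=<ISO-8601>`
#' and `#epoch_s=<30|60>` followed by a single `stage` column of tokens.
#' The JSON twin is `{"start": ..., "epoch_s": ..., "stages": [...]}`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"json"`; guessed from the extension when
#'   omitted.
#' @param ... passed to [hypnogram()] (`subject_id`, `source`, ...).
#' @return A `hypnogram`.
#' @export
read_hypnogram <- function(path, dialect = NULL, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "json"))
  if (dialect == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in c("start", "epoch_s", "stages")) {
      if (is.null(obj[[k]])) stop("missing JSON key: ", k, call. = FALSE)
    }
    return(hypnogram(obj$stages, obj$start, obj$epoch_s, ...))
  }
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  get_key <- function(key) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m) != 1) stop("missing or duplicated header key: ", key,
                             call. = FALSE)
    sub(paste0("^#", key, "="), "", m)
  }
  start <- get_key("start")
  epoch_s <- as.numeric(get_key("epoch_s"))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0 || body[1] != "stage") {
    stop("expected a single 'stage' column header", call. = FALSE)
  }
  stages <- body[-1]
  known <- unique(unlist(stage_vocabularies))
  bad <- !stages %in% known
  if (any(bad)) {
    stop(sprintf("unknown stage token '%s' at data row %d",
                 stages[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  hypnogram(stages, start, epoch_s, ...)
}

#' Write a hypnogram in the CSV or JSON dialect
#'
#' @param h a `hypnogram`.
#' @param path destination file.
#' @param dialect `"csv"` or `"json"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "json"))
  if (dialect == "json") {
    jsonlite::write_json(
      list(start = .fmt_clock(h$start), epoch_s = h$epoch_len,
           stages = h$labels),
      path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(c(sprintf("#start=%s", .fmt_clock(h$start)),
                 sprintf("#epoch_s=%d", as.integer(h$epoch_len)),
                 "stage", h$labels),
               path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read / write an analysis period (JSON)
#'
#' @param path file path.
#' @return An `analysis_period` (read) or `path` invisibly (write).
#' @export
read_analysis_period <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  analysis_period(obj$t_start, obj$t_end, obj$kind)
}

#' @param ap an `analysis_period`.
#' @rdname read_analysis_period
#' @export
write_analysis_period <- function(ap, path) {
  jsonlite::write_json(
    list(t_start = .fmt_clock(ap$t_start), t_end = .fmt_clock(ap$t_end),
         kind = ap$kind),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
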