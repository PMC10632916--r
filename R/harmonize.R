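#' Map a hypnogram to a coarser stage vocabulary
#'
#' Applies a stage mapping scheme (see [stage_mapping_schemes()]): the
#' default device collapse `FOUR_DEFAULT` (N1, N2 -> LS; N3 -> DS), the
#' alternate assumption `FOUR_ALT` (only N1 -> LS; N2, N3 -> DS), the
#' three-stage collapse `THREE` (LS, DS -> NREM) and the binary collapse
#' `TWO` (all sleep -> SLEEP). ART and ABSENT map to themselves. Start,
#' epoch length and epoch count are unchanged.
#'
#' @param h a `hypnogram` whose vocabulary is refinable under `scheme`
#'   (e.g. `FOUR_DEFAULT` needs a `FIVE` input; `TWO` accepts `FIVE`,
#'   `FOUR` or `THREE`, composing the intermediate collapses).
#' @param scheme scheme name.
#' @return A `hypnogram` in the scheme's target vocabulary.
#' @export
map_stages <- function(h, scheme = stage_mapping_schemes()) {
  stopifnot(inherits(h, "hypnogram"))
  scheme <- match.arg(scheme)
  target <- .scheme_to[[scheme]]
  if (.vocab_rank[h$vocabulary] <= .vocab_rank[target]) {
    stop(sprintf("scheme %s does not apply to a %s-vocabulary hypnogram",
                 scheme, h$vocabulary), call. = FALSE)
  }
  if (scheme %in% c("FOUR_DEFAULT", "FOUR_ALT") && h$vocabulary != "FIVE") {
    stop(sprintf("scheme %s needs a FIVE-vocabulary hypnogram", scheme),
         call. = FALSE)
  }
  four_scheme <- if (scheme == "FOUR_ALT") "FOUR_ALT" else "FOUR_DEFAULT"
  labels <- collapse_labels(h$labels, target, scheme = four_scheme)
  hypnogram(labels, h$start, h$epoch_len, vocabulary = target,
            subject_id = h$subject_id, source = h$source)
}

#' Convert a 60-second hypnogram to 30-second resolution
#'
#' Each 60-s epoch is split in two 30-s epochs: the first half keeps the
#' minute's own label and the unavailable second half is imputed with the
#' label of the next adjacent minute (the last minute duplicates itself).
#' A 30-s input is returned unchanged with a message.
#'
#' @param h a `hypnogram` with `epoch_len` 60 (30 passes through).
#' @return A `hypnogram` at 30-s resolution with twice the epoch count.
#' @export
upsample_to_30s <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (h$epoch_len == 30) {
    message("hypnogram already at 30-s resolution; returned unchanged")
    return(h)
  }
  n <- length(h)
  nxt <- h$labels[c(seq_len(n - 1) + 1L, n)]
  labels <- as.vector(rbind(h$labels, nxt))
  hypnogram(labels, h$start, 30, vocabulary = h$vocabulary,
            subject_id = h$subject_id, source = h$source)
}

#' Crop a hypnogram to an analysis period
#'
#' Keeps the epochs whose half-open interval is fully contained in
#' `[ap$t_start, ap$t_end)`; an epoch split by a period boundary is
#' excluded. The start time is moved to the first retained epoch.
#'
#' @param h a `hypnogram`.
#' @param ap an `analysis_period` overlapping `h`'s span.
#' @return The cropped `hypnogram`.
#' @export
crop_to_period <- function(h, ap) {
  stopifnot(inherits(h, "hypnogram"), inherits(ap, "analysis_period"))
  n <- length(h)
  begins <- h$start + (seq_len(n) - 1) * h$epoch_len
  ends <- begins + h$epoch_len
  keep <- begins >= ap$t_start & ends <= ap$t_end
  if (!any(keep)) {
    stop("analysis period contains no complete epoch of the hypnogram",
         call. = FALSE)
  }
  idx <- which(keep)
  hypnogram(h$labels[idx], begins[idx[1]], h$epoch_len,
            vocabulary = h$vocabulary, subject_id = h$subject_id,
            source = h$source)
}

#' Pair reference and test epochs on a shared 30-second grid
#'
#' Forms the epoch pairs over the clock-time intersection of the two
#' hypnograms, snapping the test series to the reference grid (offsets of
#' at most 15 s round to the nearest boundary). Pairs where either side
#' is ART (artifact) or ABSENT (missing / no presence) are dropped: only
#' valid, complete label pairs are kept.
#'
#' @param ref reference `hypnogram` at 30-s resolution.
#' @param test test `hypnogram` at 30-s resolution (upsample 60-s devices
#'   first, see [upsample_to_30s()]).
#' @return An object of class `epoch_pairs`: a [tibble::tibble] with
#'   columns `ref_index`, `test_index` (0-based original indices), `ref`
#'   and `test` labels; attribute `dropped` holds the reference indices of
#'   excluded (ART/ABSENT) pairs.
#' @export
pair_epochs <- function(ref, test) {
  stopifnot(inherits(ref, "hypnogram"), inherits(test, "hypnogram"))
  if (ref$epoch_len != 30 || test$epoch_len != 30) {
    stop("both hypnograms must be at 30-s resolution; upsample first",
         call. = FALSE)
  }
  shift <- round(as.numeric(difftime(test$start, ref$start, units = "secs")) / 30)
  # ref index i pairs with test index i - shift
  i_lo <- max(0L, shift)
  i_hi <- min(length(ref), shift + length(test)) - 1L
  if (i_hi < i_lo) stop("hypnograms do not overlap in clock time", call. = FALSE)
  ri <- i_lo:i_hi
  ti <- ri - shift
  rl <- ref$labels[ri + 1L]
  tl <- test$labels[ti + 1L]
  drop <- .is_excluded(rl) | .is_excluded(tl)
  out <- tibble::tibble(ref_index = ri[!drop], test_index = ti[!drop],
                        ref = rl[!drop], test = tl[!drop])
  attr(out, "dropped") <- ri[drop]
  class(out) <- c("epoch_pairs", class(out))
  out
}
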