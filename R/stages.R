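#' Stage vocabularies and mapping schemes
#'
#' Sleep-stage hypnograms occur at several label resolutions. PSG consensus
#' scoring uses the five-stage AASM vocabulary (`FIVE`: W, N1, N2, N3, REM,
#' plus ART for artifact-scored epochs). Contactless devices emit a
#' four-stage vocabulary (`FOUR`: W, LS light sleep, DS deep sleep, REM,
#' plus ABSENT for missing / no-presence epochs). Coarser vocabularies
#' collapse sleep further: `THREE` (W, NREM, REM) and `TWO` (W, SLEEP).
#' ART and ABSENT are pass-through tokens in every vocabulary; they mark
#' epochs to be excluded from pairing, never sleep or wake.
#'
#' @format `stage_vocabularies` is a named list of character vectors, one
#'   per vocabulary tag.
#' @name stage-vocabularies
NULL

stage_vocabularies <- list(
  FIVE  = c("W", "N1", "N2", "N3", "REM", "ART", "ABSENT"),
  FOUR  = c("W", "LS", "DS", "REM", "ART", "ABSENT"),
  THREE = c("W", "NREM", "REM", "ART", "ABSENT"),
  TWO   = c("W", "SLEEP", "ART", "ABSENT")
)

# tokens counting as sleep in any vocabulary
.sleep_tokens <- c("N1", "N2", "N3", "REM", "LS", "DS", "NREM", "SLEEP")
# tokens excluded from pairing and from sleep/wake accounting
.excluded_tokens <- c("ART", "ABSENT")

# label -> label tables; ART/ABSENT always map to themselves
.scheme_tables <- list(
  FOUR_DEFAULT = c(W = "W", N1 = "LS", N2 = "LS", N3 = "DS", REM = "REM"),
  FOUR_ALT     = c(W = "W", N1 = "LS", N2 = "DS", N3 = "DS", REM = "REM"),
  THREE        = c(W = "W", LS = "NREM", DS = "NREM", REM = "REM"),
  TWO          = c(W = "W", LS = "SLEEP", DS = "SLEEP", REM = "SLEEP",
                   NREM = "SLEEP")
)

.scheme_from <- list(
  FOUR_DEFAULT = "FIVE", FOUR_ALT = "FIVE", THREE = "FOUR", TWO = "FOUR"
)
.scheme_to <- list(
  FOUR_DEFAULT = "FOUR", FOUR_ALT = "FOUR", THREE = "THREE", TWO = "TWO"
)

# ordering used when a vocabulary must be "refinable" to another:
# FIVE is the finest, TWO the coarsest
.vocab_rank <- c(FIVE = 4L, FOUR = 3L, THREE = 2L, TWO = 1L)

#' Available stage mapping schemes
#'
#' * `FOUR_DEFAULT`: N1 and N2 collapse to light sleep (LS), N3 to deep
#'   sleep (DS) — the standard reading of device stage semantics.
#' * `FOUR_ALT`: the alternate assumption that DS covers both N2 and N3
#'   (only N1 is LS).
#' * `THREE`: LS and DS collapse to NREM.
#' * `TWO`: all sleep tokens collapse to SLEEP.
#'
#' @return Character vector of scheme names.
#' @export
stage_mapping_schemes <- function() names(.scheme_tables)

#' Collapse a label vector to a target resolution
#'
#' Maps stage tokens (from the FIVE or FOUR vocabulary) to the vocabulary
#' of `resolution`, composing the default N1/N2 -> LS, N3 -> DS collapse
#' with the NREM / SLEEP collapses as required. ART and ABSENT are kept
#' as-is.
#'
#' @param labels character vector of stage tokens.
#' @param resolution one of `"FOUR"`, `"THREE"`, `"TWO"` (or `"FIVE"`,
#'   identity).
#' @param scheme four-stage collapse used for five-stage input:
#'   `"FOUR_DEFAULT"` or `"FOUR_ALT"`.
#' @return character vector of mapped tokens.
#' @export
collapse_labels <- function(labels, resolution,
                            scheme = c("FOUR_DEFAULT", "FOUR_ALT")) {
  scheme <- match.arg(scheme)
  resolution <- match.arg(resolution, c("FIVE", "FOUR", "THREE", "TWO"))
  out <- labels
  four <- .scheme_tables[[scheme]]
  is5 <- out %in% names(four)
  if (resolution == "FIVE") return(out)
  out[is5] <- four[out[is5]]
  if (resolution == "FOUR") return(out)
  three <- .scheme_tables$THREE
  is4 <- out %in% names(three)
  out[is4] <- three[out[is4]]
  if (resolution == "THREE") return(out)
  two <- .scheme_tables$TWO
  is3 <- out %in% names(two)
  out[is3] <- two[out[is3]]
  out
}

.is_sleep <- function(labels) labels %in% .sleep_tokens
.is_excluded <- function(labels) labels %in% .excluded_tokens

# infer the vocabulary tag from a set of labels
.infer_vocabulary <- function(labels) {
  u <- setdiff(unique(labels), .excluded_tokens)
  for (v in c("TWO", "THREE", "FOUR", "FIVE")) {
    if (all(u %in% stage_vocabularies[[v]])) return(v)
  }
  stop("labels do not fit any known stage vocabulary: ",
       paste(setdiff(u, unlist(stage_vocabularies)), collapse = ", "),
       call. = FALSE)
}
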