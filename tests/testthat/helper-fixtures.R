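# shared fixture builders and independent oracles

T0 <- "2021-06-01T22:00:00"

mk_hyp <- function(labels, start = T0, epoch_len = 30, ...) {
  hypnogram(labels, start, epoch_len, ...)
}

full_ap <- function(h, kind = "manual") {
  analysis_period(h$start, hypnogram_end(h), kind = kind)
}

# independent MCC oracle: Pearson correlation of the one-vs-rest
# indicator vectors
mcc_oracle <- function(ref, test, positive) {
  a <- as.numeric(ref == positive)
  b <- as.numeric(test == positive)
  suppressWarnings(stats::cor(a, b))
}

# independent consistency-ICC oracle via a two-way aov fit
icc_oracle <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(v ~ subj + rater, data = df))[[1]]
  msr <- tab[1, "Mean Sq"]   # subjects
  mse <- tab[3, "Mean Sq"]   # residuals
  (msr - mse) / (msr + mse)
}

# brute-force loop oracles for the standardized metrics
smape_oracle <- function(x, y) {
  acc <- 0
  for (i in seq_along(x)) {
    den <- abs(x[i]) + abs(y[i])
    if (den > 0) acc <- acc + abs(x[i] - y[i]) / den
  }
  100 * acc / length(x)
}

sad_oracle <- function(x, y) {
  mean(abs(x - y)) / sqrt((stats::var(x) + stats::var(y)) / 2)
}

# a small random FOUR-vocabulary label pair set
random_pairs <- function(n, seed) {
  set.seed(seed)
  classes <- c("W", "LS", "DS", "REM")
  tibble::tibble(ref_index = seq_len(n) - 1L, test_index = seq_len(n) - 1L,
                 ref = sample(classes, n, replace = TRUE,
                              prob = c(0.3, 0.4, 0.15, 0.15)),
                 test = sample(classes, n, replace = TRUE,
                               prob = c(0.25, 0.35, 0.2, 0.2)))
}

# identity (noiseless) four-stage device profile
identity_profile <- function(name = "perfect", epoch_len = 30, ...) {
  device_profile(name, epoch_len,
                 confusion = diag(4) |>
                   `dimnames<-`(list(c("W", "LS", "DS", "REM"),
                                     c("W", "LS", "DS", "REM"))),
                 ...)
}
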