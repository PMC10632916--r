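test_that("lag alignment recovers pure shifts and identity", {
  set.seed(12)
  lab <- sample(c("W", "LS", "DS", "REM"), 120, replace = TRUE)
  ref <- mk_hyp(lab)
  expect_equal(align_by_lag(ref, ref)$lag_epochs, 0)
  expect_equal(align_by_lag(ref, ref)$concordance_at_lag, 1)
  # a device delayed by 3 epochs: its epoch i carries the reference
  # label of epoch i - 3
  delayed <- mk_hyp(c(lab[1:3], lab[1:117]))
  r <- align_by_lag(ref, delayed)
  expect_equal(r$lag_epochs, 3)
  expect_equal(r$concordance_at_lag, 1)
  advanced <- mk_hyp(c(lab[4:120], lab[118:120]))
  expect_equal(align_by_lag(ref, advanced)$lag_epochs, -3)
  expect_error(align_by_lag(mk_hyp(lab[1:10]), mk_hyp(lab[1:10])),
               "overlap")
})

test_that("lag recovery survives moderate label corruption", {
  set.seed(13)
  classes <- c("W", "LS", "DS", "REM")
  hits <- vapply(1:50, function(i) {
    lab <- sample(classes, 400, replace = TRUE)
    lag <- sample(-10:10, 1)
    shifted <- if (lag >= 0) c(lab[seq_len(lag)], lab[seq_len(400 - lag)])
               else c(lab[(1 - lag):400], lab[seq_len(-lag)])
    corrupt <- sample(400, 40)  # 10%
    shifted[corrupt] <- vapply(shifted[corrupt], function(s)
      sample(setdiff(classes, s), 1), "")
    align_by_lag(mk_hyp(lab), mk_hyp(shifted))$lag_epochs == lag
  }, logical(1))
  expect_gte(mean(hits), 0.98)
})

test_that("confusion matrices count pairs at each resolution", {
  p <- tibble::tibble(ref_index = 0:1, test_index = 0:1,
                      ref = c("W", "LS"), test = c("W", "DS"))
  cm2 <- confusion_matrix(p, "TWO")
  expect_equal(as.integer(cm2), c(1L, 0L, 0L, 1L))
  expect_equal(rownames(cm2), c("W", "SLEEP"))
  cm4 <- confusion_matrix(tibble::tibble(ref = "DS", test = "LS",
                                         ref_index = 0, test_index = 0),
                          "FOUR")
  expect_equal(cm4["DS", "LS"], 1L)
  expect_equal(sum(cm4), 1)
  # conservation at every resolution
  pr <- random_pairs(500, 91)
  for (res in c("TWO", "THREE", "FOUR")) {
    expect_equal(sum(confusion_matrix(pr, res)), 500)
  }
  # five-stage reference labels are collapsed on the fly
  p5 <- tibble::tibble(ref = c("N1", "N3"), test = c("LS", "DS"),
                       ref_index = 0:1, test_index = 0:1)
  expect_equal(sum(diag(confusion_matrix(p5, "FOUR"))), 2)
})

test_that("pooling sums matrices and flags scope", {
  m <- confusion_matrix(random_pairs(200, 3), "FOUR")
  p2 <- pool_matrices(list(m, m))
  expect_equal(as.integer(p2), 2L * as.integer(m))
  expect_equal(attr(p2, "scope"), "pooled")
  p1 <- pool_matrices(list(m))
  expect_equal(attr(p1, "scope"), "pooled")
  expect_equal(sum(p2), 2 * sum(m))
  m2 <- confusion_matrix(random_pairs(200, 4), "TWO")
  expect_error(pool_matrices(list(m, m2)), "mismatch")
})

test_that("binary metrics match the hand-computed 2x2 oracle", {
  cm <- structure(matrix(c(40L, 10L, 5L, 45L), 2, byrow = TRUE,
                         dimnames = list(reference = c("W", "SLEEP"),
                                         test = c("W", "SLEEP"))),
                  resolution = "TWO", scope = "per_participant",
                  class = c("confusion_matrix", "matrix", "array"))
  bm <- binary_metrics(cm)
  expect_equal(bm$sensitivity, 0.90)
  expect_equal(bm$specificity, 0.80)
  expect_equal(bm$accuracy, 0.85)
  expect_equal(bm$mcc, (45 * 40 - 10 * 5) / sqrt(50 * 55 * 50 * 45))
  expect_equal(bm$f1, 2 * 45 / (2 * 45 + 10 + 5))
  perfect <- confusion_matrix(tibble::tibble(
    ref = c("W", "SLEEP"), test = c("W", "SLEEP"),
    ref_index = 0:1, test_index = 0:1), "TWO")
  pm <- binary_metrics(perfect)
  expect_equal(unlist(pm[c("sensitivity", "specificity", "accuracy",
                           "f1", "mcc")]), rep(1, 5), ignore_attr = TRUE)
})

test_that("MCC vanishes for independent labels", {
  set.seed(14)
  n <- 1e5
  p <- tibble::tibble(ref_index = seq_len(n), test_index = seq_len(n),
                      ref = sample(c("W", "SLEEP"), n, TRUE, c(0.3, 0.7)),
                      test = sample(c("W", "SLEEP"), n, TRUE, c(0.4, 0.6)))
  expect_lt(abs(binary_metrics(confusion_matrix(p, "TWO"))$mcc), 0.02)
})

test_that("one-vs-rest equals pre-collapsed binary metrics", {
  pr <- random_pairs(800, 17)
  cm <- confusion_matrix(pr, "FOUR")
  for (cls in c("W", "LS", "DS", "REM")) {
    ovr <- one_vs_rest_metrics(cm, cls)
    # oracle: indicator correlation on the raw pairs
    expect_equal(ovr$mcc, mcc_oracle(pr$ref, pr$test, cls), tolerance = 1e-12)
    # oracle: collapse the labels first, then binary metrics
    p2 <- tibble::tibble(ref = ifelse(pr$ref == cls, cls, "REST"),
                         test = ifelse(pr$test == cls, cls, "REST"),
                         ref_index = pr$ref_index, test_index = pr$test_index)
    tab <- table(factor(p2$ref, c("REST", cls)), factor(p2$test, c("REST", cls)))
    expect_equal(ovr$sensitivity, tab[2, 2] / sum(tab[2, ]))
    expect_equal(ovr$specificity, tab[1, 1] / sum(tab[1, ]))
  }
  # absent class -> undefined sensitivity, reported missing
  pnone <- tibble::tibble(ref = c("W", "LS"), test = c("REM", "LS"),
                          ref_index = 0:1, test_index = 0:1)
  cmn <- confusion_matrix(pnone, "FOUR")
  expect_true(is.na(one_vs_rest_metrics(cmn, "REM")$sensitivity))
  expect_error(one_vs_rest_metrics(cmn, "N9"), "not present")
  perfect4 <- confusion_matrix(tibble::tibble(
    ref = c("W", "LS", "DS", "REM"), test = c("W", "LS", "DS", "REM"),
    ref_index = 0:3, test_index = 0:3), "FOUR")
  expect_equal(one_vs_rest_metrics(perfect4, "DS")$mcc, 1)
})

test_that("coarsening the resolution never loses matching pairs", {
  for (seed in 1:10) {
    pr <- random_pairs(300, 100 + seed)
    d4 <- sum(diag(confusion_matrix(pr, "FOUR")))
    d3 <- sum(diag(confusion_matrix(pr, "THREE")))
    d2 <- sum(diag(confusion_matrix(pr, "TWO")))
    expect_gte(d3, d4)
    expect_gte(d2, d3)
  }
})

test_that("pooled-matrix metrics equal concatenated-pair metrics", {
  prs <- lapply(1:6, function(i) random_pairs(200, 200 + i))
  pooled <- pool_matrices(lapply(prs, confusion_matrix, resolution = "TWO"))
  concat <- confusion_matrix(do.call(rbind, prs), "TWO")
  expect_equal(binary_metrics(pooled), binary_metrics(concat))
})

test_that("participant aggregation reproduces printed-style CIs", {
  agg <- aggregate_participants(rep(0.95, 18), bounds = c(0, 1))
  expect_equal(agg$sd, 0)
  expect_equal(agg$ci, c(0.95, 0.95))
  # normal-approximation CI from (mean, SD, n)
  ci <- 0.95 + c(-1, 1) * 1.96 * 0.02 / sqrt(18)
  expect_equal(round(ci, 2), c(0.94, 0.96))
  ci2 <- 0.63 + c(-1, 1) * 1.96 * 0.12 / sqrt(17)
  expect_equal(round(ci2, 2), c(0.57, 0.69))
  v <- c(0.2, NA, 0.4, 0.6)
  agg2 <- aggregate_participants(v, bounds = c(-1, 1))
  expect_equal(agg2$n, 3)
  expect_equal(agg2$n_missing, 1)
  expect_equal(agg2$mean, 0.4)
  expect_error(aggregate_participants(c(0.5, NA, NA)), "at least 2")
})

test_that("satisfactory EBE concordance uses strict MCC thresholds", {
  expect_true(is_satisfactory_ebe("NREM", 0.53))
  expect_false(is_satisfactory_ebe("SLEEP_WAKE", 0.63))
  expect_false(is_satisfactory_ebe("DS", 0.57))
  expect_error(is_satisfactory_ebe("N1", 0.5), "threshold")
})
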