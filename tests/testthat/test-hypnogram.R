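test_that("construction validates labels, vocabulary and epoch length", {
  h <- mk_hyp(c("W", "N2", "N3"))
  expect_s3_class(h, "hypnogram")
  expect_length(h, 3)
  expect_equal(h$epoch_len, 30)
  expect_equal(h$vocabulary, "FIVE")
  expect_error(mk_hyp(c("W", "N4")), "N4|vocabulary")
  expect_error(mk_hyp(c("W", "LS"), vocabulary = "FIVE"), "LS")
  expect_error(hypnogram("W", T0, epoch_len = 45), "30 or 60")
})

test_that("CSV dialect round-trips bit-exactly and rejects bad input", {
  h <- mk_hyp(c("W", "N2", "N3", "REM", "ART"), subject_id = "S01")
  f <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(h, f)
  expect_identical(readLines(f),
                   c("#start=2021-06-01T22:00:00", "#epoch_s=30", "stage",
                     "W", "N2", "N3", "REM", "ART"))
  h2 <- read_hypnogram(f, subject_id = "S01")
  expect_identical(h2$labels, h$labels)
  expect_identical(h2$start, h$start)
  expect_identical(h2$epoch_len, h$epoch_len)
  # second round trip is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(h2, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#start=2021-06-01T22:00:00", "#epoch_s=30", "stage",
               "W", "N4"), bad)
  expect_error(read_hypnogram(bad), "N4.*row 2")
  nohdr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#start=2021-06-01T22:00:00", "stage", "W"), nohdr)
  expect_error(read_hypnogram(nohdr), "epoch_s")
})

test_that("JSON twin and analysis-period files round-trip", {
  h <- mk_hyp(c("W", "LS", "DS"), epoch_len = 60)
  f <- withr::local_tempfile(fileext = ".json")
  write_hypnogram(h, f)
  h2 <- read_hypnogram(f)
  expect_identical(h2$labels, h$labels)
  expect_identical(h2$epoch_len, h$epoch_len)
  ap <- analysis_period(T0, "2021-06-02T07:00:00", kind = "automatic")
  g <- withr::local_tempfile(fileext = ".json")
  write_analysis_period(ap, g)
  ap2 <- read_analysis_period(g)
  expect_identical(ap2$t_start, ap$t_start)
  expect_identical(ap2$kind, "automatic")
})

test_that("stage mapping follows the default and alternate collapses", {
  h <- mk_hyp(c("W", "N1", "N2", "N3", "REM"))
  expect_identical(map_stages(h, "FOUR_DEFAULT")$labels,
                   c("W", "LS", "LS", "DS", "REM"))
  expect_identical(map_stages(h, "FOUR_ALT")$labels,
                   c("W", "LS", "DS", "DS", "REM"))
  h4 <- mk_hyp(c("W", "LS", "DS", "REM"))
  expect_identical(map_stages(h4, "TWO")$labels,
                   c("W", "SLEEP", "SLEEP", "SLEEP"))
  expect_identical(map_stages(h4, "THREE")$labels,
                   c("W", "NREM", "NREM", "REM"))
  # ART/ABSENT pass through every scheme
  ha <- mk_hyp(c("ART", "N2", "ABSENT"), vocabulary = "FIVE")
  expect_identical(map_stages(ha, "TWO")$labels, c("ART", "SLEEP", "ABSENT"))
  # not refinable
  h2 <- mk_hyp(c("W", "SLEEP"))
  expect_error(map_stages(h2, "FOUR_DEFAULT"), "vocabulary|apply")
  expect_error(map_stages(h4, "FOUR_DEFAULT"), "FOUR|FIVE")
})

test_that("60-to-30 s upsampling imputes from the next minute", {
  h <- mk_hyp(c("W", "N2"), epoch_len = 60)
  up <- upsample_to_30s(h)
  expect_identical(up$labels, c("W", "N2", "N2", "N2"))
  expect_equal(up$epoch_len, 30)
  expect_identical(upsample_to_30s(mk_hyp("W", epoch_len = 60))$labels,
                   c("W", "W"))
  expect_identical(upsample_to_30s(mk_hyp(rep("N2", 3), epoch_len = 60))$labels,
                   rep("N2", 6))
  expect_message(upsample_to_30s(mk_hyp(c("W", "W"))), "already")
})

test_that("upsampling conserves the 60-s labels across half pairs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    lab <- sample(c("W", "LS", "DS", "REM"), n, replace = TRUE)
    up <- upsample_to_30s(mk_hyp(lab, epoch_len = 60))
    expect_length(up$labels, 2 * n)
    firsts <- up$labels[seq(1, 2 * n, by = 2)]
    expect_identical(firsts, lab)
    seconds <- up$labels[seq(2, 2 * n, by = 2)]
    expect_identical(seconds, c(lab[-1], lab[n]))
  }
})

test_that("cropping keeps only epochs fully inside the period", {
  h <- mk_hyp(rep(c("W", "N2"), 10))  # 20 epochs, 10 min
  ap <- analysis_period(h$start + 4 * 30, h$start + 14 * 30)
  hc <- crop_to_period(h, ap)
  expect_length(hc, 10)
  expect_identical(hc$start, h$start + 4 * 30)
  expect_identical(hc$labels, h$labels[5:14])
  # identity on the full span
  expect_identical(crop_to_period(h, full_ap(h))$labels, h$labels)
  # boundary splitting an epoch excludes that epoch
  ap2 <- analysis_period(h$start + 15, h$start + 14 * 30)
  expect_length(crop_to_period(h, ap2), 13)
  expect_error(crop_to_period(h, analysis_period(h$start + 3600,
                                                 h$start + 7200)),
               "no complete epoch")
})

test_that("epoch pairing drops ART/ABSENT and reports indices", {
  ref <- mk_hyp(c("W", "N2", "ART", "N3"))
  test <- mk_hyp(c("W", "LS", "LS", "DS"))
  p <- pair_epochs(ref, test)
  expect_equal(nrow(p), 3)
  expect_equal(p$ref_index, c(0, 1, 3))
  expect_equal(attr(p, "dropped"), 2)
  p2 <- pair_epochs(mk_hyp(c("W", "W")), mk_hyp(c("ABSENT", "W")))
  expect_equal(nrow(p2), 1)
  expect_error(pair_epochs(mk_hyp(c("W", "W")),
                           mk_hyp(c("W", "W"), start = "2021-06-02T22:00:00")),
               "overlap")
  expect_error(pair_epochs(ref, mk_hyp(c("W", "LS"), epoch_len = 60)),
               "30-s")
})

test_that("pairing respects clock offsets snapped to the 30-s grid", {
  ref <- mk_hyp(c("W", "N1", "N2", "N3", "REM"))
  # test starts 2 epochs later: its epoch 0 aligns with ref epoch 2
  test <- mk_hyp(c("LS", "DS", "REM"), start = ref$start + 60)
  p <- pair_epochs(ref, test)
  expect_equal(nrow(p), 3)
  expect_equal(p$ref_index, 2:4)
  expect_equal(p$test_index, 0:2)
  expect_true(nrow(p) <= min(length(ref), length(test)))
})

test_that("mapping and cropping commute for every scheme", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(12:60, 1)
    h <- mk_hyp(sample(c("W", "N1", "N2", "N3", "REM", "ART"), n,
                       replace = TRUE), vocabulary = "FIVE")
    i0 <- sample(0:(n - 6), 1)
    ap <- analysis_period(h$start + i0 * 30, h$start + (i0 + 5) * 30)
    for (scheme in c("FOUR_DEFAULT", "FOUR_ALT", "THREE", "TWO")) {
      a <- crop_to_period(map_stages(h, scheme), ap)
      b <- map_stages(crop_to_period(h, ap), scheme)
      expect_identical(a$labels, b$labels)
      expect_identical(a$start, b$start)
    }
  }
})
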