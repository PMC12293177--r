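# Recording construction, rating binarization, trial-wise splitting,
# segmentation, resampling, and container round-trips.

test_that("binarize_rating follows the strict-greater rule and validates", {
  sp <- label_spec("valence", 5)
  expect_identical(binarize_rating(7.0, sp), 1L)
  expect_identical(binarize_rating(5.0, sp), 0L)
  expect_identical(binarize_rating(1.0, sp), 0L)
  expect_identical(binarize_rating(9.0, sp), 1L)
  expect_error(binarize_rating(0.5, sp), "1, 9")
  expect_error(binarize_rating(9.5, sp), "1, 9")
  # monotone in the rating
  r <- sort(runif(50, 1, 9))
  expect_true(all(diff(binarize_rating(r, sp)) >= 0))
  expect_error(label_spec("valence", 9), "strictly inside")
})

test_that("split_by_trial apportions by largest remainder and is seeded", {
  trials <- sprintf("s01/t%02d", 1:40)
  sp <- split_by_trial(trials, c(8, 1, 1), seed = 3L)
  expect_length(sp$train_trials, 32L)
  expect_length(sp$val_trials, 4L)
  expect_length(sp$test_trials, 4L)
  sp10 <- split_by_trial(sprintf("t%d", 1:10), c(8, 1, 1), seed = 1L)
  expect_identical(lengths(sp10[1:3]), c(train_trials = 8L, val_trials = 1L,
                                         test_trials = 1L))
  expect_identical(split_by_trial(trials, seed = 11L),
                   split_by_trial(trials, seed = 11L))
  expect_error(split_by_trial(c("a", "b"), seed = 1L), "at least")
  expect_error(split_by_trial(sprintf("t%d", 1:5), c(98, 1, 1), seed = 1L),
               "too few")
})

test_that("trial-wise splits are leakage-free over many seeds", {
  trials <- sprintf("s%02d/t%02d", rep(1:2, each = 20), rep(1:20, 2))
  for (seed in 1:30) {
    sp <- split_by_trial(trials, seed = seed)
    all_t <- c(sp$train_trials, sp$val_trials, sp$test_trials)
    expect_identical(sort(all_t), sort(trials))
    expect_identical(anyDuplicated(all_t), 0L)
  }
})

make_rec <- function(seconds, fs = 128, baseline_seconds = 0, ch = 4) {
  n <- round(seconds * fs)
  recording("s01", "t01", matrix(rnorm(ch * n), ch, n),
            matrix(rnorm(2 * n), 2, n), fs,
            c(valence = 7, arousal = 3),
            baseline_samples = round(baseline_seconds * fs))
}

test_that("segment_trial cuts non-overlapping windows and drops remainders", {
  rec <- make_rec(63, baseline_seconds = 3)
  segs <- segment_trial(rec, window_seconds = 4, drop_baseline = TRUE)
  expect_length(segs, 15L)
  expect_true(all(vapply(segs, function(s) ncol(s$eeg_block), 1L) == 512L))
  expect_identical(segs[[1]]$labels$valence, 1L)
  expect_identical(segs[[1]]$labels$arousal, 0L)
  # the first window starts right after the baseline
  expect_equal(segs[[1]]$eeg_block, rec$eeg[, 385:896])
  expect_length(segment_trial(make_rec(4)), 1L)
  expect_warning(s0 <- segment_trial(make_rec(3.9)), "shorter than one window")
  expect_length(s0, 0L)
  expect_error(segment_trial(make_rec(8), window_seconds = 4.0001), "integral")
})

test_that("segment counts are conserved across a cohort", {
  secs <- c(8, 12, 9.5, 4, 17)
  recs <- lapply(seq_along(secs), function(i) {
    r <- make_rec(secs[i], baseline_seconds = 0)
    r$trial_id <- sprintf("t%02d", i)
    r
  })
  segs <- segment_recordings(recs, window_seconds = 4)
  expect_length(segs, sum(floor(secs / 4)))
})

test_that("resample_signal preserves channels, length and amplitude", {
  x <- matrix(rnorm(2 * 1024), 2, 1024)
  y <- resample_signal(x, 256, 128)
  expect_identical(dim(y), c(2L, 512L))
  expect_identical(resample_signal(x, 128, 128), x)
  expect_error(resample_signal(x, 128, 256), "upsampling")
  expect_identical(dim(resample_signal(x, 128, 256, allow_upsample = TRUE)),
                   c(2L, 2048L))
  # a pure 10 Hz sinusoid survives 256 -> 128 Hz with amplitude within 1%
  t256 <- seq(0, 8 - 1 / 256, by = 1 / 256)
  s <- matrix(sin(2 * pi * 10 * t256), 1)
  y <- resample_signal(s, 256, 128)
  t128 <- seq(0, 8 - 1 / 128, by = 1 / 128)
  ref <- sin(2 * pi * 10 * t128)
  core <- 65:(length(ref) - 64)
  expect_lt(max(abs(y[1, core] - ref[core])), 0.01)
})

test_that("the native container round-trips recordings bit-exactly", {
  recs <- lapply(1:3, function(i) {
    r <- make_rec(6, baseline_seconds = 1)
    r$trial_id <- sprintf("t%02d", i)
    r$subject_id <- if (i < 3) "s01" else "s02"
    r
  })
  f <- withr::local_tempfile(fileext = ".rds")
  save_recordings(recs, f)
  back <- load_recordings(f, "container")
  expect_length(back, 3L)
  key <- function(l) vapply(l, function(r) paste(r$subject_id, r$trial_id), "")
  back <- back[match(key(recs), key(back))]
  for (i in 1:3) {
    expect_identical(back[[i]]$eeg, recs[[i]]$eeg)
    expect_identical(back[[i]]$eog, recs[[i]]$eog)
    expect_identical(back[[i]]$ratings, recs[[i]]$ratings)
    expect_identical(back[[i]]$baseline_samples, recs[[i]]$baseline_samples)
  }
  saveRDS(list(bogus = 1), f)
  expect_error(load_recordings(f, "container"), "format")
})

test_that("DEAP-layout arrays map channels and baseline correctly", {
  n_tr <- 40L
  dat <- array(rnorm(n_tr * 34 * 8064), c(n_tr, 34L, 8064L))
  labs <- matrix(runif(n_tr * 4, 1, 9), n_tr, 4)
  recs <- as_recordings(dat, labs, subject_id = "s07", fs = 128,
                        baseline_seconds = 3)
  expect_length(recs, 40L)
  expect_identical(nrow(recs[[1]]$eeg), 32L)
  expect_identical(nrow(recs[[1]]$eog), 2L)
  expect_identical(recs[[1]]$baseline_samples, 384L)
  expect_equal(recs[[5]]$eeg[3, ], dat[5, 3, ])
  expect_equal(recs[[5]]$eog[2, ], dat[5, 34, ])
  expect_equal(unname(recs[[5]]$ratings["valence"]), labs[5, 1])
  # the same layout loads from an RDS file
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(data = dat, labels = labs), f)
  recs2 <- load_recordings(f, "deap", subject_id = "s07")
  expect_equal(recs2[[5]]$eeg, recs[[5]]$eeg)
  saveRDS(list(data = dat), f)
  expect_error(load_recordings(f, "deap"), "labels")
})

test_that("split manifests round-trip through JSON", {
  sp <- split_by_trial(sprintf("s01/t%02d", 1:20), seed = 9L)
  f <- withr::local_tempfile(fileext = ".json")
  save_split(sp, f)
  back <- load_split(f)
  expect_identical(back$train_trials, sp$train_trials)
  expect_identical(back$test_trials, sp$test_trials)
  expect_identical(back$seed, sp$seed)
})

test_that("recording construction validates its invariants", {
  expect_error(recording("s", "t", matrix(0, 2, 10), matrix(0, 2, 8), 128,
                         c(valence = 5)), "sample count")
  expect_error(recording("s", "t", matrix(0, 2, 10), matrix(0, 2, 10), 0,
                         c(valence = 5)), "positive")
  expect_error(recording("s", "t", matrix(0, 2, 10), matrix(0, 2, 10), 128,
                         c(valence = 11)), "\\[1, 9\\]")
  expect_error(recording("s", "t", matrix(0, 2, 10), matrix(0, 2, 10), 128,
                         c(valence = 5), baseline_samples = 10), "baseline")
})
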