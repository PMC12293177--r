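# Generator properties: seeded determinism, label/ground-truth consistency,
# blink statistics, spectral class signal, and cross-modal coupling.

small_spec <- function(...) {
  cohort_spec(n_subjects = 2L, n_trials_per_subject = 5L, trial_seconds = 4,
              baseline_seconds = 0, fs = 64, n_eeg_channels = 4L, ...)
}

test_that("generate_cohort is a pure function of its spec", {
  a <- generate_cohort(small_spec(seed = 7L))
  b <- generate_cohort(small_spec(seed = 7L))
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$ground_truth$classes, b$ground_truth$classes)
  expect_false(identical(
    a$recordings[[1]]$eeg,
    generate_cohort(small_spec(seed = 8L))$recordings[[1]]$eeg))
  expect_length(a$recordings, 10L)
})

test_that("emitted ratings re-binarize to the ground-truth classes", {
  co <- generate_cohort(small_spec(seed = 11L))
  gt <- co$ground_truth$classes
  for (i in seq_along(co$recordings)) {
    r <- co$recordings[[i]]
    expect_identical(binarize_rating(r$ratings[["valence"]]),
                     gt$class_valence[i])
    expect_identical(binarize_rating(r$ratings[["arousal"]]),
                     gt$class_arousal[i])
  }
})

test_that("degenerate cohort specs are rejected", {
  expect_error(cohort_spec(n_subjects = 0L), "positive")
  expect_error(cohort_spec(trial_seconds = 0), "positive")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(shared_latent_weight = 1.5), "\\[0, 1\\]")
  expect_error(cohort_spec(baseline_seconds = 99), "baseline")
})

test_that("inject_blinks is the identity at rate or amplitude zero and adds
           Poisson-distributed events otherwise", {
  x <- matrix(rnorm(2 * 640), 2, 640)
  expect_identical(inject_blinks(x, 0, 5, fs = 64), x)
  expect_identical(inject_blinks(x, 0.3, 0, fs = 64), x)
  # estimate the event count from the added template mass; over 200 seeds
  # the mean count must sit inside the 99% interval of a Poisson mean
  fs <- 128
  quiet <- matrix(0, 1, 60 * fs)
  tmpl_mass <- sum(emokd:::blink_template(fs))
  counts <- vapply(1:200, function(s) {
    out <- inject_blinks(quiet, 0.3, 1, fs = fs, seed = s)
    sum(out) / tmpl_mass
  }, numeric(1))
  lam <- 0.3 * 60
  se <- sqrt(lam / 200)
  expect_gt(mean(counts), lam - 3 * se - 0.3)
  expect_lt(mean(counts), lam + 3 * se)
  expect_error(inject_blinks(x, -1, 5), ">= 0")
})

test_that("EEG alpha-band class margin grows with eeg_snr", {
  margin <- function(snr) {
    co <- generate_cohort(cohort_spec(
      n_subjects = 2L, n_trials_per_subject = 50L, trial_seconds = 4,
      baseline_seconds = 0, fs = 64, n_eeg_channels = 4L, eeg_snr = snr,
      eog_snr = 0, trial_sd = 0, shared_latent_weight = 0, seed = 31L))
    pow <- vapply(co$recordings, function(r) {
      mean(apply(r$eeg, 1, function(x) bandpower(x, r$fs, c(8, 13))))
    }, numeric(1))
    cl <- co$ground_truth$classes$class_valence
    mean(pow[cl == 1]) - mean(pow[cl == 0])
  }
  m0 <- margin(0); m1 <- margin(0.8); m2 <- margin(2.5)
  expect_gt(m2, m1)
  expect_gt(m1, m0)
  expect_gt(m2, 0)
})

test_that("cross-modal coupling tracks shared_latent_weight", {
  coupling <- function(w) {
    co <- generate_cohort(cohort_spec(
      n_subjects = 1L, n_trials_per_subject = 20L, trial_seconds = 6,
      baseline_seconds = 0, fs = 64, n_eeg_channels = 8L,
      shared_latent_weight = w, eeg_snr = 0, eog_snr = 0, trial_sd = 0,
      blink_rate = 0.2, seed = 53L))
    mean(vapply(seq_along(co$recordings), function(i) {
      r <- co$recordings[[i]]
      lat <- co$ground_truth$latents[[emokd:::trial_key(r)]]
      z_eeg <- as.vector(crossprod(lat$map_eeg, r$eeg)) / sum(lat$map_eeg^2)
      z_eog <- as.vector(crossprod(lat$map_eog, r$eog)) / sum(lat$map_eog^2)
      abs(cor(z_eeg, z_eog))
    }, numeric(1)))
  }
  c0 <- coupling(0); c5 <- coupling(0.5); c1 <- coupling(1)
  expect_lt(c0, 0.15)
  expect_gt(c5, c0)
  expect_gt(c1, c5)
})

test_that("a bandpower probe scores higher on EEG than on EOG features", {
  co <- cached("probe_cohort", generate_cohort(cohort_spec(
    n_subjects = 6L, n_trials_per_subject = 12L, trial_seconds = 4,
    baseline_seconds = 0, fs = 64, n_eeg_channels = 8L,
    eeg_snr = 2, eog_snr = 0.5, shared_latent_weight = 0.7, seed = 77L)))
  cl <- co$ground_truth$classes$class_valence
  eeg_feat <- vapply(co$recordings, function(r) {
    log(mean(apply(r$eeg, 1, function(x) bandpower(x, r$fs, c(8, 13)))))
  }, numeric(1))
  eog_feat <- vapply(co$recordings, function(r) {
    log(mean(pmax(r$eog[1, ], 0)^2) + 1e-9)
  }, numeric(1))
  cv_acc <- function(x) {
    folds <- rep(1:4, length.out = length(x))
    mean(vapply(1:4, function(k) {
      fit <- stats::glm(cl[folds != k] ~ x[folds != k], family = binomial)
      pr <- stats::plogis(coef(fit)[1] + coef(fit)[2] * x[folds == k])
      mean((pr > 0.5) == cl[folds == k])
    }, numeric(1)))
  }
  expect_gt(cv_acc(eeg_feat), cv_acc(eog_feat))
  expect_gt(cv_acc(eeg_feat), 0.75)
})
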