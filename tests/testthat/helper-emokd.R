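# Shared fixtures: toy model configurations small enough for finite
# differences, synthetic micro-cohorts, and a cache so expensive objects are
# built once per test run.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  v <- get0(key, envir = .test_cache)
  if (is.null(v)) {
    v <- force(expr)
    assign(key, v, envir = .test_cache)
  }
  v
}

toy_teacher_cfg <- function(d = 8L) {
  teacher_config(fs = 16, n_eeg_channels = 3L, n_eog_channels = 2L,
                 d_model = d, n_heads = 2L, n_layers = 2L, ff_width = 2L * d,
                 conv_filters = 2L, conv_kernel = 8L, conv_stride = 4L,
                 dropout = 0, ie_hidden = d, conv_activation = "relu")
}

toy_student_cfg <- function(d = 8L) {
  student_config(fs = 16, n_eog_channels = 2L, d_model = d, n_heads = 2L,
                 n_layers = 3L, ff_width = 2L * d, conv_filters = 2L,
                 conv_kernel = 8L, conv_stride = 4L, dropout = 0,
                 he_hidden = d, align_width = 2L * d,
                 conv_activation = "relu")
}

# random labeled segments matching the toy configs (1 s at 16 Hz)
toy_segments <- function(n, seed = 1L, samples = 16L, ch_eeg = 3L,
                         ch_eog = 2L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    structure(
      list(eeg_block = matrix(rnorm(ch_eeg * samples), ch_eeg, samples),
           eog_block = matrix(rnorm(ch_eog * samples), ch_eog, samples),
           labels = list(valence = sample(0:1, 1), arousal = sample(0:1, 1)),
           provenance = list(subject_id = "sx", trial_id = sprintf("t%02d", i),
                             segment_index = 1L),
           fs = 16),
      class = "emokd_segment")
  }))
}

# micro cohort + matching narrow model configs for fast training smoke runs
micro_cohort <- function() {
  cached("micro_cohort", generate_cohort(cohort_spec(
    n_subjects = 3L, n_trials_per_subject = 10L, trial_seconds = 4,
    baseline_seconds = 0, fs = 64, n_eeg_channels = 8L, n_eog_channels = 2L,
    eeg_snr = 2, eog_snr = 0.5, shared_latent_weight = 0.7, trial_sd = 0.3,
    seed = 42L)))
}

micro_teacher_cfg <- function() {
  teacher_config(fs = 64, n_eeg_channels = 8L, n_eog_channels = 2L,
                 d_model = 16L, n_heads = 2L, n_layers = 2L, ff_width = 32L,
                 conv_filters = 4L, conv_kernel = 32L, conv_stride = 16L,
                 dropout = 0, ie_hidden = 32L, conv_activation = "abs")
}

micro_student_cfg <- function() {
  student_config(fs = 64, n_eog_channels = 2L, d_model = 16L, n_heads = 2L,
                 n_layers = 3L, ff_width = 32L, conv_filters = 4L,
                 conv_kernel = 32L, conv_stride = 16L, dropout = 0,
                 he_hidden = 32L, align_width = 32L, conv_activation = "abs")
}

micro_partitions <- function() {
  cached("micro_parts", {
    co <- micro_cohort()
    split <- split_by_trial_per_subject(co$recordings, seed = 5L)
    segs <- segment_recordings(co$recordings, split = split)
    list(split = split,
         train = Filter(function(s) identical(s$partition, "train"), segs),
         val = Filter(function(s) identical(s$partition, "val"), segs),
         test = Filter(function(s) identical(s$partition, "test"), segs))
  })
}

# central-difference derivative of f (scalar) at selected coordinates of a
# named list of parameter matrices
num_grad_params <- function(f, params, coords, eps = 1e-5) {
  vapply(seq_len(nrow(coords)), function(r) {
    nm <- coords$param[r]; i <- coords$index[r]
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    (f(pp) - f(pm)) / (2 * eps)
  }, numeric(1))
}

# pick the k largest-magnitude coordinates of an analytic gradient list
top_coords <- function(grads, k = 25L) {
  rows <- do.call(rbind, lapply(names(grads), function(nm) {
    g <- grads[[nm]]
    data.frame(param = nm, index = seq_along(g), g = as.vector(g),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(-abs(rows$g)), ]
  utils::head(rows, k)
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-10)
}
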