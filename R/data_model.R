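# Canonical representation of trial-structured EEG+EOG recordings:
# construction and validation, rating binarization, leakage-safe trial-wise
# splitting, resampling, 4-s segmentation, and the native cohort container.

#' Construct a trial recording
#'
#' A `Recording` holds one trial's multichannel EEG and EOG signals (channels
#' in rows, samples in columns, microvolt-scale arbitrary units), the
#' sampling rate, the trial's self-reported 1-9 affect ratings, and the
#' number of leading baseline samples.
#'
#' @param subject_id,trial_id Opaque identifiers.
#' @param eeg,eog Numeric matrices `[channels x samples]`; must share the
#'   sample count.
#' @param fs Sampling rate in Hz.
#' @param ratings Named numeric vector/list with entries in `[1, 9]`,
#'   typically `valence` and `arousal`.
#' @param baseline_samples Count of leading baseline samples (default 0).
#' @return An object of class `emokd_recording`.
#' @export
recording <- function(subject_id, trial_id, eeg, eog, fs, ratings,
                      baseline_samples = 0L) {
  eeg <- as.matrix(eeg); eog <- as.matrix(eog)
  if (ncol(eeg) != ncol(eog)) {
    stop("eeg and eog must share the sample count (got ",
         ncol(eeg), " vs ", ncol(eog), ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling rate in Hz")
  }
  ratings <- unlist(ratings)
  if (is.null(names(ratings)) || any(!nzchar(names(ratings)))) {
    stop("ratings must be named (e.g. valence, arousal)")
  }
  if (any(ratings < 1 | ratings > 9)) {
    stop("ratings must lie in [1, 9]")
  }
  baseline_samples <- as.integer(baseline_samples)
  if (baseline_samples < 0L || baseline_samples >= ncol(eeg)) {
    stop("baseline_samples must be non-negative and smaller than n_samples")
  }
  structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         eeg = eeg, eog = eog, fs = fs,
         ratings = ratings, baseline_samples = baseline_samples),
    class = "emokd_recording")
}

#' @export
print.emokd_recording <- function(x, ...) {
  cat(sprintf(
    "<recording %s/%s: %d EEG + %d EOG channels, %d samples @ %g Hz, %s>\n",
    x$subject_id, x$trial_id, nrow(x$eeg), nrow(x$eog), ncol(x$eeg), x$fs,
    paste(sprintf("%s=%.2f", names(x$ratings), x$ratings), collapse = " ")))
  invisible(x)
}

#' Label specification for rating binarization
#'
#' Maps a 1-9 affect rating to a binary class with a strict-greater rule:
#' class 1 iff `rating > threshold`. The conventional cut on the nine-point
#' scale is 5.
#'
#' @param dimension `"valence"` or `"arousal"`.
#' @param threshold Cut-point, strictly inside `(1, 9)`; default 5.
#' @return An object of class `emokd_label_spec`.
#' @export
label_spec <- function(dimension = c("valence", "arousal"), threshold = 5) {
  dimension <- match.arg(dimension)
  if (!is.numeric(threshold) || threshold <= 1 || threshold >= 9) {
    stop("threshold must lie strictly inside (1, 9)")
  }
  structure(list(dimension = dimension, threshold = threshold),
            class = "emokd_label_spec")
}

#' Binarize an affect rating
#'
#' @param rating Numeric rating(s) in `[1, 9]`.
#' @param spec A [label_spec()].
#' @return Integer 0/1 vector: 1 iff `rating > spec$threshold`.
#' @export
binarize_rating <- function(rating, spec = label_spec()) {
  if (any(!is.finite(rating)) || any(rating < 1 | rating > 9)) {
    stop("rating must lie in [1, 9]")
  }
  as.integer(rating > spec$threshold)
}

#' Leakage-safe trial-wise split
#'
#' Partitions whole trials into train/validation/test sets so that no trial
#' contributes segments to more than one partition. Partition sizes follow
#' the largest-remainder apportionment of the trial count by `ratios`
#' (8:1:1 by default), which is deterministic and ratio-faithful for counts
#' that do not divide evenly.
#'
#' @param trials Character vector of trial keys (or a list of recordings,
#'   whose `subject/trial` keys are used).
#' @param ratios Length-3 positive numeric vector, default `c(8, 1, 1)`.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return An object of class `emokd_trial_split` with elements
#'   `train_trials`, `val_trials`, `test_trials`, `seed`, `ratios`.
#' @export
split_by_trial <- function(trials, ratios = c(8, 1, 1), seed = 1L) {
  if (is.list(trials)) trials <- vapply(trials, trial_key, character(1))
  trials <- as.character(trials)
  if (anyDuplicated(trials)) stop("trial ids must be unique")
  n <- length(trials)
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("ratios must be three positive numbers")
  }
  if (n < 3L) stop("need at least as many trials as partitions")
  sizes <- largest_remainder(n, ratios)
  if (any(sizes == 0L)) {
    stop("too few trials (", n, ") to fill all three partitions at ratios ",
         paste(ratios, collapse = ":"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- sample(trials)
  structure(
    list(train_trials = sort(perm[seq_len(sizes[1L])]),
         val_trials = sort(perm[sizes[1L] + seq_len(sizes[2L])]),
         test_trials = sort(perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])]),
         seed = as.integer(seed), ratios = ratios),
    class = "emokd_trial_split")
}

# largest-remainder apportionment of n by positive weights
largest_remainder <- function(n, w) {
  q <- n * w / sum(w)
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    take <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[take] <- fl[take] + 1
  }
  as.integer(fl)
}

trial_key <- function(rec) paste(rec$subject_id, rec$trial_id, sep = "/")

#' Split every subject's trials independently
#'
#' Applies [split_by_trial()] per subject (subject-dependent protocol) and
#' concatenates the partitions.
#'
#' @param recordings List of [recording()] objects.
#' @inheritParams split_by_trial
#' @return An `emokd_trial_split` over all subjects' trials.
#' @export
split_by_trial_per_subject <- function(recordings, ratios = c(8, 1, 1),
                                       seed = 1L) {
  subj <- vapply(recordings, function(r) r$subject_id, character(1))
  keys <- vapply(recordings, trial_key, character(1))
  parts <- list(train_trials = character(), val_trials = character(),
                test_trials = character())
  for (s in unique(subj)) {
    sp <- split_by_trial(keys[subj == s], ratios = ratios, seed = seed)
    parts$train_trials <- c(parts$train_trials, sp$train_trials)
    parts$val_trials <- c(parts$val_trials, sp$val_trials)
    parts$test_trials <- c(parts$test_trials, sp$test_trials)
  }
  structure(c(lapply(parts, sort), list(seed = as.integer(seed),
                                        ratios = ratios)),
            class = "emokd_trial_split")
}

#' Segment a recording into fixed windows
#'
#' Cuts the usable signal (after optional removal of the leading baseline)
#' into consecutive non-overlapping windows of `window_seconds`; a trailing
#' remainder shorter than one window is dropped. Each segment carries the
#' binarized labels for every supplied label dimension and its provenance
#' `(subject_id, trial_id, segment_index)`.
#'
#' @param rec A [recording()].
#' @param window_seconds Window length in seconds (default 4); must give an
#'   integral sample count at `rec$fs`.
#' @param drop_baseline Remove the leading `baseline_samples` first
#'   (default `TRUE`).
#' @param label_specs List of [label_spec()]s, default valence and arousal
#'   at threshold 5.
#' @return List of `emokd_segment` objects (possibly empty, with a warning).
#' @export
segment_trial <- function(rec, window_seconds = 4, drop_baseline = TRUE,
                          label_specs = default_label_specs()) {
  ws <- window_seconds * rec$fs
  if (abs(ws - round(ws)) > 1e-9) {
    stop("window_seconds x fs must be an integral sample count")
  }
  ws <- as.integer(round(ws))
  start <- if (drop_baseline) rec$baseline_samples else 0L
  usable <- ncol(rec$eeg) - start
  n_seg <- usable %/% ws
  if (n_seg < 1L) {
    warning(sprintf("trial %s: usable signal (%d samples) shorter than one window",
                    trial_key(rec), usable))
    return(list())
  }
  labels <- list()
  for (sp in label_specs) {
    if (!sp$dimension %in% names(rec$ratings)) next
    labels[[sp$dimension]] <- binarize_rating(rec$ratings[[sp$dimension]], sp)
  }
  lapply(seq_len(n_seg), function(i) {
    cols <- start + (i - 1L) * ws + seq_len(ws)
    structure(
      list(eeg_block = rec$eeg[, cols, drop = FALSE],
           eog_block = rec$eog[, cols, drop = FALSE],
           labels = labels,
           provenance = list(subject_id = rec$subject_id,
                             trial_id = rec$trial_id, segment_index = i),
           fs = rec$fs),
      class = "emokd_segment")
  })
}

default_label_specs <- function(threshold = 5) {
  list(label_spec("valence", threshold), label_spec("arousal", threshold))
}

#' Segment many recordings and attach partition roles
#'
#' @param recordings List of [recording()] objects.
#' @param split Optional `emokd_trial_split`; when given, each segment gains
#'   a `partition` field (`train`/`val`/`test`).
#' @inheritParams segment_trial
#' @return Flat list of segments.
#' @export
segment_recordings <- function(recordings, split = NULL, window_seconds = 4,
                               drop_baseline = TRUE,
                               label_specs = default_label_specs()) {
  out <- list()
  for (rec in recordings) {
    segs <- segment_trial(rec, window_seconds, drop_baseline, label_specs)
    if (!is.null(split)) {
      key <- trial_key(rec)
      part <- if (key %in% split$train_trials) "train"
      else if (key %in% split$val_trials) "val"
      else if (key %in% split$test_trials) "test"
      else NA_character_
      for (i in seq_along(segs)) segs[[i]]$partition <- part
    }
    out <- c(out, segs)
  }
  out
}

#' Resample a multichannel signal
#'
#' Rational-factor FIR resampling of each channel from `fs_in` to `fs_out`:
#' zero-stuff by `p`, apply a windowed-sinc anti-aliasing lowpass designed
#' with [signal::fir1()], compensate the filter's group delay, and keep
#' every `q`-th sample. Output length is exactly
#' `round(n_samples * fs_out / fs_in)`; edge samples within half a filter
#' length of the boundaries carry the usual transient. Upsampling is
#' refused unless `allow_upsample = TRUE`.
#'
#' @param x Numeric matrix `[channels x samples]` (a vector is treated as
#'   one channel).
#' @param fs_in,fs_out Input/output sampling rates in Hz.
#' @param allow_upsample Permit `fs_out > fs_in` (default `FALSE`).
#' @return Matrix `[channels x round(n * fs_out / fs_in)]`.
#' @export
resample_signal <- function(x, fs_in, fs_out = 128, allow_upsample = FALSE) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  if (fs_out > fs_in && !allow_upsample) {
    stop("fs_out > fs_in: upsampling refused (set allow_upsample = TRUE)")
  }
  if (fs_in == fs_out) return(x)
  g <- pracma_gcd(round(fs_out * 1e6), round(fs_in * 1e6))
  p <- round(fs_out * 1e6) / g
  q <- round(fs_in * 1e6) / g
  n <- ncol(x)
  n_out <- round(n * fs_out / fs_in)
  # windowed-sinc lowpass at the tighter of the two Nyquist limits,
  # on the p-fold upsampled grid
  taps <- 2L * 10L * max(p, q)
  h <- signal::fir1(taps, min(1 / p, 1 / q)) * p
  delay <- taps / 2L
  out <- matrix(0, nrow(x), n_out)
  pick <- (seq_len(n_out) - 1L) * q + 1L + delay
  for (c in seq_len(nrow(x))) {
    up <- numeric(n * p)
    up[seq(1L, n * p, by = p)] <- x[c, ]
    full <- stats::convolve(up, rev(h), type = "open")
    out[c, ] <- full[pick]
  }
  out
}

pracma_gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# ---- container I/O --------------------------------------------------------

#' Save recordings to the native cohort container
#'
#' Serializes the cohort as a structured list
#' (`subjects/<id>/trials/<id>/{eeg, eog, ratings, fs, baseline_samples}`)
#' in an RDS file. Signals and metadata round-trip bit-exactly.
#'
#' @param recordings List of [recording()]s.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_recordings <- function(recordings, path) {
  subjects <- list()
  for (rec in recordings) {
    sid <- rec$subject_id
    if (is.null(subjects[[sid]])) subjects[[sid]] <- list(trials = list())
    subjects[[sid]]$trials[[rec$trial_id]] <-
      list(eeg = rec$eeg, eog = rec$eog, ratings = rec$ratings,
           fs = rec$fs, baseline_samples = rec$baseline_samples)
  }
  saveRDS(list(format = "emokd-cohort", version = 1L, subjects = subjects),
          path, version = 2)
  invisible(path)
}

#' Load recordings
#'
#' Reads either the native cohort container written by [save_recordings()]
#' (`format = "container"`) or an RDS file in the DEAP-style layout
#' (`format = "deap"`): a list with elements `data`
#' (`trials x channels x samples` array) and `labels` (`trials x 4` matrix of
#' valence, arousal, dominance, liking ratings), interpreted with the DEAP
#' channel convention via [as_recordings()].
#'
#' @param path Input file path.
#' @param format `"container"` or `"deap"`.
#' @param ... Passed to [as_recordings()] for the DEAP layout.
#' @return List of [recording()]s, one per trial.
#' @export
load_recordings <- function(path, format = c("container", "deap"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  if (format == "container") {
    if (!identical(obj$format, "emokd-cohort")) {
      stop("parse error: missing/invalid 'format' field (expected 'emokd-cohort')")
    }
    out <- list()
    for (sid in names(obj$subjects)) {
      trials <- obj$subjects[[sid]]$trials
      for (tid in names(trials)) {
        tr <- trials[[tid]]
        for (f in c("eeg", "eog", "ratings", "fs", "baseline_samples")) {
          if (is.null(tr[[f]])) {
            stop("parse error in subject ", sid, " trial ", tid,
                 ": missing field '", f, "'")
          }
        }
        out[[length(out) + 1L]] <- recording(
          sid, tid, tr$eeg, tr$eog, tr$fs, tr$ratings, tr$baseline_samples)
      }
    }
    out
  } else {
    if (is.null(obj$data) || is.null(obj$labels)) {
      stop("parse error: DEAP layout needs fields 'data' and 'labels'")
    }
    as_recordings(obj$data, obj$labels, ...)
  }
}

#' Convert a DEAP-layout array to recordings
#'
#' DEAP's preprocessed per-subject layout is a `trials x channels x samples`
#' array plus a `trials x 4` ratings matrix (valence, arousal, dominance,
#' liking). EEG is the first 32 channels; EOG is the two dedicated
#' horizontal/vertical EOG channels of the peripheral block (channels 33-34
#' by default).
#'
#' @param data 3-d array `[trials x channels x samples]`.
#' @param labels Matrix `[trials x >=2]`, columns valence then arousal.
#' @param subject_id Subject identifier for all trials.
#' @param fs Sampling rate (default 128 Hz).
#' @param baseline_seconds Leading baseline duration (default 3 s).
#' @param eeg_channels,eog_channels Channel index vectors.
#' @return List of [recording()]s, one per trial.
#' @export
as_recordings <- function(data, labels, subject_id = "s01", fs = 128,
                          baseline_seconds = 3,
                          eeg_channels = 1:32, eog_channels = 33:34) {
  if (length(dim(data)) != 3L) stop("data must be trials x channels x samples")
  n_trials <- dim(data)[1L]
  labels <- as.matrix(labels)
  if (nrow(labels) != n_trials) stop("labels rows must match trial count")
  if (max(c(eeg_channels, eog_channels)) > dim(data)[2L]) {
    stop("channel index exceeds available channels")
  }
  bl <- as.integer(round(baseline_seconds * fs))
  lapply(seq_len(n_trials), function(i) {
    recording(subject_id, sprintf("t%02d", i),
              eeg = data[i, eeg_channels, , drop = TRUE],
              eog = data[i, eog_channels, , drop = TRUE],
              fs = fs,
              ratings = c(valence = labels[i, 1L], arousal = labels[i, 2L]),
              baseline_samples = bl)
  })
}

#' Write a split manifest
#'
#' JSON manifest listing the trial keys per partition plus the seed, so a
#' split can be archived next to run outputs and reloaded exactly.
#'
#' @param split An `emokd_trial_split`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
save_split <- function(split, path) {
  jsonlite::write_json(
    list(train_trials = split$train_trials, val_trials = split$val_trials,
         test_trials = split$test_trials, seed = split$seed,
         ratios = split$ratios),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a split manifest written by [save_split()]
#' @param path JSON path.
#' @return An `emokd_trial_split`.
#' @export
load_split <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_trials = as.character(o$train_trials),
                 val_trials = as.character(o$val_trials),
                 test_trials = as.character(o$test_trials),
                 seed = as.integer(o$seed), ratios = as.numeric(o$ratios)),
            class = "emokd_trial_split")
}
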