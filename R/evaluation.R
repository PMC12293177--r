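# Metrics, paired significance testing, trial-wise model evaluation, and the
# ablation / leakage experiment drivers.

#' Confusion counts for a binary task
#'
#' Positive class is class 1 (high rating).
#'
#' @param predicted,actual Integer 0/1 vectors of equal length.
#' @return Object of class `emokd_confusion`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (!all(predicted %in% 0:1) || !all(actual %in% 0:1)) {
    stop("predictions and labels must be 0/1")
  }
  structure(list(TP = sum(predicted == 1L & actual == 1L),
                 TN = sum(predicted == 0L & actual == 0L),
                 FP = sum(predicted == 1L & actual == 0L),
                 FN = sum(predicted == 0L & actual == 1L)),
            class = "emokd_confusion")
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c An [confusion_counts()] object.
#' @return Real in `[0, 1]`.
#' @export
accuracy <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("undefined metric: no evaluated samples")
  (c$TP + c$TN) / total
}

#' F1 score (positive class 1)
#'
#' `2 TP / (2 TP + FP + FN)`: the harmonic mean of precision and recall for
#' the high-rating class. When the positive class is entirely absent from
#' predictions and labels (`2 TP + FP + FN = 0`) the score is defined as 0
#' with a warning.
#'
#' @param c An [confusion_counts()] object.
#' @return Real in `[0, 1]`.
#' @export
f1_score <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("undefined metric: no evaluated samples")
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) {
    warning("no positive instances in predictions or labels; F1 set to 0")
    return(0)
  }
  2 * c$TP / den
}

#' Macro-averaged F1
#'
#' Mean of the per-class F1 scores; exposed alongside the single-class
#' default.
#'
#' @inheritParams f1_score
#' @return Real in `[0, 1]`.
#' @export
f1_macro <- function(c) {
  f_pos <- {
    den <- 2 * c$TP + c$FP + c$FN
    if (den == 0) 0 else 2 * c$TP / den
  }
  f_neg <- {
    den <- 2 * c$TN + c$FN + c$FP
    if (den == 0) 0 else 2 * c$TN / den
  }
  (f_pos + f_neg) / 2
}

#' Two-sided paired t-test
#'
#' Thin wrapper over [stats::t.test()] with `paired = TRUE`; inputs must be
#' aligned by a common pairing key (seed, subject, fold). Degenerate
#' zero-variance differences are flagged and reported as `p = NaN`.
#'
#' @param scores_a,scores_b Equal-length numeric vectors.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("paired scores must align")
  if (length(scores_a) < 2L) stop("need at least two pairs")
  d <- scores_a - scores_b
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0))
    }
    warning("zero-variance nonconstant differences; p reported as NaN")
    return(list(t = NaN, p = NaN, df = length(d) - 1L, mean_diff = mean(d)))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' Evaluate a trained model on a segment partition
#'
#' Aggregates confusion counts over all segments for the model's label
#' dimension, attaches accuracy and F1, and keeps the per-segment
#' predictions so every reported number can be re-derived.
#'
#' @param model An `emokd_teacher` or `emokd_student` carrying a
#'   `dimension` field (or pass `dimension`).
#' @param segments Non-empty list of segments (normally the test
#'   partition).
#' @param dimension Label dimension override.
#' @param partition Partition name recorded in the access log (default
#'   `"test"`).
#' @return Object of class `emokd_run_result`: `accuracy`, `f1`, `counts`,
#'   `dimension`, `n`, and a `predictions` data frame.
#' @export
evaluate_model <- function(model, segments, dimension = NULL,
                           partition = "test") {
  if (length(segments) == 0L) stop("empty evaluation set")
  dimension <- dimension %||% model$dimension
  if (is.null(dimension)) stop("no label dimension given")
  log_access(partition, "evaluate_model", length(segments))
  probs <- model_probs(model, segments)
  pred <- max.col(probs) - 1L
  labs <- vapply(segments, function(s) s$labels[[dimension]], integer(1))
  cc <- confusion_counts(pred, labs)
  prov <- do.call(rbind, lapply(segments, function(s) {
    data.frame(subject_id = s$provenance$subject_id,
               trial_id = s$provenance$trial_id,
               segment_index = s$provenance$segment_index,
               stringsAsFactors = FALSE)
  }))
  prov$label <- labs
  prov$predicted <- pred
  prov$p1 <- probs[, 2L]
  structure(list(accuracy = accuracy(cc), f1 = f1_score(cc), counts = cc,
                 dimension = dimension, n = length(segments),
                 predictions = prov),
            class = "emokd_run_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.emokd_run_result <- function(x, ...) {
  cat(sprintf("<%s: accuracy %.4f, F1 %.4f on %d segments>\n",
              x$dimension, x$accuracy, x$f1, x$n))
  invisible(x)
}

# shared prep: cohort -> per-subject split -> role-tagged segments
prepare_partitions <- function(cohort, split_seed, window_seconds = 4,
                               ratios = c(8, 1, 1)) {
  split <- split_by_trial_per_subject(cohort$recordings, ratios = ratios,
                                      seed = split_seed)
  segs <- segment_recordings(cohort$recordings, split = split,
                             window_seconds = window_seconds)
  list(split = split,
       train = Filter(function(s) identical(s$partition, "train"), segs),
       val = Filter(function(s) identical(s$partition, "val"), segs),
       test = Filter(function(s) identical(s$partition, "test"), segs))
}

#' Ablation study over the three distillation variations
#'
#' For every seed: split the cohort trial-wise per subject, pretrain one
#' teacher per label dimension, run variations 1-3 of the distillation, and
#' evaluate each best student on the held-out test trials. Emits the
#' per-run records, a mean +/- sd summary per (variation, dimension), and
#' paired t-tests of variation 3 against variation 1.
#'
#' @param cohort An `emokd_cohort`.
#' @param cfg Experiment configuration, as returned by [benchmark_config()]
#'   (model configs, loss weights, schedule, budgets).
#' @param seeds Integer vector (>= 3 for the t-tests to be meaningful).
#' @param dimensions Label dimensions to evaluate.
#' @param verbose Print progress lines.
#' @return List of class `emokd_ablation`: `records` (one row per
#'   seed/variation/dimension), `summary`, `tests` (V3 vs V1 per
#'   dimension).
#' @export
run_ablation <- function(cohort, cfg = benchmark_config(), seeds = 1:5,
                         dimensions = c("valence", "arousal"),
                         verbose = FALSE) {
  records <- list()
  for (seed in seeds) {
    parts <- prepare_partitions(cohort, split_seed = seed,
                                window_seconds = cfg$window_seconds)
    for (dim in dimensions) {
      sub_seeds <- derive_seeds(seed + 7919L * match(dim, dimensions), 4L)
      teacher <- pretrain_teacher(parts$train, parts$val, cfg$teacher_cfg,
                                  dimension = dim,
                                  epochs = cfg$pretrain_epochs,
                                  batch_size = cfg$batch_size,
                                  lr = cfg$teacher_lr %||% cfg$lr,
                                  seed = sub_seeds[1L])
      for (v in 1:3) {
        run <- run_distillation(parts$train, parts$val, dim, teacher,
                                cfg$student_cfg, variation = v,
                                w = cfg$weights, schedule = cfg$schedule,
                                epochs = cfg$distill_epochs,
                                batch_size = cfg$batch_size, lr = cfg$lr,
                                seed = sub_seeds[1L + v])
        res <- evaluate_model(run$student, parts$test)
        if (verbose) {
          message(sprintf("seed %d %s V%d: acc %.3f f1 %.3f",
                          seed, dim, v, res$accuracy, res$f1))
        }
        records[[length(records) + 1L]] <-
          data.frame(seed = seed, variation = v, dimension = dim,
                     accuracy = res$accuracy, f1 = res$f1,
                     n_test = res$n, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  summary <- stats::aggregate(cbind(accuracy, f1) ~ variation + dimension,
                              data = records, FUN = mean)
  sds <- stats::aggregate(cbind(accuracy, f1) ~ variation + dimension,
                          data = records, FUN = stats::sd)
  names(sds)[3:4] <- c("accuracy_sd", "f1_sd")
  summary <- merge(summary, sds, by = c("variation", "dimension"))
  tests <- lapply(dimensions, function(dim) {
    a <- records[records$variation == 3L & records$dimension == dim, ]
    b <- records[records$variation == 1L & records$dimension == dim, ]
    a <- a[order(a$seed), ]; b <- b[order(b$seed), ]
    if (nrow(a) >= 2L) paired_ttest(a$accuracy, b$accuracy) else NULL
  })
  names(tests) <- dimensions
  structure(list(records = records, summary = summary, tests = tests),
            class = "emokd_ablation")
}

#' @export
print.emokd_ablation <- function(x, ...) {
  s <- x$summary
  cat("Ablation summary (test partition, mean over seeds):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  V%d %-8s accuracy %5.1f%% +/- %4.1f  F1 %5.1f%% +/- %4.1f\n",
                s$variation[i], s$dimension[i],
                100 * s$accuracy[i], 100 * s$accuracy_sd[i],
                100 * s$f1[i], 100 * s$f1_sd[i]))
  }
  invisible(x)
}

# segment-level split that ignores trial boundaries but matches the
# partition sizes of a reference trial-wise assignment
shuffle_segments_split <- function(segments, sizes, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ord <- sample.int(length(segments))
  roles <- rep(c("train", "val", "test"), times = sizes)
  for (i in seq_along(segments)) segments[[ord[i]]]$partition <- roles[i]
  segments
}

#' Leakage demonstration: trial-wise vs segment-shuffled splitting
#'
#' Trains the same multimodal model twice on the same cohort: once under
#' the leakage-safe trial-wise split and once with segments shuffled across
#' trials into partitions of identical sizes. When segments within a trial
#' are correlated (shared latent, per-trial gains), the shuffled regime
#' lets the model exploit trial fingerprints and its test accuracy is
#' inflated; the gap is the leakage inflation.
#'
#' @param cohort An `emokd_cohort`.
#' @param cfg Experiment configuration ([benchmark_config()]).
#' @param seed Integer seed (split, initialization, batch order).
#' @param dimension Label dimension (default `"valence"`).
#' @return List of class `emokd_leakage`: `trial_wise` and `shuffled`
#'   run results, and `gap` = shuffled minus trial-wise test accuracy.
#' @export
leakage_experiment <- function(cohort, cfg = benchmark_config(), seed = 1L,
                               dimension = "valence") {
  parts <- prepare_partitions(cohort, split_seed = seed,
                              window_seconds = cfg$window_seconds)
  sizes <- c(length(parts$train), length(parts$val), length(parts$test))
  all_segs <- c(parts$train, parts$val, parts$test)
  shuffled <- shuffle_segments_split(all_segs, sizes, seed = seed + 1L)
  sh <- list(train = Filter(function(s) s$partition == "train", shuffled),
             val = Filter(function(s) s$partition == "val", shuffled),
             test = Filter(function(s) s$partition == "test", shuffled))
  stopifnot(length(sh$train) == sizes[1L], length(sh$test) == sizes[3L])

  seeds <- derive_seeds(seed, 2L)
  m1 <- pretrain_teacher(parts$train, parts$val, cfg$teacher_cfg, dimension,
                         epochs = cfg$leakage_epochs,
                         batch_size = cfg$batch_size,
                         lr = cfg$teacher_lr %||% cfg$lr,
                         seed = seeds[1L])
  r1 <- evaluate_model(m1, parts$test, dimension)
  m2 <- pretrain_teacher(sh$train, sh$val, cfg$teacher_cfg, dimension,
                         epochs = cfg$leakage_epochs,
                         batch_size = cfg$batch_size,
                         lr = cfg$teacher_lr %||% cfg$lr,
                         seed = seeds[1L])
  r2 <- evaluate_model(m2, sh$test, dimension)
  structure(list(trial_wise = r1, shuffled = r2,
                 gap = r2$accuracy - r1$accuracy,
                 n_segments = length(all_segs), dimension = dimension,
                 seed = as.integer(seed)),
            class = "emokd_leakage")
}

#' @export
print.emokd_leakage <- function(x, ...) {
  cat(sprintf(
    "<leakage demo (%s): trial-wise %.1f%%, segment-shuffled %.1f%%, inflation %+.1f points>\n",
    x$dimension, 100 * x$trial_wise$accuracy, 100 * x$shuffled$accuracy,
    100 * x$gap))
  invisible(x)
}
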