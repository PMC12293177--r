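# Teacher model: frontend arithmetic and linearity, attention oracles,
# encoder structure, forward-pass invariants, gradient correctness, and
# training sanity on signal-free data.

test_that("conv_frontend obeys the stride arithmetic and channel checks", {
  m <- init_teacher(toy_teacher_cfg(), seed = 1L)
  x <- matrix(rnorm(3 * 16), 3, 16)
  feat <- conv_frontend(x, m, "eeg")
  expect_identical(dim(feat), c(3L, 8L)) # T = (16-8)/4+1, d = 8
  expect_error(conv_frontend(matrix(0, 5, 16), m, "eeg"), "expects 3 channels")
  expect_error(conv_frontend(matrix(0, 3, 4), m, "eeg"), "shorter")
  # zero input gives zero pre-activation output under the zero-bias init
  z <- conv_frontend(matrix(0, 3, 16), m, "eeg", pre_activation = TRUE)
  expect_equal(z, matrix(0, 3, 8))
  # pre-activation output is linear in the input
  a <- conv_frontend(x, m, "eeg", pre_activation = TRUE)
  b <- conv_frontend(2 * x, m, "eeg", pre_activation = TRUE)
  expect_lt(max(abs(b - 2 * a)), 1e-10)
})

test_that("scaled_dot_attention matches a brute-force double loop", {
  set.seed(9)
  q <- matrix(rnorm(8), 4, 2); k <- matrix(rnorm(8), 4, 2)
  v <- matrix(rnorm(12), 4, 3)
  out <- scaled_dot_attention(q, k, v)
  # independent double-loop evaluation
  ref <- matrix(0, 4, 3)
  for (i in 1:4) {
    s <- numeric(4)
    for (j in 1:4) s[j] <- sum(q[i, ] * k[j, ]) / sqrt(2)
    w <- exp(s) / sum(exp(s))
    for (j in 1:4) ref[i, ] <- ref[i, ] + w[j] * v[j, ]
  }
  expect_lt(max(abs(out - ref)), 1e-6)
  expect_equal(rowSums(attr(out, "attention")), rep(1, 4))
  # single position: softmax of a scalar is 1, so the output is v
  expect_equal(as.vector(scaled_dot_attention(matrix(1, 1, 2),
                                              matrix(2, 1, 2),
                                              matrix(c(3, 4), 1))),
               c(3, 4))
  # zero queries: uniform attention, output = column means of v
  u <- scaled_dot_attention(matrix(0, 4, 2), k, v)
  expect_equal(u[1, ], colMeans(v))
  expect_error(scaled_dot_attention(q, k[1:2, ], v), "sequence length")
})

test_that("encode_stream returns one output per layer and is permutation
           equivariant without position encodings", {
  m <- init_teacher(toy_teacher_cfg(), seed = 2L)
  seq <- matrix(rnorm(5 * 8), 5, 8)
  outs <- encode_stream(seq, m, "eeg")
  expect_length(outs, 2L)
  expect_identical(dim(outs[[2]]), c(5L, 8L))
  perm <- c(3, 1, 5, 2, 4)
  outs_p <- encode_stream(seq[perm, ], m, "eeg")
  for (l in 1:2) expect_lt(max(abs(outs_p[[l]] - outs[[l]][perm, ])), 1e-10)
})

test_that("a single-head encoder layer reduces to one scaled-dot attention", {
  cfg <- toy_teacher_cfg()
  cfg$n_heads <- 1L
  m <- init_teacher(cfg, seed = 3L)
  seq <- matrix(rnorm(4 * 8), 4, 8)
  outs <- encode_stream(seq, m, "eeg")
  att <- attr(outs, "attention")[[1]][[1]]
  p <- m$params
  ref <- scaled_dot_attention(seq %*% p[["eeg.l1.Wq"]],
                              seq %*% p[["eeg.l1.Wk"]],
                              seq %*% p[["eeg.l1.Wv"]])
  expect_lt(max(abs(att - attr(ref, "attention"))), 1e-10)
})

test_that("teacher_forward yields normalized probabilities, is deterministic,
           and demands both modalities", {
  m <- init_teacher(toy_teacher_cfg(), seed = 4L)
  segs <- toy_segments(3, seed = 21L)
  out <- teacher_forward(m, segs)
  expect_identical(dim(out$probabilities), c(3L, 2L))
  expect_equal(rowSums(out$probabilities), rep(1, 3), tolerance = 1e-6)
  expect_identical(out$logits, teacher_forward(m, segs)$logits)
  expect_identical(dim(out$fused), c(3L, 16L))
  expect_identical(dim(out$taps$x1_eeg), c(3L, 8L))
  s_bad <- segs[[1]]
  s_bad$eog_block <- NULL
  expect_error(teacher_forward(m, list(s_bad)), "multimodal")
  # attention rows are probability vectors at every layer and head
  for (stream in out$attention) {
    for (layer in stream) {
      for (head in layer) {
        expect_equal(apply(head, 3, rowSums),
                     matrix(1, nrow(head), dim(head)[3]), tolerance = 1e-6)
      }
    }
  }
})

test_that("the teacher forward-backward gradient matches finite differences", {
  m <- init_teacher(toy_teacher_cfg(), seed = 5L)
  segs <- toy_segments(4, seed = 31L)
  cfg <- m$cfg
  loss_of <- function(params) {
    mm <- m; mm$params <- params
    probs <- emokd:::model_probs(mm, segs)
    y <- emokd:::one_hot(vapply(segs, function(s) s$labels$valence, integer(1)))
    loss_ce(y, probs)
  }
  batch <- emokd:::make_batch(segs, cfg, "valence")
  tp <- emokd:::ad_tape()
  pn <- emokd:::params_to_nodes(tp, m$params, track = TRUE)
  fw <- emokd:::teacher_forward_nodes(tp, pn, batch, cfg)
  emokd:::ad_backward(tp, emokd:::ce_node(tp, fw$probs, batch$y))
  grads <- emokd:::grads_of(pn)
  set.seed(77)
  coords <- do.call(rbind, lapply(sample(names(grads), 16), function(nm) {
    data.frame(param = nm, index = sample(length(grads[[nm]]), 2),
               stringsAsFactors = FALSE)
  }))
  coords$g <- vapply(seq_len(nrow(coords)), function(r) {
    grads[[coords$param[r]]][coords$index[r]]
  }, numeric(1))
  ng <- num_grad_params(loss_of, m$params, coords)
  expect_lt(rel_err(coords$g, ng), 1e-4)
})

test_that("pretraining on a signal-free cohort stays at chance", {
  null_spec <- function(seed) cohort_spec(
    n_subjects = 3L, n_trials_per_subject = 10L, trial_seconds = 8,
    baseline_seconds = 0, fs = 64, n_eeg_channels = 8L, eeg_snr = 0,
    eog_snr = 0, shared_latent_weight = 0, trial_sd = 0, seed = seed)
  co <- cached("null_micro_cohort", generate_cohort(null_spec(99L)))
  split <- split_by_trial_per_subject(co$recordings, seed = 1L)
  segs <- segment_recordings(co$recordings, split = split)
  train <- Filter(function(s) identical(s$partition, "train"), segs)
  rest <- Filter(function(s) !identical(s$partition, "train"), segs)
  m <- pretrain_teacher(train, rest, micro_teacher_cfg(), "valence",
                        epochs = 3L, batch_size = 16L, seed = 2L)
  # evaluate on a fresh signal-free cohort: expected accuracy is 0.5
  eval_co <- cached("null_micro_cohort_eval", generate_cohort(null_spec(100L)))
  eval_segs <- segment_recordings(eval_co$recordings)
  res <- evaluate_model(m, eval_segs, "valence")
  expect_gt(res$accuracy, 0.35)
  expect_lt(res$accuracy, 0.65)
})

test_that("teacher checkpointing resumes exactly and reload reproduces the
           validation loss", {
  parts <- micro_partitions()
  ck <- withr::local_tempfile(fileext = ".rds")
  full <- pretrain_teacher(parts$train, parts$val, micro_teacher_cfg(),
                           "valence", epochs = 4L, batch_size = 16L,
                           seed = 3L)
  m2 <- pretrain_teacher(parts$train, parts$val, micro_teacher_cfg(),
                         "valence", epochs = 2L, batch_size = 16L, seed = 3L,
                         checkpoint_path = ck)
  resumed <- pretrain_teacher(parts$train, parts$val, micro_teacher_cfg(),
                              "valence", epochs = 4L, batch_size = 16L,
                              seed = 3L, checkpoint_path = ck)
  expect_equal(resumed$history, full$history, tolerance = 1e-6)
  expect_equal(resumed$params, full$params, tolerance = 1e-12)
  # a reloaded checkpoint reproduces the recorded validation loss
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(full, f)
  back <- readRDS(f)
  ev <- emokd:::internal_eval(back, parts$val, "valence", "val")
  expect_equal(ev$loss, full$history$val_loss[full$best_epoch],
               tolerance = 1e-6)
})
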