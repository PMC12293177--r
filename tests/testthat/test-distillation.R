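# The three losses (closed forms and oracles), the combined objective and
# its gradient, phase-purity contracts, the feedback step's analytic
# degeneracies, and the variation semantics of the full driver.

test_that("cross-entropy matches its closed forms and validates input", {
  expect_lt(loss_ce(c(1, 0), c(1 - 1e-9, 1e-9)), 1e-6)
  expect_equal(loss_ce(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(loss_ce(c(0, 1), c(0.9, 0.1)), -log(0.1), tolerance = 1e-9)
  expect_error(loss_ce(c(1, 0), c(0.7, 0.1)), "not normalized")
  # batch form averages rows
  y <- rbind(c(1, 0), c(0, 1))
  p <- rbind(c(0.5, 0.5), c(0.1, 0.9))
  expect_equal(loss_ce(y, p), mean(c(log(2), -log(0.9))))
})

test_that("feature MSE matches its closed forms and a component loop", {
  expect_equal(loss_mse(1:4, 1:4), 0)
  expect_equal(loss_mse(c(0, 0), c(2, 2)), 4)
  set.seed(11)
  a <- rnorm(10); b <- rnorm(10)
  loop <- 0
  for (i in 1:10) loop <- loop + (a[i] - b[i])^2
  expect_equal(loss_mse(a, b), loop / 10, tolerance = 1e-12)
  expect_error(loss_mse(1:3, 1:4), "widths differ")
})

test_that("KL divergence uses the teacher as reference and is non-negative", {
  expect_equal(loss_kl(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(loss_kl(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-9)
  expect_equal(loss_kl(c(0.75, 0.25), c(0.5, 0.5)), 0.1308, tolerance = 1e-4)
  set.seed(12)
  for (i in 1:20) {
    p <- runif(3); p <- p / sum(p)
    q <- runif(3); q <- q / sum(q)
    expect_gte(loss_kl(p, q), 0)
  }
  # never infinite against a zero student probability
  expect_true(is.finite(loss_kl(c(0.5, 0.5), c(1, 0))))
  # temperature re-softens both distributions and rescales by T^2
  p4 <- c(0.9, 0.1)^(1 / 4); p4 <- p4 / sum(p4)
  expect_equal(loss_kl(c(0.9, 0.1), c(0.5, 0.5), temperature = 4),
               16 * loss_kl(p4, c(0.5, 0.5)), tolerance = 1e-9)
  expect_error(loss_kl(c(0.5, 0.5), c(0.5, 0.5), temperature = 0), "positive")
})

toy_pair <- function(seed = 1L) {
  list(teacher = init_teacher(toy_teacher_cfg(), seed = seed),
       student = init_student(toy_student_cfg(), seed = seed + 1L))
}

test_that("total_student_loss degenerates to plain CE and carries exact
           gradients", {
  p <- toy_pair(20L)
  segs <- toy_segments(4, seed = 40L)
  w_ce <- loss_weights(1, 0, 0)
  out <- total_student_loss(segs, "valence", p$teacher, p$student, w_ce)
  probs <- student_forward(p$student, segs)$probabilities
  y <- emokd:::one_hot(vapply(segs, function(s) s$labels$valence, integer(1)))
  expect_equal(out$loss, loss_ce(y, probs), tolerance = 1e-12)
  expect_equal(out$kl, 0)
  expect_equal(out$mse, 0)

  # full objective: analytic gradient vs central differences
  w <- loss_weights()
  full <- total_student_loss(segs, "valence", p$teacher, p$student, w)
  expect_true(all(vapply(full[c("loss", "ce", "kl", "mse")], is.finite, TRUE)))
  f <- function(params) {
    ss <- p$student; ss$params <- params
    total_student_loss(segs, "valence", p$teacher, ss, w)$loss
  }
  coords <- top_coords(full$grads, 20L)
  ng <- num_grad_params(f, p$student$params, coords)
  expect_lt(rel_err(coords$g, ng), 1e-4)
})

test_that("the teaching phase updates only the student", {
  p <- toy_pair(30L)
  st <- distill_state(p$teacher, p$student, "valence")
  fp_t <- param_fingerprint(st$teacher$params)
  fp_s <- param_fingerprint(st$student$params)
  batches <- list(toy_segments(4, seed = 50L), toy_segments(4, seed = 51L))
  st0 <- teach_phase(st, batches, steps = 0L)
  expect_identical(param_fingerprint(st0$student$params), fp_s)
  st2 <- teach_phase(st, batches, steps = 6L)
  expect_identical(param_fingerprint(st2$teacher$params), fp_t)
  expect_false(identical(param_fingerprint(st2$student$params), fp_s))
})

test_that("the feedback phase freezes the student and degenerates to the
           teacher CE gradient at alpha = 0", {
  p <- toy_pair(31L)
  tr <- toy_segments(4, seed = 60L)
  va <- toy_segments(4, seed = 61L)
  sch0 <- feedback_schedule(inner_lr = 0)
  fg <- feedback_outer_gradient(p$teacher, p$student, tr, va, "valence",
                                schedule = sch0)
  # direct teacher CE gradient on the validation batch
  batch <- emokd:::make_batch(va, p$teacher$cfg, "valence")
  tp <- emokd:::ad_tape()
  pn <- emokd:::params_to_nodes(tp, p$teacher$params, track = TRUE)
  fw <- emokd:::teacher_forward_nodes(tp, pn, batch, p$teacher$cfg)
  emokd:::ad_backward(tp, emokd:::ce_node(tp, fw$probs, batch$y))
  ref <- emokd:::grads_of(pn)
  for (nm in names(ref)) expect_equal(fg$grads[[nm]], ref[[nm]])
  expect_identical(fg$theta_ts, p$student$params)

  st <- distill_state(p$teacher, p$student, "valence",
                      schedule = feedback_schedule(inner_lr = 1e-2))
  fp_s <- param_fingerprint(st$student$params)
  fp_t <- param_fingerprint(st$teacher$params)
  st2 <- feedback_phase(st, tr, va)
  expect_identical(param_fingerprint(st2$student$params), fp_s)
  expect_false(identical(param_fingerprint(st2$teacher$params), fp_t))
  # the temporary student was created by copying and stepping theta_s
  expect_identical(names(st2$theta_ts), names(p$student$params))
  expect_error(feedback_schedule(inner_lr = -1), "alpha")
})

test_that("the second-order outer gradient matches finite differences
           through the full two-step computation", {
  p <- toy_pair(32L)
  tr <- toy_segments(4, seed = 70L)
  va <- toy_segments(4, seed = 71L)
  w <- loss_weights()
  sch <- feedback_schedule(inner_lr = 0.05, mode = "second-order")
  fg <- feedback_outer_gradient(p$teacher, p$student, tr, va, "valence", w, sch)
  outer_value <- function(tparams) {
    tt <- p$teacher; tt$params <- tparams
    g <- total_student_loss(tr, "valence", tt, p$student, w)$grads
    theta_ts <- mapply(function(pp, gg) pp - sch$inner_lr * gg,
                       p$student$params, g, SIMPLIFY = FALSE)
    ss <- p$student; ss$params <- theta_ts
    probs_s <- student_forward(ss, va)$probabilities
    probs_t <- teacher_forward(tt, va)$probabilities
    y <- emokd:::one_hot(vapply(va, function(s) s$labels$valence, integer(1)))
    loss_ce(y, probs_s) + w$lambda_t * loss_ce(y, probs_t)
  }
  coords <- top_coords(fg$grads, 15L)
  ng <- num_grad_params(outer_value, p$teacher$params, coords, eps = 1e-4)
  expect_lt(rel_err(coords$g, ng), 1e-3)
})

test_that("run_distillation honours the variation semantics and is
           deterministic", {
  parts <- micro_partitions()
  teacher <- cached("micro_teacher", pretrain_teacher(
    parts$train, parts$val, micro_teacher_cfg(), "valence",
    epochs = 2L, batch_size = 16L, seed = 4L))
  sch <- feedback_schedule(warmup_epochs = 1L)
  runs <- lapply(1:3, function(v) {
    run_distillation(parts$train, parts$val, "valence", teacher,
                     micro_student_cfg(), variation = v, schedule = sch,
                     epochs = 3L, batch_size = 16L, seed = 6L)
  })
  # static variations leave the teacher untouched; V3 adapts it
  expect_identical(runs[[1]]$teacher_fingerprints[["before"]],
                   runs[[1]]$teacher_fingerprints[["after"]])
  expect_identical(runs[[2]]$teacher_fingerprints[["before"]],
                   runs[[2]]$teacher_fingerprints[["after"]])
  expect_false(identical(runs[[3]]$teacher_fingerprints[["before"]],
                         runs[[3]]$teacher_fingerprints[["after"]]))
  # V3 with no feedback cycles is V2
  sch_never <- feedback_schedule(warmup_epochs = 99L)
  v3_never <- run_distillation(parts$train, parts$val, "valence", teacher,
                               micro_student_cfg(), variation = 3L,
                               schedule = sch_never, epochs = 3L,
                               batch_size = 16L, seed = 6L)
  expect_equal(v3_never$history, runs[[2]]$history)
  expect_identical(param_fingerprint(v3_never$student$params),
                   param_fingerprint(runs[[2]]$student$params))
  # identical seed and configuration reproduce the history exactly
  again <- run_distillation(parts$train, parts$val, "valence", teacher,
                            micro_student_cfg(), variation = 2L,
                            schedule = sch, epochs = 3L, batch_size = 16L,
                            seed = 6L)
  expect_identical(again$history, runs[[2]]$history)
  expect_error(run_distillation(parts$train, parts$val, "valence", teacher,
                                micro_student_cfg(), variation = 4L),
               "variation")
})
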