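# The three-term distillation objective, the teaching phase, the dynamic
# feedback phase (a bilevel step in which a temporary student takes one
# inner gradient step and the teacher is updated through it on validation
# data), and the driver covering the three ablation variations:
#   V1  logit-only static distillation (Hinton baseline; lambda3 = 0)
#   V2  full objective (CE + KL + feature MSE), static teacher
#   V3  full objective + dynamic feedback cycles

#' Loss weights for the distillation objective
#'
#' `L_S = lambda1 * CE + lambda2 * KL + lambda3 * MSE`; the feedback phase
#' weighs the teacher's own CE term by `lambda_t`. The defaults
#' (1, 1, 1, 1) reproduce the reference training setup. The temperature
#' re-softens both probability vectors before the KL term and scales it by
#' `T^2`; the default `T = 1` leaves outputs untouched.
#'
#' @param lambda1,lambda2,lambda3 Non-negative weights of the CE, KL and
#'   feature-MSE terms.
#' @param lambda_t Non-negative weight of the teacher CE term in the
#'   feedback objective.
#' @param temperature Positive softmax temperature.
#' @param normalize_features Compare RMS-normalized feature vectors in the
#'   MSE term (default `TRUE`), so the published 1:1:1 weight ratio stays
#'   meaningful regardless of feature scale.
#' @param align_mode Which teacher features the student's features are
#'   matched against: `"fused"` (default) aligns the projected HDF output
#'   with the teacher's fused interaction feature (widths and roles
#'   correspond at any scale); `"taps"` aligns the student's pooled
#'   layer-1/2 encoder outputs with the teacher's EOG-stream heterogeneous
#'   features layer-wise, the structural-alignment reading.
#' @return An object of class `emokd_loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1, lambda3 = 1,
                         lambda_t = 1, temperature = 1,
                         normalize_features = TRUE,
                         align_mode = c("fused", "taps")) {
  align_mode <- match.arg(align_mode)
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda_t = lambda_t, temperature = temperature,
            normalize_features = isTRUE(normalize_features),
            align_mode = align_mode)
  if (any(unlist(w[1:4]) < 0)) stop("loss weights must be non-negative")
  if (w$lambda1 + w$lambda2 + w$lambda3 <= 0) {
    stop("at least one of lambda1..lambda3 must be positive")
  }
  if (w$temperature <= 0) stop("temperature must be positive")
  structure(w, class = "emokd_loss_weights")
}

#' Feedback schedule
#'
#' Controls the alternation between the teaching phase and the feedback
#' phase: after each of the first `warmup_epochs` teaching epochs the
#' teacher is left untouched; afterwards every teaching epoch is followed by
#' `feedback_steps` feedback invocations. The inner step of each invocation
#' is one plain gradient-descent step of size `inner_lr` on a training
#' batch; the outer step descends the feedback objective on a validation
#' batch with Adam at `outer_lr`.
#'
#' @param feedback_steps Feedback invocations per cycle (>= 1).
#' @param warmup_epochs Teaching epochs before the first feedback.
#' @param inner_lr Inner (temporary-student) learning rate `alpha` (>= 0).
#' @param outer_lr Teacher update learning rate.
#' @param mode `"second-order"` (gradient flows through the inner step via a
#'   Hessian-vector product) or `"first-order"` (coupling term dropped).
#' @return An object of class `emokd_feedback_schedule`.
#' @export
feedback_schedule <- function(feedback_steps = 1L, warmup_epochs = 3L,
                              inner_lr = 1e-3, outer_lr = 1e-4,
                              mode = c("second-order", "first-order")) {
  mode <- match.arg(mode)
  if (inner_lr < 0) stop("inner_lr (alpha) must be >= 0")
  if (feedback_steps < 1L) stop("feedback_steps must be >= 1")
  structure(list(feedback_steps = as.integer(feedback_steps),
                 warmup_epochs = as.integer(warmup_epochs),
                 inner_lr = inner_lr, outer_lr = outer_lr, mode = mode),
            class = "emokd_feedback_schedule")
}

# ---- closed-form losses (numeric API) -------------------------------------

#' Cross-entropy loss
#'
#' `-sum_k y_k log(yhat_k)` with the predicted probabilities clipped to
#' `[eps, 1]` before the logarithm. Vector inputs are treated as one
#' sample; matrices as one sample per row (mean loss returned).
#'
#' @param y One-hot labels (vector or matrix).
#' @param yhat Predicted probabilities, same shape; rows must sum to 1
#'   within 1e-3.
#' @param eps Clipping floor (default 1e-12).
#' @return Non-negative scalar.
#' @export
loss_ce <- function(y, yhat, eps = 1e-12) {
  y <- as_row_matrix(y); yhat <- as_row_matrix(yhat)
  if (!all(dim(y) == dim(yhat))) stop("y and yhat must share a shape")
  if (any(abs(rowSums(yhat) - 1) > 1e-3)) {
    stop("yhat rows are not normalized probability vectors")
  }
  mean(-rowSums(y * log(pmin(pmax(yhat, eps), 1))))
}

#' Mean squared error between feature vectors
#'
#' `(1/N) sum_n (f_n - f'_n)^2` over the N feature components; matrix
#' inputs average over rows as well (batch mean).
#'
#' @param fs,ft Equal-shape numeric vectors or matrices.
#' @return Non-negative scalar.
#' @export
loss_mse <- function(fs, ft) {
  fs <- as_row_matrix(fs); ft <- as_row_matrix(ft)
  if (!all(dim(fs) == dim(ft))) {
    stop(sprintf("feature widths differ: %dx%d vs %dx%d",
                 nrow(fs), ncol(fs), nrow(ft), ncol(ft)))
  }
  mean((fs - ft)^2)
}

#' Kullback-Leibler divergence from the teacher's soft output
#'
#' `sum_k y'_k log(y'_k / yhat_k)` with the teacher distribution `y'` as
#' the reference; always non-negative, zero iff the distributions agree.
#' With `temperature != 1` both distributions are re-softened
#' (`p^(1/T)`, renormalized — equivalent to dividing the logits by `T`) and
#' the result is scaled by `T^2`. Zero probabilities are handled by
#' clipping, never returning infinities.
#'
#' @param teacher_probs,student_probs Probability vectors (or matrices, one
#'   distribution per row; mean divergence returned).
#' @param temperature Positive temperature `T`.
#' @param eps Clipping floor.
#' @return Non-negative scalar.
#' @export
loss_kl <- function(teacher_probs, student_probs, temperature = 1,
                    eps = 1e-12) {
  p <- as_row_matrix(teacher_probs); q <- as_row_matrix(student_probs)
  if (!all(dim(p) == dim(q))) stop("probability vectors must share a shape")
  if (any(abs(rowSums(p) - 1) > 1e-3) || any(abs(rowSums(q) - 1) > 1e-3)) {
    stop("inputs must be normalized probability vectors")
  }
  if (temperature <= 0) stop("temperature must be positive")
  soften <- function(m, T) {
    m <- pmax(m, eps)^(1 / T)
    m / rowSums(m)
  }
  if (temperature != 1) {
    p <- soften(p, temperature)
    q <- soften(q, temperature)
  }
  p <- pmax(p, eps); q <- pmax(q, eps)
  kl <- mean(rowSums(p * (log(p) - log(q))))
  if (temperature != 1) kl * temperature^2 else kl
}

# ---- node-level loss builders ---------------------------------------------

# mean CE over a batch given a probs node and a one-hot constant
ce_node <- function(tp, probs, y_const, eps = 1e-12) {
  lp <- ad_log(ad_clip_min(probs, eps))
  ad_scale(ad_sum_all(ad_mul(ad_const(tp, y_const), lp)), -1 / nrow(y_const))
}

# mean KL(teacher || student) over a batch from the two logits nodes
kl_node <- function(tp, t_logits, s_logits, temperature = 1, eps = 1e-12) {
  B <- nrow(t_logits$val)
  tl <- if (temperature != 1) ad_scale(t_logits, 1 / temperature) else t_logits
  sl <- if (temperature != 1) ad_scale(s_logits, 1 / temperature) else s_logits
  pt <- ad_clip_min(ad_softmax_rows(tl), eps)
  ps <- ad_clip_min(ad_softmax_rows(sl), eps)
  kl <- ad_scale(ad_sum_all(ad_mul(pt, ad_sub(ad_log(pt), ad_log(ps)))), 1 / B)
  if (temperature != 1) ad_scale(kl, temperature^2) else kl
}

mse_node <- function(a, b) {
  d <- ad_sub(a, b)
  ad_mean_all(ad_mul(d, d))
}

# divide each row by its root-mean-square (plus eps for stability)
rms_normalize_node <- function(tp, x, eps = 1e-8) {
  d <- ncol(x$val)
  ones <- ad_const(tp, matrix(1 / d, d, 1L))
  r <- ad_sqrt(ad_add(ad_matmul(ad_mul(x, x), ones), ad_const(tp, matrix(eps, 1, 1))))
  ad_div(x, r)
}

# Build the full distillation loss L_S on one tape.
# teacher_pn / student_pn are parameter node lists (tracked or not as the
# caller requires); returns the scalar node plus the component nodes.
distill_loss_nodes <- function(tp, teacher_pn, teacher_cfg, student_pn,
                               student_cfg, batch, w, train_student = FALSE) {
  tf <- teacher_forward_nodes(tp, teacher_pn, batch, teacher_cfg, train = FALSE)
  sf <- student_forward_nodes(tp, student_pn, batch, student_cfg,
                              train = train_student)
  ce <- ce_node(tp, sf$probs, batch$y)
  total <- ad_scale(ce, w$lambda1)
  kl <- NULL; mse <- NULL
  if (w$lambda2 > 0) {
    kl <- kl_node(tp, tf$logits, sf$logits, w$temperature)
    total <- ad_add(total, ad_scale(kl, w$lambda2))
  }
  if (w$lambda3 > 0) {
    if (identical(w$align_mode, "taps")) {
      if (ncol(sf$taps$x1$val) != ncol(tf$taps$x1_eog$val)) {
        stop("tap alignment needs teacher and student d_model to agree")
      }
      pairs <- list(list(sf$taps$x1, tf$taps$x1_eog),
                    list(sf$taps$x2, tf$taps$x2_eog))
      acc <- NULL
      for (pr in pairs) {
        a <- pr[[1L]]; b <- pr[[2L]]
        if (isTRUE(w$normalize_features)) {
          a <- rms_normalize_node(tp, a)
          b <- rms_normalize_node(tp, b)
        }
        term <- mse_node(a, b)
        acc <- if (is.null(acc)) term else ad_add(acc, term)
      }
      mse <- ad_scale(acc, 1 / length(pairs))
    } else {
      ft <- tf$fused
      fs <- sf$align
      if (ncol(fs$val) != ncol(ft$val)) {
        stop(sprintf(
          "alignment width %d does not match the teacher fused width %d; configure align_width",
          ncol(fs$val), ncol(ft$val)))
      }
      if (isTRUE(w$normalize_features)) {
        ft <- rms_normalize_node(tp, ft)
        fs <- rms_normalize_node(tp, fs)
      }
      mse <- mse_node(fs, ft)
    }
    total <- ad_add(total, ad_scale(mse, w$lambda3))
  }
  list(total = total, ce = ce, kl = kl, mse = mse, teacher = tf, student = sf)
}

#' Distillation loss and its student gradient on a batch
#'
#' Evaluates `L_S = lambda1 CE + lambda2 KL + lambda3 MSE` (batch-averaged,
#' teacher in evaluation mode) and returns the analytic gradient with
#' respect to every student parameter.
#'
#' @param segments List of `emokd_segment`s (the batch).
#' @param dimension Label dimension (`"valence"` or `"arousal"`).
#' @param teacher An `emokd_teacher`.
#' @param student An `emokd_student`.
#' @param w A [loss_weights()].
#' @return List with `loss`, the components (`ce`, `kl`, `mse`), and
#'   `grads` (named list over student parameters).
#' @export
total_student_loss <- function(segments, dimension, teacher, student,
                               w = loss_weights()) {
  batch <- make_batch(segments, teacher$cfg, dimension, need = c("eeg", "eog"))
  tp <- ad_tape(grad = TRUE)
  tpn <- params_to_nodes(tp, teacher$params, track = FALSE)
  spn <- params_to_nodes(tp, student$params, track = TRUE)
  parts <- distill_loss_nodes(tp, tpn, teacher$cfg, spn, student$cfg, batch, w)
  if (!is.finite(parts$total$val[1L])) {
    stop("non-finite distillation loss on batch of ", length(segments),
         " segments (first: ",
         paste(unlist(segments[[1L]]$provenance), collapse = "/"), ")")
  }
  ad_backward(tp, parts$total)
  list(loss = parts$total$val[1L],
       ce = parts$ce$val[1L],
       kl = if (!is.null(parts$kl)) parts$kl$val[1L] else 0,
       mse = if (!is.null(parts$mse)) parts$mse$val[1L] else 0,
       grads = grads_of(spn))
}

# ---- phases ---------------------------------------------------------------

#' Create a distillation state
#'
#' Bundles the (pretrained) teacher, the student, their optimizer states and
#' the cycle position. The state's invariants are the phase-purity
#' contracts: [teach_phase()] never mutates teacher parameters and
#' [feedback_phase()] never mutates student parameters.
#'
#' @param teacher A pretrained `emokd_teacher`.
#' @param student An `emokd_student`.
#' @param dimension Label dimension being trained.
#' @param w A [loss_weights()].
#' @param schedule A [feedback_schedule()].
#' @param lr Student Adam learning rate.
#' @return An object of class `emokd_distill_state`.
#' @export
distill_state <- function(teacher, student, dimension, w = loss_weights(),
                          schedule = feedback_schedule(), lr = 1e-3) {
  structure(list(teacher = teacher, student = student,
                 theta_ts = NULL, dimension = dimension, w = w,
                 schedule = schedule,
                 opt_s = adam_init(student$params, lr = lr),
                 opt_t = adam_init(teacher$params, lr = schedule$outer_lr),
                 cycle = 0L, phase = "teach", history = list()),
            class = "emokd_distill_state")
}

#' Teaching phase: update the student on training batches
#'
#' Runs `steps` Adam steps on the distillation objective, one batch per
#' step. Teacher parameters are read-only throughout (bitwise identical
#' before and after).
#'
#' @param state An [distill_state()].
#' @param batches List of segment batches (each a list of segments); steps
#'   beyond `length(batches)` recycle.
#' @param steps Number of gradient steps (default: one per batch; 0 leaves
#'   the state unchanged).
#' @return The updated state.
#' @export
teach_phase <- function(state, batches, steps = length(batches)) {
  if (steps == 0L) return(state)
  w <- state$w
  tcfg <- state$teacher$cfg; scfg <- state$student$cfg
  losses <- numeric(steps)
  for (i in seq_len(steps)) {
    segs <- batches[[(i - 1L) %% length(batches) + 1L]]
    log_access("train", "teach_phase", length(segs))
    batch <- make_batch(segs, tcfg, state$dimension, need = c("eeg", "eog"))
    tp <- ad_tape(grad = TRUE)
    tpn <- params_to_nodes(tp, state$teacher$params, track = FALSE)
    spn <- params_to_nodes(tp, state$student$params, track = TRUE)
    parts <- distill_loss_nodes(tp, tpn, tcfg, spn, scfg, batch, w,
                                train_student = TRUE)
    if (!is.finite(parts$total$val[1L])) {
      stop("non-finite loss during teaching step ", i)
    }
    ad_backward(tp, parts$total)
    state$student$params <- adam_step(state$opt_s, state$student$params,
                                      grads_of(spn))
    losses[i] <- parts$total$val[1L]
  }
  state$phase <- "teach"
  state$last_teach_loss <- mean(losses)
  state
}

# gradient of L_S w.r.t. teacher parameters at given student parameters
grad_LS_wrt_teacher <- function(teacher, student_params, student_cfg, batch, w) {
  tp <- ad_tape(grad = TRUE)
  tpn <- params_to_nodes(tp, teacher$params, track = TRUE)
  spn <- params_to_nodes(tp, student_params, track = FALSE)
  parts <- distill_loss_nodes(tp, tpn, teacher$cfg, spn, student_cfg, batch, w)
  ad_backward(tp, parts$total)
  grads_of(tpn)
}

#' Outer gradient of the feedback objective with respect to the teacher
#'
#' Implements the bilevel feedback step's gradient: the temporary student
#' `theta_ts = theta_s - alpha * dL_S/dtheta_s` is formed on a training
#' batch; the outer objective on a validation batch is
#' `CE(y, f_s(x_V; theta_ts)) + lambda_t * CE(y, f_t(x_V; theta_t))`.
#' In `"second-order"` mode the first term's dependence on the teacher flows
#' through the inner step: its gradient is
#' `-alpha * (d^2 L_S / dtheta_t dtheta_s) . g_val`, computed as a
#' Hessian-vector product by symmetric differencing of the analytic teacher
#' gradient of `L_S` at `theta_s +/- r * g_val`. In `"first-order"` mode the
#' coupling term is dropped. With `alpha = 0` both modes reduce exactly to
#' `lambda_t * dCE(teacher)/dtheta_t`.
#'
#' @param teacher An `emokd_teacher`.
#' @param student An `emokd_student` (its parameters are `theta_s`).
#' @param train_segments,val_segments Segment batches for the inner and
#'   outer step.
#' @param dimension Label dimension.
#' @param w A [loss_weights()].
#' @param schedule A [feedback_schedule()] (supplies `alpha` and the mode).
#' @return List with `grads` (named list over teacher parameters),
#'   `theta_ts` (the temporary student parameters) and `val_ce` terms.
#' @export
feedback_outer_gradient <- function(teacher, student, train_segments,
                                    val_segments, dimension,
                                    w = loss_weights(),
                                    schedule = feedback_schedule()) {
  alpha <- schedule$inner_lr
  tcfg <- teacher$cfg; scfg <- student$cfg
  train_batch <- make_batch(train_segments, tcfg, dimension,
                            need = c("eeg", "eog"))
  val_batch <- make_batch(val_segments, tcfg, dimension, need = c("eeg", "eog"))

  # inner step on the training batch
  theta_ts <- student$params
  g_s <- NULL
  if (alpha > 0) {
    tp <- ad_tape(grad = TRUE)
    tpn <- params_to_nodes(tp, teacher$params, track = FALSE)
    spn <- params_to_nodes(tp, student$params, track = TRUE)
    parts <- distill_loss_nodes(tp, tpn, tcfg, spn, scfg, train_batch, w)
    ad_backward(tp, parts$total)
    g_s <- grads_of(spn)
    theta_ts <- mapply(function(p, g) p - alpha * g, student$params, g_s,
                       SIMPLIFY = FALSE)
  }

  # teacher's own CE on validation data
  tp <- ad_tape(grad = TRUE)
  tpn <- params_to_nodes(tp, teacher$params, track = TRUE)
  tf <- teacher_forward_nodes(tp, tpn, val_batch, tcfg)
  ce_t <- ce_node(tp, tf$probs, val_batch$y)
  ad_backward(tp, ce_t)
  grads <- lapply(grads_of(tpn), function(g) w$lambda_t * g)

  # validation CE of the temporary student and its gradient g_val
  tp <- ad_tape(grad = TRUE)
  spn <- params_to_nodes(tp, theta_ts, track = TRUE)
  sf <- student_forward_nodes(tp, spn, val_batch, scfg)
  ce_s <- ce_node(tp, sf$probs, val_batch$y)
  ad_backward(tp, ce_s)
  g_val <- grads_of(spn)

  if (alpha > 0 && schedule$mode == "second-order") {
    gnorm <- sqrt(sum(vapply(g_val, function(g) sum(g * g), numeric(1))))
    if (gnorm > 1e-12) {
      r <- 1e-4 / gnorm
      plus <- mapply(function(p, g) p + r * g, student$params, g_val,
                     SIMPLIFY = FALSE)
      minus <- mapply(function(p, g) p - r * g, student$params, g_val,
                      SIMPLIFY = FALSE)
      gt_plus <- grad_LS_wrt_teacher(teacher, plus, scfg, train_batch, w)
      gt_minus <- grad_LS_wrt_teacher(teacher, minus, scfg, train_batch, w)
      for (nm in names(grads)) {
        grads[[nm]] <- grads[[nm]] -
          alpha * (gt_plus[[nm]] - gt_minus[[nm]]) / (2 * r)
      }
    }
  }
  list(grads = grads, theta_ts = theta_ts,
       val_ce_student = ce_s$val[1L], val_ce_teacher = ce_t$val[1L])
}

#' Feedback phase: adapt the teacher through the temporary student
#'
#' Copies the student into a temporary student, takes the inner step on a
#' training batch, and updates the teacher by one Adam step on the outer
#' objective evaluated on a validation batch (see
#' [feedback_outer_gradient()]). Student parameters are bitwise unchanged.
#'
#' @param state An [distill_state()].
#' @param train_segments,val_segments Segment batches.
#' @return The updated state (new teacher parameters, `theta_ts` recorded).
#' @export
feedback_phase <- function(state, train_segments, val_segments) {
  log_access("train", "feedback_inner", length(train_segments))
  log_access("val", "feedback_outer", length(val_segments))
  fg <- feedback_outer_gradient(state$teacher, state$student, train_segments,
                                val_segments, state$dimension, state$w,
                                state$schedule)
  state$teacher$params <- adam_step(state$opt_t, state$teacher$params,
                                    fg$grads)
  state$theta_ts <- fg$theta_ts
  state$phase <- "feedback"
  state$cycle <- state$cycle + 1L
  state
}

# ---- full run -------------------------------------------------------------

#' Run the two-phase distillation
#'
#' Trains the student against a pretrained teacher for `epochs` passes over
#' the training partition. Variation 1 drops the feature-matching loss
#' (`lambda3 = 0`, classic logit distillation) and never runs feedback;
#' variation 2 uses the full objective with a static teacher; variation 3
#' adds feedback cycles per the schedule. The best student checkpoint by
#' validation accuracy is returned.
#'
#' @param train_segments,val_segments Segment lists from a trial-wise split.
#' @param dimension Label dimension (`"valence"` or `"arousal"`).
#' @param teacher A pretrained `emokd_teacher` (left untouched; variation 3
#'   adapts a copy).
#' @param student_cfg A [student_config()].
#' @param variation 1, 2 or 3.
#' @param w A [loss_weights()].
#' @param schedule A [feedback_schedule()].
#' @param epochs,batch_size,lr Training budget.
#' @param seed Integer seed controlling initialization, batch order and
#'   dropout.
#' @param checkpoint_path Optional RDS path written after every epoch; if it
#'   already exists the run resumes from it.
#' @return List with the best `student`, the `final_student`,
#'   `teacher_final`, a per-epoch `history` data frame, fingerprints of the
#'   teacher before/after, and the variation/seed.
#' @export
run_distillation <- function(train_segments, val_segments, dimension, teacher,
                             student_cfg, variation = 2L, w = loss_weights(),
                             schedule = feedback_schedule(), epochs = 10L,
                             batch_size = 64L, lr = 1e-3, seed = 1L,
                             checkpoint_path = NULL) {
  if (!variation %in% 1:3) stop("variation must be 1, 2 or 3")
  if (variation == 1L) w <- loss_weights(w$lambda1, w$lambda2, 0, w$lambda_t,
                                         w$temperature, w$normalize_features,
                                         w$align_mode)
  seeds <- derive_seeds(seed, 3L)
  teacher <- structure(list(cfg = teacher$cfg,
                            params = copy_params(teacher$params)),
                       class = "emokd_teacher")
  fp_teacher_before <- param_fingerprint(teacher$params)

  start_epoch <- 0L
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    ck <- readRDS(checkpoint_path)
    state <- ck$state
    best <- ck$best
    history <- ck$history
    start_epoch <- ck$epoch
    assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    student <- init_student(student_cfg, seed = seeds[1L])
    state <- distill_state(teacher, student, dimension, w, schedule, lr)
    best <- list(acc = -Inf, loss = Inf, params = NULL)
    history <- list()
    set.seed(seeds[2L])
  }

  n <- length(train_segments)
  for (ep in seq_len(epochs)) {
    if (ep <= start_epoch) next
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    batches <- lapply(starts, function(s) {
      train_segments[ord[s:min(s + batch_size - 1L, n)]]
    })
    state <- teach_phase(state, batches)
    if (variation == 3L && ep > schedule$warmup_epochs) {
      # feedback batches come from their own seeded stream so the teaching
      # trajectory of V3 matches V2 exactly until the teacher update itself
      # takes effect
      main_rng <- get(".Random.seed", envir = globalenv())
      set.seed((seeds[3L] + ep) %% 2147483647L)
      for (k in seq_len(schedule$feedback_steps)) {
        tb <- sample.int(length(batches), 1L)
        vidx <- sample.int(length(val_segments),
                           min(batch_size, length(val_segments)))
        state <- feedback_phase(state, batches[[tb]], val_segments[vidx])
      }
      assign(".Random.seed", main_rng, envir = globalenv())
    }
    ev <- internal_eval(state$student, val_segments, dimension, "val")
    history[[length(history) + 1L]] <-
      data.frame(epoch = ep, train_loss = state$last_teach_loss,
                 val_loss = ev$loss, val_acc = ev$acc)
    if (ev$acc > best$acc || (ev$acc == best$acc && ev$loss < best$loss)) {
      best <- list(acc = ev$acc, loss = ev$loss,
                   params = copy_params(state$student$params), epoch = ep)
    }
    if (!is.null(checkpoint_path)) {
      saveRDS(list(state = state, best = best, history = history, epoch = ep,
                   rng = get(".Random.seed", envir = globalenv())),
              checkpoint_path, version = 2)
    }
  }
  best_student <- structure(list(cfg = student_cfg, params = best$params,
                                 dimension = dimension),
                            class = "emokd_student")
  final_student <- state$student
  final_student$dimension <- dimension
  fp_after <- param_fingerprint(state$teacher$params)
  list(student = best_student, final_student = final_student,
       teacher_final = state$teacher,
       history = do.call(rbind, history),
       variation = as.integer(variation), seed = as.integer(seed),
       dimension = dimension,
       teacher_fingerprints = c(before = fp_teacher_before, after = fp_after),
       best_epoch = best$epoch)
}

# evaluation-mode loss/accuracy on a partition, with access logging
internal_eval <- function(model, segments, dimension, partition) {
  log_access(partition, "validation_eval", length(segments))
  probs <- model_probs(model, segments)
  labs <- vapply(segments, function(s) s$labels[[dimension]], integer(1))
  y <- one_hot(labs, ncol(probs))
  list(loss = loss_ce(y, probs),
       acc = mean(max.col(probs) - 1L == labs))
}
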