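# Supervised pretraining of the multimodal teacher (cross-entropy on the
# training partition, best checkpoint selected on validation accuracy).

#' Pretrain the multimodal teacher
#'
#' Minimizes cross-entropy with Adam over the training segments; the
#' returned model carries the best validation checkpoint and the per-epoch
#' training curve. Training aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param train_segments,val_segments Non-empty segment lists from a
#'   trial-wise split.
#' @param cfg A [teacher_config()].
#' @param dimension Label dimension to train on.
#' @param epochs,batch_size,lr Training budget.
#' @param seed Integer seed (initialization, batch order, dropout).
#' @param checkpoint_path Optional RDS path written each epoch; an existing
#'   file resumes the run (including its RNG stream).
#' @return An `emokd_teacher` with fields `history` (data frame),
#'   `dimension`, `best_epoch`.
#' @export
pretrain_teacher <- function(train_segments, val_segments,
                             cfg = teacher_config(), dimension = "valence",
                             epochs = 10L, batch_size = 64L, lr = 1e-3,
                             seed = 1L, checkpoint_path = NULL) {
  if (length(train_segments) == 0L || length(val_segments) == 0L) {
    stop("train and validation partitions must be non-empty")
  }
  seeds <- derive_seeds(seed, 2L)
  start_epoch <- 0L
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    ck <- readRDS(checkpoint_path)
    model <- ck$model
    opt <- ck$opt
    best <- ck$best
    history <- ck$history
    start_epoch <- ck$epoch
    assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    model <- init_teacher(cfg, seed = seeds[1L])
    opt <- adam_init(model$params, lr = lr)
    best <- list(acc = -Inf, loss = Inf, params = NULL, epoch = 0L)
    history <- list()
    set.seed(seeds[2L])
  }
  n <- length(train_segments)
  for (ep in seq_len(epochs)) {
    if (ep <= start_epoch) next
    ord <- sample.int(n)
    losses <- c()
    for (s in seq(1L, n, by = batch_size)) {
      segs <- train_segments[ord[s:min(s + batch_size - 1L, n)]]
      log_access("train", "pretrain_teacher", length(segs))
      batch <- make_batch(segs, cfg, dimension, need = c("eeg", "eog"))
      tp <- ad_tape(grad = TRUE)
      pn <- params_to_nodes(tp, model$params, track = TRUE)
      fw <- teacher_forward_nodes(tp, pn, batch, cfg, train = TRUE)
      loss <- ce_node(tp, fw$probs, batch$y)
      if (!is.finite(loss$val[1L])) {
        stop("teacher training diverged (non-finite loss) at epoch ", ep)
      }
      ad_backward(tp, loss)
      model$params <- adam_step(opt, model$params, grads_of(pn))
      losses <- c(losses, loss$val[1L])
    }
    ev <- internal_eval(model, val_segments, dimension, "val")
    history[[length(history) + 1L]] <-
      data.frame(epoch = ep, train_loss = mean(losses),
                 val_loss = ev$loss, val_acc = ev$acc)
    if (ev$acc > best$acc || (ev$acc == best$acc && ev$loss < best$loss)) {
      best <- list(acc = ev$acc, loss = ev$loss,
                   params = copy_params(model$params), epoch = ep)
    }
    if (!is.null(checkpoint_path)) {
      saveRDS(list(model = model, opt = opt, best = best, history = history,
                   epoch = ep, rng = get(".Random.seed", envir = globalenv())),
              checkpoint_path, version = 2)
    }
  }
  structure(list(cfg = cfg, params = best$params, dimension = dimension,
                 history = do.call(rbind, history), best_epoch = best$epoch,
                 final_params = model$params),
            class = "emokd_teacher")
}
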