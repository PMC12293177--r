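# Shared network machinery for the teacher and student models: convolutional
# frontends (temporal conv then spatial collapse), sinusoidal position
# encodings, multi-head transformer encoder layers, batched forward passes,
# and parameter initialization. All forward passes run on the autodiff tape;
# evaluation-mode passes use an untracked tape and are deterministic.

# memo cache for index matrices / position encodings
.cache_get <- function(key, build) {
  if (is.null(the$memo)) the$memo <- new.env(parent = emptyenv())
  v <- get0(key, envir = the$memo)
  if (is.null(v)) {
    v <- build()
    assign(key, v, envir = the$memo)
  }
  v
}

# im2col index for one ch x S signal: row (t-1)*ch + c, col k holds the
# linear index of X[c, (t-1)*stride + k]
im2col_idx <- function(ch, S, K, stride) {
  .cache_get(sprintf("P_%d_%d_%d_%d", ch, S, K, stride), function() {
    T <- (S - K) %/% stride + 1L
    t <- rep(seq_len(T), each = ch)
    c <- rep(seq_len(ch), T)
    # linear index of X[c, (t-1)*stride + k] in a ch x S matrix
    idx <- outer(((t - 1L) * stride) * ch + c - ch, (seq_len(K)) * ch, `+`)
    list(idx = idx, T = T)
  })
}

# gather index turning Y [(B*T*ch) x F1] into [(B*T) x (ch*F1)]
reshape_idx <- function(B, T, ch, F1) {
  .cache_get(sprintf("R_%d_%d_%d_%d", B, T, ch, F1), function() {
    b <- rep(seq_len(B), each = T)
    t <- rep(seq_len(T), B)
    row_off <- (b - 1L) * T * ch + (t - 1L) * ch
    c <- rep(seq_len(ch), each = F1)
    f <- rep(seq_len(F1), ch)
    col_off <- (f - 1L) * (B * T * ch) + c
    outer(row_off, col_off, `+`)
  })
}

# fixed sinusoidal position encoding, T x d
position_encoding <- function(T, d) {
  .cache_get(sprintf("PE_%d_%d", T, d), function() {
    pe <- matrix(0, T, d)
    pos <- seq_len(T) - 1L
    for (i in seq_len(ceiling(d / 2))) {
      w <- 1 / 10000^((2 * (i - 1)) / d)
      pe[, 2L * i - 1L] <- sin(pos * w)
      if (2L * i <= d) pe[, 2L * i] <- cos(pos * w)
    }
    pe
  })
}

# stack im2col matrices for a list of ch x S blocks; one gather over the
# column-bound signals
stack_frontend_input <- function(blocks, K, stride) {
  ch <- nrow(blocks[[1L]])
  S <- ncol(blocks[[1L]])
  B <- length(blocks)
  ix <- im2col_idx(ch, S, K, stride)
  X <- do.call(cbind, blocks)
  nr <- nrow(ix$idx)
  idx_all <- ix$idx[rep.int(seq_len(nr), B), , drop = FALSE] +
    rep(ch * S * (seq_len(B) - 1L), each = nr)
  P <- matrix(X[idx_all], nr * B, K)
  list(P = P, T = ix$T, B = B, ch = ch)
}

# ---- configurations -------------------------------------------------------

#' Teacher model configuration
#'
#' The multimodal teacher: one convolutional frontend and one transformer
#' encoder stream per modality, interaction fusion of the pooled layer taps,
#' and an affine softmax classifier on the fused feature.
#'
#' @param fs Sampling rate of the input segments (Hz).
#' @param n_eeg_channels,n_eog_channels Channel counts.
#' @param n_classes Number of classes (2: binary affect dimension).
#' @param d_model Encoder width; each pooled tap has this width, so the
#'   fused feature has width `2 * d_model`.
#' @param n_heads Attention heads (`d_model` must be divisible).
#' @param n_layers Encoder layers per stream (>= 2; layers 1 and 2 are
#'   tapped).
#' @param ff_width Feed-forward width inside each encoder layer.
#' @param conv_filters Temporal filter count of the frontend's first stage.
#' @param conv_kernel Temporal kernel length in samples (default `fs / 2`,
#'   half a second).
#' @param conv_stride Temporal stride in samples (default `fs / 4`).
#' @param dropout Dropout rate on the convolutional stages, in `[0, 1)`.
#' @param ie_hidden Hidden width of the interaction extractors (their input
#'   width is `2 * d_model`).
#' @param conv_activation Rectification after the second convolution stage:
#'   `"abs"` (default; exposes band amplitude), `"relu"`, or `"square"`.
#' @return An object of class `emokd_teacher_config`.
#' @export
teacher_config <- function(fs = 128, n_eeg_channels = 32L, n_eog_channels = 2L,
                           n_classes = 2L, d_model = 256L, n_heads = 4L,
                           n_layers = 2L, ff_width = 512L, conv_filters = 8L,
                           conv_kernel = NULL, conv_stride = NULL,
                           dropout = 0.25, ie_hidden = 1024L,
                           conv_activation = c("abs", "relu", "square")) {
  if (is.null(conv_kernel)) conv_kernel <- as.integer(fs / 2)
  if (is.null(conv_stride)) conv_stride <- as.integer(fs / 4)
  cfg <- list(fs = fs, n_eeg_channels = as.integer(n_eeg_channels),
              n_eog_channels = as.integer(n_eog_channels),
              n_classes = as.integer(n_classes), d_model = as.integer(d_model),
              n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
              ff_width = as.integer(ff_width),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              conv_stride = as.integer(conv_stride),
              dropout = dropout, ie_hidden = as.integer(ie_hidden),
              conv_activation = match.arg(conv_activation))
  if (cfg$d_model %% cfg$n_heads != 0L) {
    stop("d_model must be divisible by n_heads")
  }
  if (cfg$n_layers < 2L) {
    stop("the teacher needs at least 2 encoder layers (two taps per stream)")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(cfg, class = "emokd_teacher_config")
}

#' Student model configuration
#'
#' The EOG-only student: the same frontend/encoder skeleton as one teacher
#' stream, three tapped encoder layers, heterogeneous deep fusion, an
#' alignment projection to the teacher's fused width, and a classifier.
#'
#' @inheritParams teacher_config
#' @param n_layers Encoder layers (default 3; layers 1-3 are tapped).
#' @param he_hidden Hidden width of the heterogeneous extractors.
#' @param align_width Width of the alignment feature compared against the
#'   teacher's fused feature (default `2 * d_model`); `NULL` disables the
#'   projection so the alignment feature is the fused feature itself.
#' @return An object of class `emokd_student_config`.
#' @export
student_config <- function(fs = 128, n_eog_channels = 2L, n_classes = 2L,
                           d_model = 256L, n_heads = 4L, n_layers = 3L,
                           ff_width = 512L, conv_filters = 8L,
                           conv_kernel = NULL, conv_stride = NULL,
                           dropout = 0.25, he_hidden = 512L,
                           align_width = NULL,
                           conv_activation = c("abs", "relu", "square")) {
  if (is.null(conv_kernel)) conv_kernel <- as.integer(fs / 2)
  if (is.null(conv_stride)) conv_stride <- as.integer(fs / 4)
  if (is.null(align_width)) align_width <- 2L * as.integer(d_model)
  cfg <- list(fs = fs, n_eog_channels = as.integer(n_eog_channels),
              n_classes = as.integer(n_classes), d_model = as.integer(d_model),
              n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
              ff_width = as.integer(ff_width),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              conv_stride = as.integer(conv_stride),
              dropout = dropout, conv_activation = match.arg(conv_activation),
              he_hidden = as.integer(he_hidden),
              align_width = if (is.na(align_width)) NULL else as.integer(align_width))
  if (cfg$d_model %% cfg$n_heads != 0L) {
    stop("d_model must be divisible by n_heads")
  }
  if (cfg$n_layers < 3L) {
    stop("the student needs at least 3 encoder layers (three HDF taps)")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(cfg, class = "emokd_student_config")
}

# ---- parameter initialization ---------------------------------------------

init_frontend <- function(params, prefix, ch, cfg) {
  K <- cfg$conv_kernel; F1 <- cfg$conv_filters; d <- cfg$d_model
  params[[paste0(prefix, ".conv.Wt")]] <- glorot(K, F1)
  params[[paste0(prefix, ".conv.bt")]] <- zeros(1L, F1)
  params[[paste0(prefix, ".conv.Ws")]] <- glorot(ch * F1, d)
  params[[paste0(prefix, ".conv.bs")]] <- zeros(1L, d)
  params
}

init_encoder_layer <- function(params, prefix, cfg) {
  d <- cfg$d_model; ff <- cfg$ff_width
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    params[[paste0(prefix, ".", nm)]] <- glorot(d, d)
  }
  params[[paste0(prefix, ".bo")]] <- zeros(1L, d)
  params[[paste0(prefix, ".ln1g")]] <- matrix(1, 1L, d)
  params[[paste0(prefix, ".ln1b")]] <- zeros(1L, d)
  params[[paste0(prefix, ".Wf1")]] <- glorot(d, ff)
  params[[paste0(prefix, ".bf1")]] <- zeros(1L, ff)
  params[[paste0(prefix, ".Wf2")]] <- glorot(ff, d)
  params[[paste0(prefix, ".bf2")]] <- zeros(1L, d)
  params[[paste0(prefix, ".ln2g")]] <- matrix(1, 1L, d)
  params[[paste0(prefix, ".ln2b")]] <- zeros(1L, d)
  params
}

init_gate <- function(params, prefix, input_width, hidden_width) {
  g <- gated_extractor_params(input_width, hidden_width, init = "glorot")
  for (nm in names(g)) params[[paste0(prefix, ".", nm)]] <- g[[nm]]
  params
}

#' Initialize a teacher model
#'
#' @param cfg A [teacher_config()].
#' @param seed Integer seed for the parameter initialization.
#' @return An object of class `emokd_teacher`: list with `cfg` and `params`
#'   (flat named list of matrices).
#' @export
init_teacher <- function(cfg = teacher_config(), seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  p <- list()
  p <- init_frontend(p, "eeg", cfg$n_eeg_channels, cfg)
  p <- init_frontend(p, "eog", cfg$n_eog_channels, cfg)
  for (m in c("eeg", "eog")) {
    for (l in seq_len(cfg$n_layers)) {
      p <- init_encoder_layer(p, sprintf("%s.l%d", m, l), cfg)
    }
  }
  p <- init_gate(p, "ie1", 2L * cfg$d_model, cfg$ie_hidden)
  p <- init_gate(p, "ie2", 2L * cfg$d_model, cfg$ie_hidden)
  p[["head.W"]] <- glorot(2L * cfg$d_model, cfg$n_classes)
  p[["head.b"]] <- zeros(1L, cfg$n_classes)
  structure(list(cfg = cfg, params = p), class = "emokd_teacher")
}

#' Initialize a student model
#'
#' @param cfg A [student_config()].
#' @param seed Integer seed for the parameter initialization.
#' @return An object of class `emokd_student`.
#' @export
init_student <- function(cfg = student_config(), seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  p <- list()
  p <- init_frontend(p, "eog", cfg$n_eog_channels, cfg)
  for (l in seq_len(cfg$n_layers)) {
    p <- init_encoder_layer(p, sprintf("eog.l%d", l), cfg)
  }
  for (k in 1:3) {
    p <- init_gate(p, sprintf("he%d", k), cfg$d_model, cfg$he_hidden)
  }
  if (!is.null(cfg$align_width)) {
    p[["align.W"]] <- glorot(cfg$d_model, cfg$align_width)
    p[["align.b"]] <- zeros(1L, cfg$align_width)
  }
  p[["head.W"]] <- glorot(cfg$d_model, cfg$n_classes)
  p[["head.b"]] <- zeros(1L, cfg$n_classes)
  structure(list(cfg = cfg, params = p), class = "emokd_student")
}

#' Student baseline with identical architecture
#'
#' The ablation baseline shares the full student architecture; only the
#' losses applied during training differ. This is therefore an alias of
#' [init_student()] kept for clarity at call sites.
#'
#' @inheritParams init_student
#' @return An `emokd_student`.
#' @export
build_student_baseline <- function(cfg = student_config(), seed = 1L) {
  init_student(cfg, seed)
}

# ---- node-level forward passes --------------------------------------------

# frontend: stacked matmul form of temporal conv + spatial collapse.
# P is the stacked im2col constant; returns (B*T) x d sequence node
# (ReLU applied; position encoding NOT included).
frontend_nodes <- function(tp, pn, prefix, P, B, T, ch, cfg, train) {
  F1 <- cfg$conv_filters
  g <- function(nm) pn[[paste0(prefix, ".conv.", nm)]]
  Y <- ad_add(ad_matmul(P, g("Wt")), g("bt"))
  ix <- reshape_idx(B, T, ch, F1)
  Zin <- ad_gather(Y, ix, B * T, ch * F1, permutation = TRUE)
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    m <- matrix((stats::runif(B * T * ch * F1) < keep) / keep, B * T, ch * F1)
    Zin <- ad_mul(Zin, ad_const(tp, m))
  }
  Zp <- ad_add(ad_matmul(Zin, g("Ws")), g("bs"))
  Z <- switch(cfg$conv_activation %||% "relu",
              relu = ad_relu(Zp),
              square = ad_mul(Zp, Zp),
              abs = ad_relu_abs(Zp))
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    m <- matrix((stats::runif(B * T * cfg$d_model) < keep) / keep,
                B * T, cfg$d_model)
    Z <- ad_mul(Z, ad_const(tp, m))
  }
  Z
}

# pre-activation frontend output (no ReLU, no dropout), for linearity checks
frontend_preact_nodes <- function(tp, pn, prefix, P, B, T, ch, cfg) {
  F1 <- cfg$conv_filters
  g <- function(nm) pn[[paste0(prefix, ".conv.", nm)]]
  Y <- ad_add(ad_matmul(P, g("Wt")), g("bt"))
  ix <- reshape_idx(B, T, ch, F1)
  Zin <- ad_gather(Y, ix, B * T, ch * F1, permutation = TRUE)
  ad_add(ad_matmul(Zin, g("Ws")), g("bs"))
}

# one encoder layer; X is (B*T) x d; returns list(out, att)
encoder_layer_nodes <- function(tp, pn, prefix, X, B, T, cfg) {
  d <- cfg$d_model; h <- cfg$n_heads; dk <- d %/% h
  g <- function(nm) pn[[paste0(prefix, ".", nm)]]
  Q <- ad_matmul(X, g("Wq"))
  K <- ad_matmul(X, g("Wk"))
  V <- ad_matmul(X, g("Wv"))
  heads <- vector("list", h)
  atts <- vector("list", h)
  for (m in seq_len(h)) {
    cols <- (m - 1L) * dk + seq_len(dk)
    o <- ad_attention(ad_slice_cols(Q, cols), ad_slice_cols(K, cols),
                      ad_slice_cols(V, cols), B, T, 1 / sqrt(dk))
    heads[[m]] <- o
    atts[[m]] <- o$att
  }
  mh <- if (h == 1L) heads[[1L]] else ad_concat_cols(heads)
  A <- ad_add(ad_matmul(mh, g("Wo")), g("bo"))
  X1 <- ad_layernorm(ad_add(X, A), g("ln1g"), g("ln1b"))
  FF <- ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(X1, g("Wf1")), g("bf1"))),
                         g("Wf2")), g("bf2"))
  X2 <- ad_layernorm(ad_add(X1, FF), g("ln2g"), g("ln2b"))
  list(out = X2, att = atts)
}

# full stream: returns list(layers = list of (B*T) x d nodes, att)
encode_stream_nodes <- function(tp, pn, prefix, X, B, T, cfg, n_layers) {
  outs <- vector("list", n_layers)
  atts <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    r <- encoder_layer_nodes(tp, pn, sprintf("%s.l%d", prefix, l), X, B, T, cfg)
    outs[[l]] <- r$out
    atts[[l]] <- r$att
    X <- r$out
  }
  list(layers = outs, att = atts)
}

# teacher forward on a prepared batch; pn: parameter nodes; returns nodes
teacher_forward_nodes <- function(tp, pn, batch, cfg, train = FALSE) {
  d <- cfg$d_model
  Pe <- ad_const(tp, batch$eeg$P)
  Po <- ad_const(tp, batch$eog$P)
  B <- batch$eeg$B
  Te <- batch$eeg$T; To <- batch$eog$T
  Ze <- frontend_nodes(tp, pn, "eeg", Pe, B, Te, cfg$n_eeg_channels, cfg, train)
  Zo <- frontend_nodes(tp, pn, "eog", Po, B, To, cfg$n_eog_channels, cfg, train)
  Ze <- ad_add(Ze, ad_const(tp, position_encoding(Te, d)[rep(seq_len(Te), B), , drop = FALSE]))
  Zo <- ad_add(Zo, ad_const(tp, position_encoding(To, d)[rep(seq_len(To), B), , drop = FALSE]))
  se <- encode_stream_nodes(tp, pn, "eeg", Ze, B, Te, cfg, cfg$n_layers)
  so <- encode_stream_nodes(tp, pn, "eog", Zo, B, To, cfg, cfg$n_layers)
  x1_eeg <- ad_pool_rows(se$layers[[1L]], B, Te)
  x2_eeg <- ad_pool_rows(se$layers[[2L]], B, Te)
  x1_eog <- ad_pool_rows(so$layers[[1L]], B, To)
  x2_eog <- ad_pool_rows(so$layers[[2L]], B, To)
  gie <- function(which, x) {
    gated_extract_nodes(x, pn[[paste0(which, ".W1")]], pn[[paste0(which, ".b1")]],
                        pn[[paste0(which, ".W2")]], pn[[paste0(which, ".b2")]])
  }
  fused <- ad_add(gie("ie1", ad_concat_cols(list(x1_eog, x1_eeg))),
                  gie("ie2", ad_concat_cols(list(x2_eog, x2_eeg))))
  logits <- ad_add(ad_matmul(fused, pn[["head.W"]]), pn[["head.b"]])
  probs <- ad_softmax_rows(logits)
  list(logits = logits, probs = probs,
       taps = list(x1_eog = x1_eog, x2_eog = x2_eog,
                   x1_eeg = x1_eeg, x2_eeg = x2_eeg),
       fused = fused, att = list(eeg = se$att, eog = so$att))
}

# student forward on a prepared EOG batch
student_forward_nodes <- function(tp, pn, batch, cfg, train = FALSE) {
  d <- cfg$d_model
  Po <- ad_const(tp, batch$eog$P)
  B <- batch$eog$B; To <- batch$eog$T
  Z <- frontend_nodes(tp, pn, "eog", Po, B, To, cfg$n_eog_channels, cfg, train)
  Z <- ad_add(Z, ad_const(tp, position_encoding(To, d)[rep(seq_len(To), B), , drop = FALSE]))
  st <- encode_stream_nodes(tp, pn, "eog", Z, B, To, cfg, cfg$n_layers)
  taps <- lapply(1:3, function(k) ad_pool_rows(st$layers[[k]], B, To))
  ghe <- function(which, x) {
    gated_extract_nodes(x, pn[[paste0(which, ".W1")]], pn[[paste0(which, ".b1")]],
                        pn[[paste0(which, ".W2")]], pn[[paste0(which, ".b2")]])
  }
  fused <- ad_add(ad_add(ghe("he1", taps[[1L]]), ghe("he2", taps[[2L]])),
                  ghe("he3", taps[[3L]]))
  FS <- if (!is.null(pn[["align.W"]])) {
    ad_add(ad_matmul(fused, pn[["align.W"]]), pn[["align.b"]])
  } else fused
  logits <- ad_add(ad_matmul(fused, pn[["head.W"]]), pn[["head.b"]])
  probs <- ad_softmax_rows(logits)
  list(logits = logits, probs = probs,
       taps = list(x1 = taps[[1L]], x2 = taps[[2L]], x3 = taps[[3L]]),
       fused = fused, align = FS, att = st$att)
}

# ---- batch preparation ----------------------------------------------------

# Build the constant tensors for a list of segments. `need` selects
# modalities; labels for `dimension` become a one-hot matrix when present.
make_batch <- function(segments, cfg, dimension = NULL,
                       need = c("eeg", "eog")) {
  out <- list(n = length(segments))
  if ("eeg" %in% need) {
    out$eeg <- stack_frontend_input(lapply(segments, function(s) s$eeg_block),
                                    cfg$conv_kernel, cfg$conv_stride)
  }
  if ("eog" %in% need) {
    out$eog <- stack_frontend_input(lapply(segments, function(s) s$eog_block),
                                    cfg$conv_kernel, cfg$conv_stride)
  }
  if (!is.null(dimension)) {
    labs <- vapply(segments, function(s) s$labels[[dimension]], integer(1))
    out$y <- one_hot(labs, cfg$n_classes)
    out$labels <- labs
  }
  out
}

# ---- public wrappers ------------------------------------------------------

#' Scaled dot-product attention
#'
#' `softmax(q k^T / sqrt(d_k)) v` for a single sequence; each attention row
#' sums to 1. The attention matrix is attached as attribute `"attention"`.
#'
#' @param q,k,v Numeric matrices `[positions x width]` with matching
#'   position counts; `q` and `k` share a width.
#' @return Matrix `[positions x ncol(v)]` with attribute `"attention"`.
#' @export
scaled_dot_attention <- function(q, k, v) {
  q <- as.matrix(q); k <- as.matrix(k); v <- as.matrix(v)
  if (nrow(q) != nrow(k) || nrow(k) != nrow(v)) {
    stop("q, k, v must share the sequence length")
  }
  if (ncol(q) != ncol(k)) stop("q and k must share the width")
  tp <- ad_tape(grad = FALSE)
  o <- ad_attention(ad_const(tp, q), ad_const(tp, k), ad_const(tp, v),
                    1L, nrow(q), 1 / sqrt(ncol(k)))
  structure(o$val, attention = o$att[, , 1L])
}

#' Convolutional frontend of a model stream
#'
#' Applies the two stacked convolutions (temporal, then spatial collapse
#' across channels) of the given stream to one multichannel segment,
#' returning the `[time-steps x d_model]` feature sequence (evaluation mode;
#' position encodings are added later, by the encoder caller).
#'
#' @param x Numeric matrix `[channels x samples]`.
#' @param model An `emokd_teacher` or `emokd_student`.
#' @param stream `"eeg"` or `"eog"` (students only have `"eog"`).
#' @param pre_activation Return the pre-activation output of the second
#'   convolution (no rectifier)?
#' @return Matrix `[T x d_model]`.
#' @export
conv_frontend <- function(x, model, stream = c("eeg", "eog"),
                          pre_activation = FALSE) {
  stream <- match.arg(stream)
  cfg <- model$cfg
  x <- as.matrix(x)
  ch_expect <- if (stream == "eeg") cfg$n_eeg_channels else cfg$n_eog_channels
  if (inherits(model, "emokd_student") && stream == "eeg") {
    stop("the student has no EEG stream")
  }
  if (nrow(x) != ch_expect) {
    stop(sprintf("%s frontend expects %d channels, got %d",
                 stream, ch_expect, nrow(x)))
  }
  if (ncol(x) < cfg$conv_kernel) {
    stop("input shorter than the convolution kernel")
  }
  tp <- ad_tape(grad = FALSE)
  pn <- params_to_nodes(tp, model$params, track = FALSE)
  sb <- stack_frontend_input(list(x), cfg$conv_kernel, cfg$conv_stride)
  P <- ad_const(tp, sb$P)
  nd <- if (pre_activation) {
    frontend_preact_nodes(tp, pn, stream, P, 1L, sb$T, sb$ch, cfg)
  } else {
    frontend_nodes(tp, pn, stream, P, 1L, sb$T, sb$ch, cfg, train = FALSE)
  }
  nd$val
}

#' Run a sequence through a model's encoder stream
#'
#' Standard encoder layers (multi-head attention, residual + layer norm,
#' feed-forward); returns every layer's output so the pooled taps are
#' available. No position encoding is added here.
#'
#' @param seq Numeric matrix `[positions x d_model]`.
#' @param model An `emokd_teacher` or `emokd_student`.
#' @param stream `"eeg"` or `"eog"`.
#' @return List of per-layer output matrices, with attribute `"attention"`
#'   (per layer, per head).
#' @export
encode_stream <- function(seq, model, stream = c("eeg", "eog")) {
  stream <- match.arg(stream)
  if (inherits(model, "emokd_student") && stream == "eeg") {
    stop("the student has no EEG stream")
  }
  seq <- as.matrix(seq)
  cfg <- model$cfg
  if (ncol(seq) != cfg$d_model) {
    stop(sprintf("sequence width %d != d_model %d", ncol(seq), cfg$d_model))
  }
  tp <- ad_tape(grad = FALSE)
  pn <- params_to_nodes(tp, model$params, track = FALSE)
  st <- encode_stream_nodes(tp, pn, stream, ad_const(tp, seq), 1L, nrow(seq),
                            cfg, cfg$n_layers)
  structure(lapply(st$layers, function(n) n$val),
            attention = lapply(st$att, function(a) {
              lapply(a, function(h) h[, , 1L])
            }))
}

#' Teacher forward pass
#'
#' Runs one or more segments through the multimodal teacher in evaluation
#' mode. Both modalities are required.
#'
#' @param model An `emokd_teacher`.
#' @param segments A single `emokd_segment` or a list of them.
#' @return List with `logits` and `probabilities` (`[n x K]`), the four
#'   pooled `taps`, the `fused` interaction feature (`[n x 2 d_model]`), and
#'   per-layer `attention` maps.
#' @export
teacher_forward <- function(model, segments) {
  stopifnot(inherits(model, "emokd_teacher"))
  if (inherits(segments, "emokd_segment")) segments <- list(segments)
  for (s in segments) {
    if (is.null(s$eeg_block) || is.null(s$eog_block)) {
      stop("the teacher is strictly multimodal: every segment needs EEG and EOG")
    }
  }
  cfg <- model$cfg
  batch <- make_batch(segments, cfg, need = c("eeg", "eog"))
  tp <- ad_tape(grad = FALSE)
  pn <- params_to_nodes(tp, model$params, track = FALSE)
  fw <- teacher_forward_nodes(tp, pn, batch, cfg, train = FALSE)
  list(logits = fw$logits$val, probabilities = fw$probs$val,
       taps = lapply(fw$taps, function(n) n$val),
       fused = fw$fused$val, attention = fw$att)
}

#' Student forward pass
#'
#' Runs EOG blocks through the unimodal student in evaluation mode. Passing
#' EEG-shaped input is an error: unimodality is the point.
#'
#' @param model An `emokd_student`.
#' @param x A single `emokd_segment` (its EOG block is used), a list of
#'   segments, or an EOG matrix `[n_eog_channels x samples]`.
#' @return List with `logits`, `probabilities`, the three pooled `taps`, the
#'   `fused` HDF feature, and the `align` feature compared against the
#'   teacher's fused feature during distillation.
#' @export
student_forward <- function(model, x) {
  stopifnot(inherits(model, "emokd_student"))
  cfg <- model$cfg
  blocks <- if (inherits(x, "emokd_segment")) {
    list(x$eog_block)
  } else if (is.list(x)) {
    lapply(x, function(s) s$eog_block)
  } else {
    list(as.matrix(x))
  }
  for (b in blocks) {
    if (nrow(b) != cfg$n_eog_channels) {
      stop(sprintf(
        "student expects EOG with %d channels, got %d: it never reads EEG",
        cfg$n_eog_channels, nrow(b)))
    }
  }
  batch <- list(eog = stack_frontend_input(blocks, cfg$conv_kernel,
                                           cfg$conv_stride))
  tp <- ad_tape(grad = FALSE)
  pn <- params_to_nodes(tp, model$params, track = FALSE)
  fw <- student_forward_nodes(tp, pn, batch, cfg, train = FALSE)
  list(logits = fw$logits$val, probabilities = fw$probs$val,
       taps = lapply(fw$taps, function(n) n$val),
       fused = fw$fused$val, align = fw$align$val, attention = fw$att)
}

# batched evaluation-mode class probabilities for either model type
model_probs <- function(model, segments, batch_size = 256L) {
  teacher <- inherits(model, "emokd_teacher")
  need <- if (teacher) c("eeg", "eog") else "eog"
  n <- length(segments)
  out <- NULL
  for (i in seq(1L, n, by = batch_size)) {
    idx <- i:min(i + batch_size - 1L, n)
    batch <- make_batch(segments[idx], model$cfg, need = need)
    tp <- ad_tape(grad = FALSE)
    pn <- params_to_nodes(tp, model$params, track = FALSE)
    fw <- if (teacher) teacher_forward_nodes(tp, pn, batch, model$cfg)
    else student_forward_nodes(tp, pn, batch, model$cfg)
    out <- rbind(out, fw$probs$val)
  }
  out
}
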