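# The shared two-layer gating extractor and the two fusion modules built on
# it: the teacher's interaction fusion (IMF), which scores concatenated
# cross-modal features, and the student's heterogeneous deep fusion (HDF),
# which scores three encoder taps. A gating extractor computes
# score = sigmoid(FC2(relu(FC1(x)))) and returns score * x elementwise, so
# its second layer width must equal the input width.

#' Construct gated-extractor parameters
#'
#' Two affine layers with a rectifier after the first and a logistic after
#' the second. The output width of the second layer equals `input_width`, as
#' required by the elementwise product with the input.
#'
#' @param input_width Width of the feature vector being gated.
#' @param hidden_width Width of the first (hidden) layer.
#' @param init `"glorot"` (random, uses the current RNG state) or `"zero"`.
#' @return Named list `W1 [in x h1]`, `b1 [1 x h1]`, `W2 [h1 x in]`,
#'   `b2 [1 x in]`, with class `emokd_gated_extractor`.
#' @export
gated_extractor_params <- function(input_width, hidden_width,
                                   init = c("glorot", "zero")) {
  init <- match.arg(init)
  if (input_width < 1L || hidden_width < 1L) stop("widths must be positive")
  p <- if (init == "zero") {
    list(W1 = zeros(input_width, hidden_width), b1 = zeros(1L, hidden_width),
         W2 = zeros(hidden_width, input_width), b2 = zeros(1L, input_width))
  } else {
    list(W1 = glorot(input_width, hidden_width), b1 = zeros(1L, hidden_width),
         W2 = glorot(hidden_width, input_width), b2 = zeros(1L, input_width))
  }
  structure(p, class = "emokd_gated_extractor")
}

check_gate_width <- function(x, params, what = "gating extractor") {
  if (ncol(x) != nrow(params$W1)) {
    stop(sprintf("%s expects input width %d, got %d",
                 what, nrow(params$W1), ncol(x)))
  }
  invisible(NULL)
}

# node-level core shared by every caller; x and the four parameter entries
# are tape nodes
gate_scores_nodes <- function(x, W1, b1, W2, b2) {
  h <- ad_relu(ad_add(ad_matmul(x, W1), b1))
  ad_sigmoid(ad_add(ad_matmul(h, W2), b2))
}

gated_extract_nodes <- function(x, W1, b1, W2, b2) {
  ad_mul(gate_scores_nodes(x, W1, b1, W2, b2), x)
}

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Gating scores of a feature vector
#'
#' `sigmoid(FC2(relu(FC1(x))))`; every component lies strictly in (0, 1).
#'
#' @param x Numeric feature vector, or matrix with one feature vector per
#'   row.
#' @param params A [gated_extractor_params()].
#' @return Matrix of scores, same shape as `as_row_matrix(x)`.
#' @export
gate_scores <- function(x, params) {
  x <- as_row_matrix(x)
  check_gate_width(x, params)
  tp <- ad_tape(grad = FALSE)
  pn <- params_to_nodes(tp, params, track = FALSE)
  gate_scores_nodes(ad_const(tp, x), pn$W1, pn$b1, pn$W2, pn$b2)$val
}

#' Gated feature extraction
#'
#' Multiplies the input elementwise with its gating scores:
#' `out = gate_scores(x) * x`. With all-zero parameters the gate is exactly
#' 0.5, so `out = 0.5 * x`.
#'
#' @inheritParams gate_scores
#' @return Matrix of gated features, same shape as the input.
#' @export
gated_extract <- function(x, params) {
  x <- as_row_matrix(x)
  check_gate_width(x, params)
  if (ncol(params$W2) != ncol(x)) {
    stop(sprintf("gate output width %d does not match input width %d",
                 ncol(params$W2), ncol(x)))
  }
  tp <- ad_tape(grad = FALSE)
  pn <- params_to_nodes(tp, params, track = FALSE)
  gated_extract_nodes(ad_const(tp, x), pn$W1, pn$b1, pn$W2, pn$b2)$val
}

#' Interaction fusion (teacher side)
#'
#' Concatenates the layer-1 taps of the two modality streams and the layer-2
#' taps, passes each concatenation through its own interaction extractor,
#' and sums the gated results:
#' `IE1(concat(X1_EOG, X1_EEG)) + IE2(concat(X2_EOG, X2_EEG))`.
#'
#' @param inputs Named list with `x1_eog`, `x1_eeg`, `x2_eog`, `x2_eeg`,
#'   each a feature vector (or matrix of row vectors) of equal width.
#' @param ie1,ie2 [gated_extractor_params()] for twice the per-modality
#'   width.
#' @return Fused feature matrix of width `2 * per-modality width`.
#' @export
fuse_imf <- function(inputs, ie1, ie2) {
  x1o <- as_row_matrix(inputs$x1_eog); x1e <- as_row_matrix(inputs$x1_eeg)
  x2o <- as_row_matrix(inputs$x2_eog); x2e <- as_row_matrix(inputs$x2_eeg)
  w <- c(ncol(x1o), ncol(x1e), ncol(x2o), ncol(x2e))
  if (length(unique(w)) != 1L) {
    stop("all four fusion inputs must share one width, got ",
         paste(w, collapse = "/"))
  }
  c1 <- cbind(x1o, x1e); c2 <- cbind(x2o, x2e)
  check_gate_width(c1, ie1, "interaction extractor 1")
  check_gate_width(c2, ie2, "interaction extractor 2")
  tp <- ad_tape(grad = FALSE)
  p1 <- params_to_nodes(tp, ie1, track = FALSE)
  p2 <- params_to_nodes(tp, ie2, track = FALSE)
  ad_add(gated_extract_nodes(ad_const(tp, c1), p1$W1, p1$b1, p1$W2, p1$b2),
         gated_extract_nodes(ad_const(tp, c2), p2$W1, p2$b1, p2$W2, p2$b2))$val
}

#' Heterogeneous deep fusion (student side)
#'
#' Gates each of the three encoder taps with its own heterogeneous extractor
#' and sums: `HE1(X1) + HE2(X2) + HE3(X3)`.
#'
#' @param inputs Named list with `x1`, `x2`, `x3`, equal-width feature
#'   vectors (or matrices of row vectors).
#' @param he1,he2,he3 [gated_extractor_params()] for that width.
#' @return Fused feature matrix of the common input width.
#' @export
fuse_hdf <- function(inputs, he1, he2, he3) {
  xs <- lapply(inputs[c("x1", "x2", "x3")], as_row_matrix)
  w <- vapply(xs, ncol, 1L)
  if (length(unique(w)) != 1L) {
    stop("the three fusion inputs must share one width, got ",
         paste(w, collapse = "/"))
  }
  hes <- list(he1, he2, he3)
  tp <- ad_tape(grad = FALSE)
  acc <- NULL
  for (i in 1:3) {
    check_gate_width(xs[[i]], hes[[i]], sprintf("heterogeneous extractor %d", i))
    pn <- params_to_nodes(tp, hes[[i]], track = FALSE)
    term <- gated_extract_nodes(ad_const(tp, xs[[i]]), pn$W1, pn$b1, pn$W2, pn$b2)
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  acc$val
}
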