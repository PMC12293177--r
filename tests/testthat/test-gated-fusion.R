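# The gating extractor and the two fusion modules: closed-form degeneracies,
# independent re-evaluation oracles, boundedness, and differentiability.

straight_line_gate <- function(x, p) {
  h <- pmax(x %*% p$W1 + matrix(p$b1, nrow(x), ncol(p$b1), byrow = TRUE), 0)
  s <- 1 / (1 + exp(-(h %*% p$W2 + matrix(p$b2, nrow(x), ncol(p$b2), byrow = TRUE))))
  s
}

test_that("zero-parameter gates score exactly 0.5 and halve the input", {
  p <- gated_extractor_params(6L, 4L, init = "zero")
  x <- matrix(rnorm(12), 2, 6)
  expect_equal(gate_scores(x, p), matrix(0.5, 2, 6))
  expect_equal(gated_extract(x, p), 0.5 * x)
  expect_equal(gated_extract(matrix(0, 1, 6), p), matrix(0, 1, 6))
})

test_that("gate scores lie strictly in (0, 1) and match a straight-line
           re-evaluation", {
  set.seed(4)
  p <- gated_extractor_params(512L, 64L)
  x <- matrix(rnorm(512), 1)
  s <- gate_scores(x, p)
  expect_true(all(s > 0 & s < 1))
  expect_lt(max(abs(s - straight_line_gate(x, p))), 1e-6)
  out <- gated_extract(x, p)
  expect_lt(max(abs(out - straight_line_gate(x, p) * x)), 1e-6)
  # gate < 1 shrinks every component
  expect_true(all(abs(out) <= abs(x)))
  expect_error(gate_scores(matrix(0, 1, 8), p), "width 512, got 8")
})

test_that("interaction fusion composes two gated extractions", {
  set.seed(5)
  d <- 16L
  ie1 <- gated_extractor_params(2L * d, 8L)
  ie2 <- gated_extractor_params(2L * d, 8L)
  xs <- list(x1_eog = rnorm(d), x1_eeg = rnorm(d),
             x2_eog = rnorm(d), x2_eeg = rnorm(d))
  fused <- fuse_imf(xs, ie1, ie2)
  c1 <- matrix(c(xs$x1_eog, xs$x1_eeg), 1)
  c2 <- matrix(c(xs$x2_eog, xs$x2_eeg), 1)
  oracle <- gated_extract(c1, ie1) + gated_extract(c2, ie2)
  expect_lt(max(abs(fused - oracle)), 1e-6)
  # zero inputs and constant gates
  zs <- lapply(xs, function(x) x * 0)
  expect_equal(fuse_imf(zs, ie1, ie2), matrix(0, 1, 2 * d))
  z1 <- gated_extractor_params(2L * d, 8L, init = "zero")
  expect_equal(fuse_imf(xs, z1, z1), 0.5 * c1 + 0.5 * c2)
  xs_bad <- xs; xs_bad$x1_eog <- rnorm(d + 1)
  expect_error(fuse_imf(xs_bad, ie1, ie2), "share one width")
})

test_that("heterogeneous fusion composes three gated extractions", {
  set.seed(6)
  d <- 16L
  hes <- lapply(1:3, function(i) gated_extractor_params(d, 8L))
  xs <- list(x1 = rnorm(d), x2 = rnorm(d), x3 = rnorm(d))
  fused <- fuse_hdf(xs, hes[[1]], hes[[2]], hes[[3]])
  oracle <- Reduce(`+`, lapply(1:3, function(i) {
    gated_extract(matrix(xs[[i]], 1), hes[[i]])
  }))
  expect_lt(max(abs(fused - oracle)), 1e-6)
  z <- gated_extractor_params(d, 8L, init = "zero")
  x <- rnorm(d)
  expect_equal(fuse_hdf(list(x1 = x, x2 = x, x3 = x), z, z, z),
               matrix(1.5 * x, 1))
  expect_equal(fuse_hdf(lapply(xs, `*`, 0), hes[[1]], hes[[2]], hes[[3]]),
               matrix(0, 1, d))
  # fused magnitude bounded by the sum of input magnitudes
  expect_true(all(abs(fused) <= abs(xs$x1) + abs(xs$x2) + abs(xs$x3)))
})

test_that("distinct extractors make fusion sensitive to tap assignment", {
  set.seed(7)
  d <- 8L
  hes <- lapply(1:3, function(i) gated_extractor_params(d, 6L))
  xs <- list(x1 = rnorm(d), x2 = rnorm(d), x3 = rnorm(d))
  base <- fuse_hdf(xs, hes[[1]], hes[[2]], hes[[3]])
  perm <- fuse_hdf(list(x1 = xs$x2, x2 = xs$x3, x3 = xs$x1),
                   hes[[1]], hes[[2]], hes[[3]])
  expect_gt(max(abs(base - perm)), 1e-8)
  # with shared parameters the sum is permutation-invariant
  shared <- fuse_hdf(xs, hes[[1]], hes[[1]], hes[[1]])
  shared_p <- fuse_hdf(list(x1 = xs$x3, x2 = xs$x1, x3 = xs$x2),
                       hes[[1]], hes[[1]], hes[[1]])
  expect_equal(shared, shared_p)
})

test_that("fusion output is differentiable in the gate parameters", {
  ad <- asNamespace("emokd")
  set.seed(8)
  d <- 6L
  p <- gated_extractor_params(d, 4L)
  x <- matrix(rnorm(d), 1)
  w <- matrix(rnorm(d), 1)
  f <- function(pl) {
    tp <- ad$ad_tape(grad = FALSE)
    pn <- ad$params_to_nodes(tp, pl, track = FALSE)
    o <- ad$gated_extract_nodes(ad$ad_const(tp, x), pn$W1, pn$b1, pn$W2, pn$b2)
    sum(o$val * w)
  }
  tp <- ad$ad_tape()
  pn <- ad$params_to_nodes(tp, unclass(p), track = TRUE)
  o <- ad$gated_extract_nodes(ad$ad_const(tp, x), pn$W1, pn$b1, pn$W2, pn$b2)
  ad$ad_backward(tp, ad$ad_sum_all(ad$ad_mul(o, ad$ad_const(tp, w))))
  grads <- ad$grads_of(pn)
  coords <- top_coords(grads, 20L)
  ng <- num_grad_params(f, unclass(p), coords)
  expect_lt(rel_err(coords$g, ng), 1e-4)
})
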