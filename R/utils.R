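# Shared internal utilities: seed fan-out, parameter initialization, the
# Adam optimizer used by every training loop, parameter fingerprints, and the
# partition access log used to audit the evaluation protocol.

the <- new.env(parent = emptyenv())
the$access_log <- list()

#' Derive independent sub-seeds from one master seed
#'
#' A single run seed fans out to named sub-seeds (data generation, parameter
#' initialization, batch shuffling, ...) so components can be varied
#' independently while the whole run stays reproducible.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483645L, n)
}

# Glorot-uniform weight matrix (fan_in x fan_out)
glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

one_hot <- function(labels, K = 2L) {
  y <- matrix(0, length(labels), K)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      st$lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + st$eps)
  }
  params
}

# ---- fingerprints and the access log --------------------------------------

#' Fingerprint a parameter set
#'
#' MD5 digest of the serialized parameter list; used to assert the
#' phase-purity contracts (the teaching phase never touches teacher
#' parameters, the feedback phase never touches student parameters).
#'
#' @param params Named list of numeric matrices.
#' @return Character MD5 digest.
#' @export
param_fingerprint <- function(params) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(params, f, compress = FALSE, version = 2)
  unname(tools::md5sum(f))
}

log_access <- function(partition, context, n = NA_integer_) {
  the$access_log[[length(the$access_log) + 1L]] <-
    list(partition = partition, context = context, n = n)
  invisible(NULL)
}

#' Partition access log
#'
#' Every training or evaluation routine records which data partition it read
#' and in what context. Auditing this log shows that test-partition segments
#' are only ever touched at final evaluation.
#'
#' @return Data frame with columns `partition`, `context`, `n`.
#' @export
access_log <- function() {
  if (length(the$access_log) == 0L) {
    return(data.frame(partition = character(), context = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(the$access_log, function(e) {
    data.frame(partition = e$partition, context = e$context, n = e$n,
               stringsAsFactors = FALSE)
  }))
}

#' Clear the partition access log
#' @return Invisibly, `NULL`.
#' @export
reset_access_log <- function() {
  the$access_log <- list()
  invisible(NULL)
}

# deep-copy guard for numeric lists (R copies on assignment, but make the
# intent explicit at checkpoint boundaries)
copy_params <- function(params) lapply(params, function(p) p + 0)
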