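# Internal helpers shared across modules.

# Run `code` under a temporary RNG state when `seed` is given; leave the
# caller's RNG untouched. `seed = NULL` uses the ambient RNG stream, which is
# what composite operations (e.g. evolve()) rely on to stay reproducible from
# a single seed.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

stop_if_not_ <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Equal-width stratified fold assignment; every fold gets samples from both
# classes whenever the class counts permit it.
stratified_folds_ <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

format_sig_ <- function(x, digits = 12) {
  sprintf(paste0("%.", digits, "g"), x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical sparse form used throughout (dgCMatrix)
to_sparse_ <- function(W) {
  if (!inherits(W, "sparseMatrix")) W <- Matrix::Matrix(W, sparse = TRUE)
  methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
}
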