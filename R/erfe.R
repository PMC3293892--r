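# Entropy-based recursive feature elimination and the bootstrap schema.

entropy_ <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Choose the optimal number of features
#'
#' Returns the candidate size attaining the minimum of the classification
#' error curve; ties go to the smallest size (parsimony).
#'
#' @param sizes candidate model sizes.
#' @param errors error estimate per size.
#' @return The chosen size.
#' @export
choose_n_features <- function(sizes, errors) {
  stop_if_not_(length(sizes) > 0 && length(sizes) == length(errors),
               "sizes and errors must be non-empty and aligned")
  o <- order(sizes)
  sizes <- sizes[o]; errors <- errors[o]
  sizes[which.min(errors)]
}

# One elimination pass: which active features to discard given weights.
erfe_discard_ <- function(w, bins, entropy_threshold, discard_fraction) {
  n <- length(w)
  wn <- if (sum(w) > 0) w / sum(w) else rep(1 / n, n)
  top <- max(wn)
  if (top == 0) return(order(w)[seq_len(max(1, n - 1))])
  cuts <- seq(0, top, length.out = bins + 1)
  bin <- pmin(pmax(findInterval(wn, cuts, rightmost.closed = TRUE), 1L), bins)
  H <- entropy_(tabulate(bin, bins) / n)
  if (H < entropy_threshold * log(bins)) {
    # weights concentrated on few features: drop the low-weight bin cluster
    drop <- which(bin == 1L)
    if (length(drop) == 0 || length(drop) == n)
      drop <- order(w)[seq_len(max(1, min(n - 1, floor(discard_fraction * n))))]
    if (length(drop) == n) drop <- drop[-which.max(w[drop])]
  } else {
    k <- max(1, min(n - 1, floor(discard_fraction * n)))
    drop <- order(w)[seq_len(k)]
  }
  drop
}

erfe_order_ <- function(spec, x, y, bins, entropy_threshold, discard_fraction) {
  p <- nrow(x)
  if (p == 1) return(list(order = 1L, sizes = 1L, w_full = 1))
  active <- seq_len(p)
  batches <- list()
  sizes <- integer(0)
  w_full <- NULL
  while (length(active) > 1) {
    sizes <- c(sizes, length(active))
    w <- weight_features(spec, x[active, , drop = FALSE], y)
    if (is.null(w_full)) w_full <- w
    drop <- erfe_discard_(w, bins, entropy_threshold, discard_fraction)
    # within a batch, higher weight ranks better
    batches[[length(batches) + 1L]] <- active[drop[order(-w[drop])]]
    active <- active[-drop]
  }
  sizes <- c(sizes, length(active))
  ord <- c(active, unlist(rev(batches)))
  list(order = ord, sizes = sizes, w_full = w_full)
}

# Honest error curve: within each fold the ERFE ordering is recomputed on
# the training part alone, so held-out samples never influence the ranking
# they are scored against (otherwise the curve reports near-zero error at
# large sizes on data with no class signal at all).
cv_curve_ <- function(spec, x, y, sizes, folds, ...) {
  fold <- stratified_folds_(y, folds)
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2)
      return(matrix(NA_real_, 2, length(sizes)))
    ord_f <- erfe_order_(spec, x[, tr, drop = FALSE], y[tr], ...)$order
    vapply(sizes, function(s) {
      top <- ord_f[seq_len(min(s, length(ord_f)))]
      pred <- fit_predict_(spec, x[top, tr, drop = FALSE], y[tr],
                           x[top, !tr, drop = FALSE])
      c(mean(pred != y[!tr]),
        mcc_from_labels_(y[!tr], pred, levels(y)[2]))
    }, numeric(2))
  })
  acc <- Reduce(`+`, lapply(per_fold, function(m) {
    m[is.na(m)] <- 0; m
  }))
  cnt <- Reduce(`+`, lapply(per_fold, function(m) !is.na(m)))
  res <- acc / pmax(cnt, 1)
  list(errors = res[1, ], mcc = res[2, ])
}

new_ranking_run_ <- function(ids, order, sizes, errors, mcc, spec, mode,
                             weights = NULL, extra = list()) {
  n_star <- if (all(is.na(errors))) sizes[1] else choose_n_features(sizes, errors)
  structure(c(list(
    ranking = ids[order], sizes = sizes, errors = errors, mcc = mcc,
    n_star = n_star, selected = ids[order][seq_len(n_star)],
    spec = spec, mode = mode, weights = weights), extra),
    class = "ranking_run")
}

#' @export
print.ranking_run <- function(x, ...) {
  cat(sprintf("Ranking run (%s, %s): %d features ranked, n* = %d (error %.3f)\n",
              x$spec$name, x$mode, length(x$ranking), x$n_star,
              min(x$errors, na.rm = TRUE)))
  invisible(x)
}

#' Entropy-based recursive feature elimination
#'
#' Iteratively fits the weighting engine on the active features and discards
#' the least informative ones: when the entropy of the normalised weight
#' distribution (over a fixed-bin histogram) falls below
#' \code{entropy_threshold * log(bins)}, all features in the lowest-weight
#' bin are discarded at once; otherwise the lowest \code{discard_fraction}
#' are. Eliminated features are appended to the tail of the ranking in
#' elimination order (later-eliminated features rank better). The
#' classification error at every visited model size is estimated by
#' stratified internal cross-validation in which the ERFE ordering is
#' recomputed on each training fold (held-out samples never touch the
#' ranking they score), and the optimal size is the error minimiser. The
#' reported ranking itself uses all samples.
#'
#' @param spec a tuned \code{\link{method_spec}}.
#' @param x features x samples matrix (rownames used as feature ids).
#' @param y two-class factor.
#' @param seed RNG seed (internal CV folds).
#' @param bins histogram bins for the entropy measure.
#' @param entropy_threshold fraction of the maximal entropy below which the
#'   adaptive discard triggers.
#' @param discard_fraction fallback fraction discarded per step.
#' @param curve \code{"cv"} to estimate the error curve, \code{"none"} to
#'   rank only.
#' @param folds internal CV folds.
#' @return An object of class \code{ranking_run}: the full ranking (best
#'   first), visited \code{sizes}, per-size \code{errors} and \code{mcc},
#'   chosen \code{n_star} and \code{selected} set.
#' @export
erfe_rank <- function(spec, x, y, seed = NULL, bins = 10,
                      entropy_threshold = 0.5, discard_fraction = 0.2,
                      curve = c("cv", "none"), folds = 3) {
  curve <- match.arg(curve)
  stopifnot(inherits(spec, "method_spec"))
  y <- droplevels(as.factor(y))
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  with_seed_(seed, {
    eo <- erfe_order_(spec, x, y, bins, entropy_threshold, discard_fraction)
    if (curve == "none") {
      return(new_ranking_run_(ids, eo$order, sizes = nrow(x),
                              errors = NA_real_, mcc = NA_real_,
                              spec = spec, mode = "single",
                              weights = stats::setNames(eo$w_full, ids)))
    }
    cc <- cv_curve_(spec, x, y, eo$sizes, folds,
                    bins = bins, entropy_threshold = entropy_threshold,
                    discard_fraction = discard_fraction)
    new_ranking_run_(ids, eo$order, eo$sizes, cc$errors, cc$mcc,
                     spec, mode = "single", weights = stats::setNames(eo$w_full, ids))
  })
}

geometric_sizes_ <- function(p, ratio = 0.7) {
  sort(unique(pmax(1L, round(p * ratio^(0:ceiling(log(1 / p) / log(ratio)))))))
}

stratified_split_ <- function(y, test_fraction) {
  test <- unlist(lapply(levels(y), function(lev) {
    idx <- which(y == lev)
    sample(idx, max(1L, round(test_fraction * length(idx))))
  }))
  sort(test)
}

#' Monte Carlo bootstrap ranking
#'
#' Runs \code{B} external stratified training/test splits. On each training
#' part only: hyperparameter tuning (3-fold CV) and ERFE ranking; the error
#' curve is then measured on the held-out part at a fixed geometric grid of
#' model sizes. Test samples never touch tuning or ranking. Per-split
#' rankings are aggregated by mean rank (Borda; ties by mean full-model
#' weight), error curves by their mean, and the optimal size is chosen on
#' the aggregated curve.
#'
#' @param spec a \code{\link{method_spec}} (tuned per split when
#'   \code{tune = TRUE}).
#' @param x features x samples matrix.
#' @param y two-class factor.
#' @param B number of external splits (study default 100).
#' @param test_fraction held-out fraction per split (default 1/3),
#'   stratified by class.
#' @param seed RNG seed.
#' @param tune tune hyperparameters on each training part?
#' @param sizes model-size grid for the held-out error curve; default a
#'   geometric grid from p down to 1.
#' @param ... passed to \code{\link{erfe_rank}} (bins, thresholds).
#' @return A \code{ranking_run} with \code{mode = "bootstrap"} and field
#'   \code{B}.
#' @export
bootstrap_rank <- function(spec, x, y, B = 100, test_fraction = 1/3,
                           seed = NULL, tune = TRUE, sizes = NULL, ...) {
  stopifnot(inherits(spec, "method_spec"))
  stop_if_not_(B >= 1, "need B >= 1")
  y <- droplevels(as.factor(y))
  p <- nrow(x)
  ids <- rownames(x) %||% as.character(seq_len(p))
  sizes <- sizes %||% geometric_sizes_(p)
  with_seed_(seed, {
    rank_sum <- numeric(p)
    w_sum <- numeric(p)
    err_mat <- matrix(NA_real_, nrow = B, ncol = length(sizes))
    mcc_mat <- matrix(NA_real_, nrow = B, ncol = length(sizes))
    budget <- 10L * B
    b <- 0L
    while (b < B) {
      stop_if_not_(budget > 0, "could not draw valid stratified splits")
      budget <- budget - 1L
      te <- stratified_split_(y, test_fraction)
      tr <- setdiff(seq_along(y), te)
      if (nlevels(droplevels(y[tr])) < 2 || min(table(y[tr])) < 2) next
      b <- b + 1L
      xtr <- x[, tr, drop = FALSE]; ytr <- y[tr]
      sp <- if (tune) tune_hyperparams(spec, xtr, ytr) else spec
      run <- erfe_rank(sp, xtr, ytr, curve = "none", ...)
      rk <- match(ids, run$ranking)
      rank_sum <- rank_sum + rk
      w_sum <- w_sum + run$weights
      ord_b <- match(run$ranking, ids)
      for (si in seq_along(sizes)) {
        top <- ord_b[seq_len(sizes[si])]
        pred <- fit_predict_(sp, x[top, tr, drop = FALSE], ytr,
                             x[top, te, drop = FALSE])
        err_mat[b, si] <- mean(pred != y[te])
        mcc_mat[b, si] <- mcc_from_labels_(y[te], pred, levels(y)[2])
      }
    }
    agg_order <- order(rank_sum / B, -w_sum / B, seq_len(p))
    new_ranking_run_(ids, agg_order, sizes,
                     colMeans(err_mat), colMeans(mcc_mat),
                     spec, mode = "bootstrap",
                     extra = list(B = B, test_fraction = test_fraction))
  })
}
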