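#' Feature-weighting method specification
#'
#' The four multivariate weighting engines: linear SVM (\code{LSVM},
#' weights = absolute hyperplane coefficients), Gaussian-kernel SVM
#' (\code{GSVM}, per-feature criterion = change of the margin objective when
#' the feature is removed from the kernel), spectral-regression discriminant
#' analysis (\code{SRDA}, absolute ridge-regularised discriminant
#' coefficients from regressing the centred class indicator), and I-Relief
#' (\code{IRELIEF}, margin-based iterative weights with a kernelised
#' nearest-neighbour strategy; the IRSVM combination classifies with a
#' linear SVM on top of the I-Relief ranking).
#'
#' @param name one of \code{"LSVM"}, \code{"GSVM"}, \code{"SRDA"},
#'   \code{"IRELIEF"}.
#' @param c SVM regularisation constant.
#' @param sigma Gaussian bandwidth (GSVM kernel / I-Relief internal kernel);
#'   \code{NULL} defers to the median-distance heuristic at fit time.
#' @param alpha SRDA ridge regularisation.
#' @param grid named list of candidate values for
#'   \code{\link{tune_hyperparams}}; \code{NULL} uses the method's default
#'   grid (bandwidths as multiples of the median pairwise distance).
#' @return An object of class \code{method_spec}.
#' @export
method_spec <- function(name = c("LSVM", "GSVM", "SRDA", "IRELIEF"),
                        c = 1, sigma = NULL, alpha = 1, grid = NULL) {
  name <- match.arg(name)
  structure(list(name = name, c = c, sigma = sigma, alpha = alpha,
                 grid = grid, tuned = FALSE),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  pars <- switch(x$name,
    LSVM = sprintf("c = %g", x$c),
    GSVM = sprintf("c = %g, sigma = %s", x$c,
                   if (is.null(x$sigma)) "auto" else format(x$sigma)),
    SRDA = sprintf("alpha = %g", x$alpha),
    IRELIEF = sprintf("sigma = %s",
                      if (is.null(x$sigma)) "auto" else format(x$sigma)))
  cat(sprintf("Method %s (%s)%s\n", x$name, pars,
              if (isTRUE(x$tuned)) " [tuned]" else ""))
  invisible(x)
}

median_dist_ <- function(x) {
  # median pairwise Euclidean distance between samples (columns)
  d <- stats::dist(t(x))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

default_grid_ <- function(spec, x) {
  if (!is.null(spec$grid)) return(spec$grid)
  s0 <- median_dist_(x)
  switch(spec$name,
    LSVM = list(c = c(0.01, 0.1, 1, 10, 100)),
    GSVM = list(c = c(0.1, 1, 10), sigma = c(0.5, 1, 2) * s0),
    SRDA = list(alpha = c(0.01, 0.1, 1, 10, 100)),
    IRELIEF = list(sigma = c(0.5, 1, 2) * s0))
}

svm_fit_ <- function(x, y, spec) {
  if (spec$name %in% c("LSVM", "SRDA", "IRELIEF")) {
    e1071::svm(t(x), y, kernel = "linear", cost = spec$c, scale = FALSE)
  } else {
    sigma <- spec$sigma %||% median_dist_(x)
    e1071::svm(t(x), y, kernel = "radial", gamma = 1 / (2 * sigma^2),
               cost = spec$c, scale = FALSE)
  }
}

srda_fit_ <- function(x, y, alpha) {
  # ridge discriminant in the dual (p >> n): w = Xc' (Xc Xc' + a I)^-1 r
  ctr <- rowMeans(x)
  Z <- t(x - ctr)                        # n x p, centred features
  r <- ifelse(y == levels(y)[2], 1, -1)
  r <- r - mean(r)
  G <- Z %*% t(Z)
  diag(G) <- diag(G) + alpha
  w <- as.numeric(crossprod(Z, solve(G, r)))
  sc <- as.numeric(Z %*% w)
  thr <- (mean(sc[y == levels(y)[1]]) + mean(sc[y == levels(y)[2]])) / 2
  list(w = w, center = ctr, threshold = thr, levels = levels(y))
}

srda_predict_ <- function(fit, x) {
  sc <- as.numeric(t(x - fit$center) %*% fit$w)
  factor(ifelse(sc > fit$threshold, fit$levels[2], fit$levels[1]),
         levels = fit$levels)
}

# Fit the method's classifier on (xtr, ytr) and predict xte. For IRELIEF the
# classifier is a linear SVM (the IRSVM combination); ranking quality, not
# the classifier, is what distinguishes it.
fit_predict_ <- function(spec, xtr, ytr, xte) {
  if (spec$name == "SRDA") {
    fit <- srda_fit_(xtr, ytr, spec$alpha)
    srda_predict_(fit, xte)
  } else {
    fit <- svm_fit_(xtr, ytr, spec)
    stats::predict(fit, t(xte))
  }
}

irelief_weights_ <- function(x, y, sigma = NULL, tol = 1e-4, max_iter = 100) {
  p <- nrow(x); n <- ncol(x)
  sigma <- sigma %||% median_dist_(x)
  same <- outer(y, y, "==")
  diag(same) <- NA                       # a sample is neither its own hit nor miss
  D <- lapply(seq_len(n), function(i) abs(x - x[, i]))  # per-sample |x_i - x_j|
  w <- rep(1 / p, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    nu <- numeric(p)
    for (i in seq_len(n)) {
      dw <- colSums(w * D[[i]])
      f <- exp(-dw / sigma)
      hit <- which(same[i, ] %in% TRUE)
      miss <- which(same[i, ] %in% FALSE)
      ph <- f[hit]; pm <- f[miss]
      if (sum(ph) > 0) ph <- ph / sum(ph) else ph <- rep(1 / length(hit), length(hit))
      if (sum(pm) > 0) pm <- pm / sum(pm) else pm <- rep(1 / length(miss), length(miss))
      nu <- nu + as.numeric(D[[i]][, miss, drop = FALSE] %*% pm) -
                 as.numeric(D[[i]][, hit, drop = FALSE] %*% ph)
    }
    nu <- nu / n
    w_new <- pmax(nu, 0)
    if (sum(w_new) == 0) w_new <- rep(1 / p, p) else w_new <- w_new / sum(w_new)
    if (sqrt(sum((w_new - w)^2)) < tol) {
      w <- w_new; converged <- TRUE; break
    }
    w <- w_new
  }
  if (!converged)
    warning("I-Relief did not converge; returning the last iterate")
  attr(w, "converged") <- converged
  w
}

gsvm_criterion_ <- function(x, y, spec) {
  fit <- svm_fit_(x, y, spec)
  S <- fit$SV                            # n_sv x p
  cf <- as.numeric(fit$coefs)
  g <- fit$gamma
  m <- nrow(S)
  if (m < 2) return(rep(0, nrow(x)))
  K <- exp(-g * as.matrix(stats::dist(S))^2)
  BK <- (cf %o% cf) * K
  W2 <- sum(BK)
  ii <- rep(seq_len(m), times = m)
  jj <- rep(seq_len(m), each = m)
  E <- exp(g * (S[ii, , drop = FALSE] - S[jj, , drop = FALSE])^2)
  abs(W2 - as.numeric(crossprod(E, as.vector(BK))))
}

#' Compute per-feature weights
#'
#' Dispatches to the engine named by \code{spec}: absolute linear-SVM
#' hyperplane coefficients, the Gaussian-SVM margin-change criterion,
#' absolute SRDA discriminant coefficients, or I-Relief margin weights
#' (non-negative, unit sum, iterated to convergence). All engines return a
#' non-negative weight per feature (row of \code{x}); larger is more
#' informative.
#'
#' @param spec a \code{\link{method_spec}} (tuned or with explicit
#'   hyperparameters).
#' @param x features x samples matrix.
#' @param y two-class factor of length \code{ncol(x)}.
#' @return Numeric vector of length \code{nrow(x)}.
#' @export
weight_features <- function(spec, x, y) {
  stopifnot(inherits(spec, "method_spec"))
  y <- droplevels(as.factor(y))
  stop_if_not_(nlevels(y) == 2, "need exactly two classes")
  switch(spec$name,
    LSVM = {
      fit <- svm_fit_(x, y, spec)
      abs(as.numeric(crossprod(fit$coefs, fit$SV)))
    },
    GSVM = gsvm_criterion_(x, y, spec),
    SRDA = abs(srda_fit_(x, y, spec$alpha)$w),
    IRELIEF = irelief_weights_(x, y, spec$sigma))
}

#' Tune hyperparameters by 3-fold cross-validation
#'
#' Evaluates every grid point by stratified 3-fold cross-validated
#' misclassification error of the method's classifier on all features (no
#' feature ranking during tuning) and returns the spec with the minimising
#' values. Ties prefer the strongest regularisation: smallest \code{c},
#' largest \code{sigma}, largest \code{alpha}.
#'
#' @param spec a \code{\link{method_spec}}.
#' @param x features x samples matrix.
#' @param y two-class factor.
#' @param folds number of folds (default 3).
#' @param seed RNG seed for the fold assignment.
#' @return The tuned \code{method_spec} (with \code{tuned = TRUE} and the
#'   grid search recorded in \code{$tuning}).
#' @export
tune_hyperparams <- function(spec, x, y, folds = 3, seed = NULL) {
  stopifnot(inherits(spec, "method_spec"))
  y <- droplevels(as.factor(y))
  stop_if_not_(nlevels(y) == 2, "need exactly two classes to tune")
  with_seed_(seed, {
    grid <- expand.grid(default_grid_(spec, x))
    # tie order: strongest regularisation first
    ord <- do.call(order, c(
      lapply(names(grid), function(nm) switch(nm,
        c = grid[[nm]], sigma = -grid[[nm]], alpha = -grid[[nm]])),
      list()))
    grid <- grid[ord, , drop = FALSE]
    if (nrow(grid) > 1) {
      fold <- stratified_folds_(y, folds)
      err <- vapply(seq_len(nrow(grid)), function(k) {
        cand <- spec
        for (nm in names(grid)) cand[[nm]] <- grid[k, nm]
        mean(vapply(seq_len(folds), function(f) {
          tr <- fold != f; te <- !tr
          if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
          pred <- fit_predict_(cand, x[, tr, drop = FALSE], y[tr],
                               x[, te, drop = FALSE])
          mean(pred != y[te])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      best <- which.min(err)
    } else {
      err <- NA_real_
      best <- 1L
    }
    for (nm in names(grid)) spec[[nm]] <- grid[best, nm]
    spec$tuned <- TRUE
    spec$tuning <- cbind(grid, cv_error = err)
    spec
  })
}
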