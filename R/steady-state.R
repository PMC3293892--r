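# Steady-state phenotype computation.
#
# Dynamics: dx_i/dt = beta_i * (ceiling_i * sigma(sum_j w_ij x_j + bias_i) - x_i)
# with logistic sigma, on the normalised expression scale x in [0, 1].
# alpha_i sets the absolute transcription scale (absolute level =
# alpha_i / beta_i * x_i) and does not move the fixed point, so all
# downstream thresholds operate on the normalised scale. The fixed point is
# found by damped fixed-point iteration (equivalent to explicit integration
# with a uniform step), with progressively smaller damping as a fallback
# when strong feedback loops make the undamped map oscillate.

logistic_ <- function(z) 1 / (1 + exp(-z))

# Core solver on an arbitrary (sub)system. W: sparse n x n, all vectors
# length n. Returns list(x, converged, residual, iterations).
solve_fixed_point_ <- function(W, bias, ceiling, clamp, x0,
                               tol = 1e-8, max_iter = 10000L) {
  x <- x0
  if (length(clamp)) x[clamp] <- 0
  for (damping in c(0.5, 0.1)) {
    for (it in seq_len(max_iter)) {
      target <- ceiling * logistic_(as.numeric(W %*% x) + bias)
      if (length(clamp)) target[clamp] <- 0
      if (any(!is.finite(target))) {
        bad <- which(!is.finite(target))[1]
        stop(sprintf("non-finite expression at gene %d during integration", bad),
             call. = FALSE)
      }
      resid <- max(abs(target - x))
      if (resid <= tol)
        return(list(x = x, converged = TRUE, residual = resid, iterations = it))
      x <- x + damping * (target - x)
    }
  }
  list(x = x, converged = FALSE, residual = resid, iterations = max_iter)
}

#' Steady-state expression of a network
#'
#' Computes the fixed point of the regulatory dynamics
#' \eqn{dx_i/dt = \beta_i (\sigma(\sum_j w_{ij} x_j + bias_i) - x_i)} with
#' logistic \eqn{\sigma}, reporting the normalised expression
#' \eqn{x \in [0,1]^p}. Genes in \code{clamp_zero} are held at exactly 0 and
#' \code{ceiling} rescales the attainable maximum (both used by the
#' knock-out/knock-down perturbations). With an all-zero \code{W} and zero
#' bias every gene settles at 0.5.
#'
#' @param net a \code{\link{grn_network}}.
#' @param x0 initial expression in \eqn{[0,1]^p} (default all 0.5).
#' @param tol convergence tolerance on the maximum update.
#' @param max_iter iteration budget per damping level.
#' @return An object of class \code{expression_state}: list with \code{x},
#'   \code{converged}, \code{residual}, \code{iterations}.
#' @export
steady_state <- function(net, x0 = NULL, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(net, "grn_network"))
  if (is.null(x0)) x0 <- rep(0.5, net$p)
  stop_if_not_(length(x0) == net$p, "x0 has wrong length")
  stop_if_not_(all(x0 >= 0 & x0 <= 1), "x0 must lie in [0, 1]")
  out <- solve_fixed_point_(net$W, net$bias, net$ceiling, net$clamp_zero,
                            x0, tol = tol, max_iter = max_iter)
  structure(out, class = "expression_state")
}

#' @export
print.expression_state <- function(x, ...) {
  cat(sprintf("Expression state: %d genes, %s (residual %.2e, %d iterations)\n",
              length(x$x),
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$iterations))
  invisible(x)
}
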