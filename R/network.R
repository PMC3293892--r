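#' Gene regulatory network
#'
#' The genotype of a simulated subject: a signed sparse connectivity matrix
#' \code{W} with \code{W[i, j] != 0} iff gene-product \code{j} directly
#' regulates gene \code{i} (sign = activation/repression, magnitude =
#' strength), per-gene kinetic parameters (maximal transcription rate
#' \code{alpha}, degradation rate \code{beta}), a basal regulatory input
#' \code{bias}, and the index set of the evolvable subnetwork. The evolvable
#' block is constrained to be disconnected from the background block in both
#' directions, so perturbations never leak across.
#'
#' \code{ceiling} and \code{clamp_zero} carry perturbation state: a gene's
#' normalised expression is \code{ceiling * sigma(input)}, and clamped genes
#' are held at exactly 0 (see \code{\link{knock_out}},
#' \code{\link{knock_down}}).
#'
#' @param W p x p matrix (coerced to sparse) of regulatory weights.
#' @param evolvable integer indices of the evolvable subnetwork.
#' @param alpha,beta per-gene kinetic parameters, strictly positive
#'   (recycled if scalar).
#' @param bias per-gene basal regulatory input (recycled).
#' @param ceiling per-gene transcription ceiling in (0, 1] (recycled).
#' @param clamp_zero integer indices of genes clamped at zero expression.
#' @return An object of class \code{grn_network}.
#' @export
grn_network <- function(W, evolvable = integer(0), alpha = 20, beta = 0.2,
                        bias = 0, ceiling = 1, clamp_zero = integer(0)) {
  W <- to_sparse_(W)
  p <- nrow(W)
  stop_if_not_(ncol(W) == p, "W must be square")
  evolvable <- sort(unique(as.integer(evolvable)))
  stop_if_not_(all(evolvable >= 1 & evolvable <= p), "evolvable index out of range")
  alpha <- rep_len(alpha, p); beta <- rep_len(beta, p)
  bias <- rep_len(bias, p); ceiling <- rep_len(ceiling, p)
  stop_if_not_(all(alpha > 0) && all(beta > 0), "alpha and beta must be > 0")
  net <- structure(list(
    p = p, W = W, evolvable = evolvable,
    alpha = alpha, beta = beta, bias = bias,
    ceiling = ceiling, clamp_zero = sort(unique(as.integer(clamp_zero))),
    nnz_evolvable = NA_integer_), class = "grn_network")
  check_block_separation_(net)
  net$nnz_evolvable <- length(evolvable_triplets_(net)$x)
  net
}

check_block_separation_ <- function(net) {
  ev <- net$evolvable
  if (length(ev) == 0 || length(ev) == net$p) return(invisible(TRUE))
  bg <- setdiff(seq_len(net$p), ev)
  cross <- Matrix::nnzero(net$W[ev, bg, drop = FALSE]) +
    Matrix::nnzero(net$W[bg, ev, drop = FALSE])
  stop_if_not_(cross == 0,
               "evolvable and background blocks must be disconnected (%d cross edges)",
               cross)
  invisible(TRUE)
}

# triplet (i, j, x) view of the evolvable block, in a fixed canonical order
evolvable_triplets_ <- function(net) {
  ev <- net$evolvable
  tr <- Matrix::summary(net$W)
  keep <- tr$i %in% ev & tr$j %in% ev
  tr <- tr[keep, , drop = FALSE]
  tr[order(tr$j, tr$i), , drop = FALSE]
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("Gene regulatory network: %d genes, %d edges\n",
              x$p, Matrix::nnzero(x$W)))
  cat(sprintf("  evolvable subnetwork: %d genes, %d edges\n",
              length(x$evolvable), x$nnz_evolvable))
  if (length(x$clamp_zero))
    cat("  knocked-out genes:", paste(x$clamp_zero, collapse = ", "), "\n")
  invisible(x)
}

# Draw a right-skewed out-degree sequence summing exactly to nnz by
# allocating edge source slots with Pareto-tail propensities, then place
# distinct targets uniformly (no self-loops). Returns an (i, j) matrix.
skewed_edges_ <- function(genes, nnz, hub_exponent = 2.3) {
  n <- length(genes)
  if (nnz == 0) return(cbind(i = integer(0), j = integer(0)))
  cap <- n - 1L
  stop_if_not_(nnz <= n * cap,
               "requested %d edges exceed capacity %d", nnz, n * cap)
  # Pareto(1, hub_exponent - 1) propensities give a heavy right tail
  prop <- (1 - stats::runif(n))^(-1 / (hub_exponent - 1))
  deg <- stats::rmultinom(1, nnz, prop / sum(prop))[, 1]
  # redistribute overflow above the per-gene target capacity
  repeat {
    over <- deg > cap
    if (!any(over)) break
    excess <- sum(deg[over] - cap)
    deg[over] <- cap
    room <- which(deg < cap)
    add <- stats::rmultinom(1, excess, prop[room] / sum(prop[room]))[, 1]
    deg[room] <- deg[room] + add
  }
  src <- rep.int(seq_len(n), deg)
  tgt <- unlist(lapply(seq_len(n), function(g) {
    if (deg[g] == 0) return(integer(0))
    sample(seq_len(n)[-g], deg[g])
  }))
  cbind(i = genes[tgt], j = genes[src])   # j regulates i
}

#' Generate a random network topology
#'
#' Builds a \code{grn_network} whose evolvable block has exactly
#' \code{nnz_sub} nonzero weights drawn from Normal(0, 1), with a
#' right-skewed out-degree distribution so regulatory hubs exist. The
#' background block receives edges at the same density, disconnected from
#' the evolvable block. The first \code{n_sub} genes form the evolvable
#' subnetwork.
#'
#' @param p total gene count.
#' @param n_sub evolvable subnetwork size.
#' @param nnz_sub exact nonzero count of the evolvable block.
#' @param hub_exponent Pareto tail exponent of the out-degree propensities;
#'   smaller values give stronger hubs.
#' @param bias basal regulatory input (default 0, the symmetric baseline).
#' @param seed RNG seed (the draw is deterministic given the seed).
#' @return A \code{grn_network}.
#' @export
generate_topology <- function(p, n_sub, nnz_sub, hub_exponent = 2.3,
                              bias = 0, seed = NULL) {
  stop_if_not_(n_sub > 0 && n_sub <= p, "need 0 < n_sub <= p")
  stop_if_not_(nnz_sub >= 0 && nnz_sub <= n_sub * (n_sub - 1L),
               "nnz_sub outside the capacity of the evolvable block")
  with_seed_(seed, {
    ev <- seq_len(n_sub)
    edges <- skewed_edges_(ev, nnz_sub, hub_exponent)
    n_bg <- p - n_sub
    if (n_bg > 1) {
      density <- nnz_sub / (n_sub * (n_sub - 1))
      nnz_bg <- min(round(density * n_bg * (n_bg - 1)), n_bg * (n_bg - 1))
      edges <- rbind(edges, skewed_edges_(n_sub + seq_len(n_bg), nnz_bg,
                                          hub_exponent))
    }
    w <- stats::rnorm(nrow(edges))
    # guard the pathological exact zero, which would silently drop an edge
    w[w == 0] <- .Machine$double.eps
    W <- Matrix::sparseMatrix(i = edges[, "i"], j = edges[, "j"], x = w,
                              dims = c(p, p))
    grn_network(W, evolvable = ev, bias = bias)
  })
}

#' Kinetics prior
#'
#' Hierarchical Gaussian prior for per-gene kinetic parameters. The
#' subject-level means are \code{mu_alpha = 20} and \code{mu_beta = 0.2};
#' the subject-level spreads \code{sigma_alpha} and \code{sigma_beta} are
#' themselves resampled per subject from Gaussians with means 0.5 and 0.02
#' and standard deviations 0.075 and 0.0025.
#'
#' @param mu_alpha,mu_beta subject-level means of the transcription and
#'   degradation rates.
#' @param sigma_alpha_mean,sigma_alpha_sd hyperprior of the alpha spread.
#' @param sigma_beta_mean,sigma_beta_sd hyperprior of the beta spread.
#' @param floor positive truncation floor for sampled values.
#' @return An object of class \code{kinetics_prior}.
#' @export
kinetics_prior <- function(mu_alpha = 20, mu_beta = 0.2,
                           sigma_alpha_mean = 0.5, sigma_alpha_sd = 0.075,
                           sigma_beta_mean = 0.02, sigma_beta_sd = 0.0025,
                           floor = 1e-6) {
  structure(list(mu_alpha = mu_alpha, mu_beta = mu_beta,
                 sigma_alpha_mean = sigma_alpha_mean,
                 sigma_alpha_sd = sigma_alpha_sd,
                 sigma_beta_mean = sigma_beta_mean,
                 sigma_beta_sd = sigma_beta_sd,
                 floor = floor),
            class = "kinetics_prior")
}

#' Sample per-gene kinetic parameters for one subject
#'
#' Draws the subject's spreads \code{sigma_alpha}, \code{sigma_beta} from the
#' hyperprior (truncated at a small positive floor), then per-gene
#' \code{alpha_i ~ N(mu_alpha, sigma_alpha)} and
#' \code{beta_i ~ N(mu_beta, sigma_beta)}, truncated positive.
#'
#' @param prior a \code{\link{kinetics_prior}}.
#' @param p gene count.
#' @param seed RNG seed.
#' @return List with \code{alpha}, \code{beta}, \code{sigma_alpha},
#'   \code{sigma_beta}.
#' @export
sample_kinetics <- function(prior = kinetics_prior(), p, seed = NULL) {
  stopifnot(inherits(prior, "kinetics_prior"))
  with_seed_(seed, {
    sa <- max(stats::rnorm(1, prior$sigma_alpha_mean, prior$sigma_alpha_sd),
              prior$floor)
    sb <- max(stats::rnorm(1, prior$sigma_beta_mean, prior$sigma_beta_sd),
              prior$floor)
    list(alpha = pmax(stats::rnorm(p, prior$mu_alpha, sa), prior$floor),
         beta = pmax(stats::rnorm(p, prior$mu_beta, sb), prior$floor),
         sigma_alpha = sa, sigma_beta = sb)
  })
}

#' Write / read a network as plain-text tables
#'
#' Serialises a network to an edge-list TSV (\code{source}, \code{target},
#' \code{weight}; source regulates target) and a per-gene parameter TSV
#' (\code{gene_id}, \code{alpha}, \code{beta}, \code{bias}, \code{ceiling},
#' \code{evolvable}, \code{clamped}). Values round-trip to 12 significant
#' digits.
#'
#' @param net a \code{grn_network}.
#' @param edges_path,params_path output/input file paths.
#' @return \code{read_network} returns a \code{grn_network};
#'   \code{write_network} returns the paths invisibly.
#' @export
write_network <- function(net, edges_path, params_path) {
  tr <- Matrix::summary(net$W)
  edges <- data.frame(source = tr$j, target = tr$i,
                      weight = format_sig_(tr$x))
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  params <- data.frame(
    gene_id = seq_len(net$p),
    alpha = format_sig_(net$alpha), beta = format_sig_(net$beta),
    bias = format_sig_(net$bias), ceiling = format_sig_(net$ceiling),
    evolvable = as.integer(seq_len(net$p) %in% net$evolvable),
    clamped = as.integer(seq_len(net$p) %in% net$clamp_zero))
  utils::write.table(params, params_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges_path, params_path))
}

#' @rdname write_network
#' @export
read_network <- function(edges_path, params_path) {
  edges <- utils::read.table(edges_path, sep = "\t", header = TRUE)
  params <- utils::read.table(params_path, sep = "\t", header = TRUE)
  p <- nrow(params)
  W <- Matrix::sparseMatrix(i = edges$target, j = edges$source,
                            x = as.numeric(edges$weight), dims = c(p, p))
  grn_network(W, evolvable = which(params$evolvable == 1),
              alpha = as.numeric(params$alpha),
              beta = as.numeric(params$beta),
              bias = as.numeric(params$bias),
              ceiling = as.numeric(params$ceiling),
              clamp_zero = which(params$clamped == 1))
}
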