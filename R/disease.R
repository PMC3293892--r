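#' Select target hubs
#'
#' Hubs are the \code{k} evolvable genes with the highest out-degree among
#' those whose normalised founder steady-state expression exceeds
#' \code{expr_min} (so that knocking them out or down has an effect). Ties
#' in out-degree are broken by higher expression, then lower gene index.
#' The returned table is sorted by descending out-degree.
#'
#' @param net the founder \code{grn_network}.
#' @param phenotype the founder steady-state expression (vector of length p
#'   or an \code{expression_state}).
#' @param k number of hubs (default 6).
#' @param expr_min minimum normalised expression for eligibility
#'   (default 0.88).
#' @return An object of class \code{hub_set}: data.frame with columns
#'   \code{gene}, \code{out_degree}, \code{expression}.
#' @export
select_hubs <- function(net, phenotype, k = 6, expr_min = 0.88) {
  stopifnot(inherits(net, "grn_network"))
  if (inherits(phenotype, "expression_state")) phenotype <- phenotype$x
  if (k == 0)
    return(structure(data.frame(gene = integer(0), out_degree = integer(0),
                                expression = numeric(0)), class = c("hub_set", "data.frame")))
  ev <- net$evolvable
  outdeg <- Matrix::colSums(net$W != 0)
  eligible <- ev[phenotype[ev] > expr_min]
  if (length(eligible) < k)
    stop(sprintf(paste0("only %d evolvable genes have expression above %.3g; ",
                        "lower expr_min (degenerate topology draw)"),
                 length(eligible), expr_min), call. = FALSE)
  o <- order(-outdeg[eligible], -phenotype[eligible], eligible)
  sel <- eligible[o][seq_len(k)]
  structure(data.frame(gene = sel, out_degree = as.integer(outdeg[sel]),
                       expression = phenotype[sel]),
            class = c("hub_set", "data.frame"))
}

#' In-silico knock-out of a gene
#'
#' Sets row \code{j} of \code{W} to zero (the gene loses all regulatory
#' inputs) and clamps the gene's expression at exactly 0, then recomputes
#' the steady state of the remaining system. The clamp is persistent:
#' without it, the basal input would re-express the gene.
#'
#' @param net a \code{grn_network}.
#' @param phenotype current steady state (warm start for the recompute);
#'   vector or \code{expression_state}.
#' @param j gene index to knock out.
#' @return List with the perturbed \code{net} and its new \code{phenotype}
#'   (an \code{expression_state}).
#' @export
knock_out <- function(net, phenotype, j) {
  stopifnot(inherits(net, "grn_network"))
  stop_if_not_(j >= 1 && j <= net$p, "invalid gene index")
  if (inherits(phenotype, "expression_state")) phenotype <- phenotype$x
  net$W[j, ] <- 0
  net$W <- Matrix::drop0(net$W)
  net$clamp_zero <- sort(unique(c(net$clamp_zero, as.integer(j))))
  x0 <- phenotype; x0[j] <- 0
  list(net = net, phenotype = steady_state(net, x0 = x0))
}

#' In-silico knock-down of a gene
#'
#' Halves every entry of row \code{j} of \code{W} and halves the gene's
#' transcription ceiling, so its normalised expression is capped at half its
#' unperturbed maximum; the steady state is recomputed starting from the
#' halved expression value so downstream effects propagate.
#'
#' @inheritParams knock_out
#' @return List with the perturbed \code{net} and its new \code{phenotype}.
#' @export
knock_down <- function(net, phenotype, j) {
  stopifnot(inherits(net, "grn_network"))
  stop_if_not_(j >= 1 && j <= net$p, "invalid gene index")
  if (inherits(phenotype, "expression_state")) phenotype <- phenotype$x
  net$W[j, ] <- net$W[j, ] / 2
  net$ceiling[j] <- net$ceiling[j] / 2
  x0 <- phenotype; x0[j] <- x0[j] / 2
  list(net = net, phenotype = steady_state(net, x0 = x0))
}

#' Assign heterogeneous perturbations to the diseased group
#'
#' Diseased subjects are partitioned into thirds carrying 4, 5 or 6 affected
#' hubs (remainders go to the smaller sizes); each subject's affected subset
#' is drawn uniformly among hub subsets of its size; within each hub's
#' affected subjects, 1/3 are knocked out and 2/3 knocked down (remainders
#' to knock-down).
#'
#' @param n_diseased number of diseased subjects.
#' @param hubs a \code{\link{select_hubs}} result (or vector of hub gene ids).
#' @param sizes affected-subset sizes (default 4, 5, 6).
#' @param seed RNG seed.
#' @return An object of class \code{perturbation_plan}: data.frame with
#'   columns \code{subject}, \code{hub}, \code{type} (\code{"KO"} or
#'   \code{"KD"}).
#' @export
assign_perturbations <- function(n_diseased, hubs, sizes = c(4, 5, 6),
                                 seed = NULL) {
  genes <- if (inherits(hubs, "hub_set")) hubs$gene else as.integer(hubs)
  stop_if_not_(n_diseased >= 0, "n_diseased must be >= 0")
  stop_if_not_(length(genes) >= max(sizes),
               "need at least %d hubs", max(sizes))
  empty <- data.frame(subject = integer(0), hub = integer(0),
                      type = character(0))
  if (n_diseased == 0)
    return(structure(empty, class = c("perturbation_plan", "data.frame")))
  with_seed_(seed, {
    ns <- length(sizes)
    if (n_diseased < ns) {
      warning("fewer diseased subjects than subset sizes; assigning sizes round-robin")
      size_per_subject <- rep_len(sizes, n_diseased)
    } else {
      base <- n_diseased %/% ns
      rem <- n_diseased %% ns
      counts <- rep(base, ns) + as.integer(seq_len(ns) <= rem)  # remainders to smaller sizes
      size_per_subject <- rep(sizes, counts)
    }
    rows <- do.call(rbind, lapply(seq_len(n_diseased), function(s) {
      sub <- if (size_per_subject[s] == length(genes)) genes
             else sample(genes, size_per_subject[s])
      data.frame(subject = s, hub = sub)
    }))
    rows$type <- "KD"
    for (g in genes) {
      aff <- which(rows$hub == g)
      n_ko <- length(aff) %/% 3            # remainders to knock-down
      if (n_ko > 0)
        rows$type[sample(aff, n_ko)] <- "KO"
    }
    rows <- rows[order(rows$subject, rows$hub), ]
    rownames(rows) <- NULL
    structure(rows, class = c("perturbation_plan", "data.frame"))
  })
}

# genes reachable from `from` in the regulation digraph (edge j -> i iff
# W[i, j] != 0), excluding the start set unless reached
reachable_from_ <- function(W, from) {
  adj <- W != 0
  seen <- logical(nrow(W))
  frontier <- from
  repeat {
    nxt <- which(Matrix::rowSums(adj[, frontier, drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Derive the ground-truth biomarker set
#'
#' True biomarkers are the genes directly or indirectly regulated by at
#' least one hub (plus the hubs themselves) whose noise-free steady-state
#' expression changes by more than \code{epsilon} under at least one
#' single-hub knock-out or knock-down of the founder. Per-gene maximum
#' absolute changes are retained for diagnostics.
#'
#' @param founder the founder \code{grn_network}.
#' @param phenotype founder steady state (vector or \code{expression_state}).
#' @param hubs a \code{hub_set} or vector of hub gene ids.
#' @param epsilon minimum absolute change, on the normalised scale, for a
#'   gene to count as modified (default 0.01).
#' @return An object of class \code{biomarker_truth}: list with
#'   \code{genes}, per-candidate \code{change}, \code{epsilon},
#'   \code{hubs}.
#' @export
derive_truth <- function(founder, phenotype, hubs, epsilon = 0.01) {
  stopifnot(inherits(founder, "grn_network"))
  if (inherits(phenotype, "expression_state")) phenotype <- phenotype$x
  genes <- if (inherits(hubs, "hub_set")) hubs$gene else as.integer(hubs)
  candidates <- sort(union(genes, reachable_from_(founder$W, genes)))
  change <- stats::setNames(numeric(length(candidates)), candidates)
  for (h in genes) {
    for (type in c("KO", "KD")) {
      pert <- if (type == "KO") knock_out(founder, phenotype, h)
              else knock_down(founder, phenotype, h)
      delta <- abs(pert$phenotype$x - phenotype)
      change <- pmax(change, delta[candidates])
    }
  }
  structure(list(genes = candidates[change > epsilon],
                 change = change, epsilon = epsilon, hubs = genes),
            class = "biomarker_truth")
}

#' @export
print.biomarker_truth <- function(x, ...) {
  cat(sprintf("Biomarker truth: %d genes (change > %.3g) from %d hubs; %d candidates reachable\n",
              length(x$genes), x$epsilon, length(x$hubs), length(x$change)))
  invisible(x)
}

#' Write the biomarker truth set to plain-text files
#'
#' @param truth a \code{biomarker_truth}.
#' @param genes_path one gene id per line (the truth set).
#' @param changes_path TSV of per-candidate maximum absolute steady-state
#'   changes.
#' @export
write_truth <- function(truth, genes_path, changes_path = NULL) {
  writeLines(as.character(truth$genes), genes_path)
  if (!is.null(changes_path)) {
    d <- data.frame(gene_id = names(truth$change),
                    max_change = format_sig_(truth$change))
    utils::write.table(d, changes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(genes_path)
}

#' Build noise-free case/control cohorts from an evolved population
#'
#' Draws disjoint healthy and diseased subject sets from the population.
#' Healthy subjects contribute their unperturbed steady states; each
#' diseased subject's plan entries (knock-outs and knock-downs of its
#' assigned hubs) are applied jointly to the subject's own evolved network
#' and the steady state recomputed.
#'
#' @param pop a \code{grn_population}.
#' @param plan a \code{\link{assign_perturbations}} plan whose subject
#'   indices run 1..\code{n_diseased}.
#' @param n_healthy,n_diseased group sizes
#'   (\code{n_healthy + n_diseased <= M}).
#' @param seed RNG seed for the subject draw.
#' @return List with matrices \code{healthy}, \code{diseased}
#'   (genes x subjects, noise-free normalised expression) and the drawn
#'   \code{healthy_ids}, \code{diseased_ids}.
#' @export
build_cohorts <- function(pop, plan, n_healthy, n_diseased, seed = NULL) {
  stopifnot(inherits(pop, "grn_population"))
  M <- ncol(pop$values)
  stop_if_not_(n_healthy + n_diseased <= M,
               "population of %d cannot supply %d + %d disjoint subjects",
               M, n_healthy, n_diseased)
  with_seed_(seed, {
    ids <- sample.int(M, n_healthy + n_diseased)
    healthy_ids <- ids[seq_len(n_healthy)]
    diseased_ids <- ids[n_healthy + seq_len(n_diseased)]

    ctx <- founder_context_(pop$founder)
    ev <- ctx$ev
    diseased <- pop$phenotypes[, diseased_ids, drop = FALSE]
    for (s in seq_len(n_diseased)) {
      rows <- plan[plan$subject == s, , drop = FALSE]
      if (nrow(rows) == 0) next
      vals <- pop$values[, diseased_ids[s]]
      ceiling <- ctx$ceiling_ev
      x0 <- pop$phenotypes[ev, diseased_ids[s]]
      clamp <- integer(0)
      for (r in seq_len(nrow(rows))) {
        h_local <- match(rows$hub[r], ev)
        stop_if_not_(!is.na(h_local), "plan hub %d is not evolvable", rows$hub[r])
        in_row <- ctx$li == h_local
        if (rows$type[r] == "KO") {
          vals[in_row] <- 0
          clamp <- c(clamp, h_local)
        } else {
          vals[in_row] <- vals[in_row] / 2
          ceiling[h_local] <- ceiling[h_local] / 2
          x0[h_local] <- x0[h_local] / 2
        }
      }
      st <- block_steady_(ctx, vals, x0 = x0, clamp = clamp,
                          ceiling = ceiling, max_iter = 10000L)
      diseased[ev, s] <- st$x
    }
    list(healthy = pop$phenotypes[, healthy_ids, drop = FALSE],
         diseased = diseased,
         healthy_ids = healthy_ids, diseased_ids = diseased_ids)
  })
}
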