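#' Experiment configuration
#'
#' Full parameterisation of an end-to-end benchmark: simulator scale,
#' disease settings, noise, study design, method roster and seeds. Defaults
#' are a reduced scale (2000 genes, 300-gene evolvable subnetwork, 400
#' subjects, 30 generations, B = 20) that keeps a complete run on a single
#' CPU practical; the full study scale (10000 genes, 900-gene subnetwork,
#' 1000 subjects, 150 generations, B = 100, sizes 50/20/15/10) is reached by
#' overriding the corresponding fields. The evolvable edge count defaults to
#' the full-scale mean degree (1619 edges among 900 genes) scaled
#' proportionally to \code{n_sub}. The hub-eligibility cutoff defaults to
#' 0.75 at this scale: with only 300 evolvable genes the extreme 0.88 tail
#' of the steady-state expression distribution holds too few genes for six
#' hubs to exist reliably, and 0.75 selects about the same top fraction of
#' the evolvable block as 0.88 does among 900 genes (full-scale runs should
#' set \code{expr_min = 0.88}).
#'
#' @param p,n_sub,nnz_sub,hub_exponent topology scale
#'   (see \code{\link{generate_topology}}).
#' @param M,generations,mutation_rate,survival_percentile,theta,n_probe
#'   evolution settings (see \code{\link{evolution_config}}).
#' @param k_hubs,expr_min,epsilon disease settings (see
#'   \code{\link{select_hubs}}, \code{\link{derive_truth}}).
#' @param affected_sizes per-subject affected-hub subset sizes (see
#'   \code{\link{assign_perturbations}}).
#' @param noise_mean,noise_sd lognormal variance moments (see
#'   \code{\link{noise_model}}).
#' @param sizes,n_datasets study design (see \code{\link{study_design}}).
#' @param methods multivariate method roster.
#' @param modes \code{"single"}, \code{"bootstrap"} or both.
#' @param B,test_fraction bootstrap schema.
#' @param sam also run the univariate SAM test?
#' @param sam_fdr,n_perm SAM settings.
#' @param seed master seed; every stage seed derives from it.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(p = 2000, n_sub = 300, nnz_sub = NULL,
                              hub_exponent = 2.3,
                              M = 400, generations = 30,
                              mutation_rate = 0.025,
                              survival_percentile = 99.5,
                              theta = NULL, n_probe = 500,
                              k_hubs = 6, expr_min = 0.75, epsilon = 0.01,
                              affected_sizes = c(4, 5, 6),
                              noise_mean = 0.22, noise_sd = 0.35,
                              sizes = c(10), n_datasets = 10,
                              methods = c("LSVM", "GSVM", "SRDA", "IRELIEF"),
                              modes = c("single", "bootstrap"),
                              B = 20, test_fraction = 1/3,
                              sam = FALSE, sam_fdr = 0.05, n_perm = 200,
                              seed = 1) {
  nnz_sub <- nnz_sub %||% round(1619 / 900 * n_sub)
  structure(as.list(environment()), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(paste0("Benchmark configuration: p = %d (evolvable %d, %d edges), ",
                     "M = %d, %d generations\n"),
              x$p, x$n_sub, x$nnz_sub, x$M, x$generations))
  cat(sprintf("  datasets: %s per group x %d replicates; methods: %s (%s)%s\n",
              paste(x$sizes, collapse = "/"), x$n_datasets,
              paste(x$methods, collapse = ", "),
              paste(x$modes, collapse = "+"),
              if (x$sam) " + SAM" else ""))
  invisible(x)
}

#' Simulate the benchmark population and datasets
#'
#' Runs the simulation half of the pipeline: topology, evolution, hub
#' selection, ground truth, perturbation plan, cohorts, noise and
#' partitioning. Used by \code{\link{run_experiment}} and exposed so the
#' datasets can be reused across method evaluations.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return List with \code{population}, \code{hubs}, \code{truth} (ids on
#'   the \code{g<i>} naming of dataset rows), \code{plan}, \code{datasets}
#'   (per size, a list of \code{expression_dataset}s), \code{variances}.
#' @export
simulate_benchmark <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  founder <- generate_topology(config$p, config$n_sub, config$nnz_sub,
                               hub_exponent = config$hub_exponent,
                               seed = seed + 1)
  pop <- evolve(founder, evolution_config(
    M = config$M, generations = config$generations,
    mutation_rate = config$mutation_rate,
    survival_percentile = config$survival_percentile,
    theta = config$theta, n_probe = config$n_probe, seed = seed + 2))
  hubs <- select_hubs(founder, pop$founder_profile, k = config$k_hubs,
                      expr_min = config$expr_min)
  truth <- derive_truth(founder, pop$founder_profile, hubs,
                        epsilon = config$epsilon)
  n_dis <- config$M %/% 2
  n_heal <- config$M - n_dis
  plan <- assign_perturbations(n_dis, hubs, sizes = config$affected_sizes,
                               seed = seed + 3)
  cohorts <- build_cohorts(pop, plan, n_heal, n_dis, seed = seed + 4)

  clean <- cbind(cohorts$healthy, cohorts$diseased)
  rownames(clean) <- paste0("g", seq_len(config$p))
  colnames(clean) <- c(paste0("h", seq_len(n_heal)),
                       paste0("d", seq_len(n_dis)))
  variances <- sample_gene_variances(config$p,
                                     noise_model(config$noise_mean,
                                                 config$noise_sd),
                                     seed = seed + 5)
  noisy <- add_noise(clean, variances, seed = seed + 6)
  labels <- factor(rep(c("healthy", "diseased"), c(n_heal, n_dis)),
                   levels = c("healthy", "diseased"))

  parts <- partition_cohorts(colnames(noisy)[labels == "healthy"],
                             colnames(noisy)[labels == "diseased"],
                             study_design(config$sizes, config$n_datasets),
                             seed = seed + 7)
  truth_ids <- paste0("g", truth$genes)
  datasets <- lapply(parts, function(size_set) {
    lapply(size_set, function(pt) {
      cols <- c(pt$healthy, pt$diseased)
      expression_dataset(noisy[, cols, drop = FALSE],
                         labels[match(cols, colnames(noisy))],
                         truth = truth_ids,
                         provenance = list(
                           seed = seed,
                           scale = list(p = config$p, n_sub = config$n_sub,
                                        nnz_sub = config$nnz_sub,
                                        M = config$M,
                                        generations = config$generations)))
    })
  })
  list(population = pop, hubs = hubs, truth = truth, truth_ids = truth_ids,
       plan = plan, datasets = datasets, variances = variances,
       config = config)
}

rank_one_ <- function(method, mode, ds, config, seed) {
  x <- ds$x; y <- ds$labels
  spec <- method_spec(method)
  if (mode == "single") {
    tuned <- tune_hyperparams(spec, x, y, seed = seed)
    run <- erfe_rank(tuned, x, y, seed = seed + 1)
  } else {
    run <- bootstrap_rank(spec, x, y, B = config$B,
                          test_fraction = config$test_fraction, seed = seed)
  }
  # both curves are held-out estimates (fold-internal re-ranking for single,
  # external splits for bootstrap), so the MCC at n* is selection-bias free
  run$outer_mcc <- run$mcc[match(run$n_star, run$sizes)]
  run
}

#' Run a full benchmark experiment
#'
#' Executes the whole pipeline: simulate, perturb, partition, rank/select
#' with every (method, mode) combination (and optionally SAM) on every
#' dataset, and score precision, recall, AUPR and MCC against the known
#' ground truth, plus the core-Canberra stability of the selected lists
#' within each size-set. MCC is always estimated on held-out data: mean over
#' the B external test splits for bootstrap runs, repeated outer
#' cross-validation at the chosen size for single runs.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param sim optionally, a precomputed \code{\link{simulate_benchmark}}
#'   result (so several rosters can share one simulation).
#' @param keep_rankings retain the full per-run rankings (memory permitting)?
#' @return An object of class \code{benchmark_result} with data.frames
#'   \code{runs} (one row per method x mode x dataset) and
#'   \code{stability}, plus \code{truth_ids}, \code{hubs} and the config.
#' @export
run_experiment <- function(config, sim = NULL, keep_rankings = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- sim %||% simulate_benchmark(config)
  truth_ids <- sim$truth_ids
  runs <- list()
  stability <- list()
  rankings <- list()
  for (si in seq_along(config$sizes)) {
    size <- config$sizes[si]
    dss <- sim$datasets[[si]]
    for (method in config$methods) {
      for (mode in config$modes) {
        sel_lists <- vector("list", length(dss))
        for (di in seq_along(dss)) {
          seed <- config$seed + 100000L * si + 1000L * di +
            37L * match(method, config$methods) + 7L * match(mode, c("single", "bootstrap"))
          run <- rank_one_(method, mode, dss[[di]], config, seed)
          pr <- precision_recall(run$selected, truth_ids)
          runs[[length(runs) + 1L]] <- data.frame(
            method = method, mode = mode, size = size, dataset = di,
            n_star = run$n_star, n_selected = length(run$selected),
            precision = pr$precision, recall = pr$recall,
            aupr = aupr(run$ranking, truth_ids), mcc = run$outer_mcc)
          sel_lists[[di]] <- run$selected
          if (keep_rankings)
            rankings[[paste(method, mode, size, di, sep = "_")]] <- run$ranking
        }
        stab <- if (length(sel_lists) >= 2)
          stability_indicator(sel_lists, p = config$p, distance = "core")$value
        else NA_real_
        stability[[length(stability) + 1L]] <- data.frame(
          method = method, mode = mode, size = size, stability = stab)
      }
    }
    if (isTRUE(config$sam)) {
      sel_lists <- list()
      for (di in seq_along(dss)) {
        seed <- config$seed + 100000L * si + 1000L * di + 997L
        sr <- sam_test(dss[[di]]$x, dss[[di]]$labels, fdr = config$sam_fdr,
                       n_perm = config$n_perm, seed = seed)
        pr <- precision_recall(sr$selected, truth_ids)
        runs[[length(runs) + 1L]] <- data.frame(
          method = "SAM", mode = "single", size = size, dataset = di,
          n_star = length(sr$selected), n_selected = length(sr$selected),
          precision = pr$precision, recall = pr$recall,
          aupr = aupr(sr$order, truth_ids), mcc = NA_real_)
        if (length(sr$selected) > 0)
          sel_lists[[length(sel_lists) + 1L]] <- sr$selected
      }
      stability[[length(stability) + 1L]] <- data.frame(
        method = "SAM", mode = "single", size = size,
        stability = if (length(sel_lists) >= 2)
          stability_indicator(sel_lists, p = config$p, distance = "core")$value
        else NA_real_)
    }
  }
  structure(list(runs = do.call(rbind, runs),
                 stability = do.call(rbind, stability),
                 truth_ids = truth_ids, hubs = sim$hubs,
                 theta = sim$population$theta,
                 evolution_log = sim$population$log,
                 rankings = if (keep_rankings) rankings else NULL,
                 config = config),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark result: %d runs (%d biomarkers in truth)\n",
              nrow(x$runs), length(x$truth_ids)))
  agg <- stats::aggregate(cbind(precision, aupr, mcc) ~ method + mode + size,
                          data = x$runs, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  print(agg, row.names = FALSE)
  invisible(x)
}

pairable_ <- function(runs, metric, method, size, mode) {
  r <- runs[runs$method == method & runs$size == size & runs$mode == mode, ]
  r[order(r$dataset), metric]
}

#' Statistical comparison of methods
#'
#' Paired Wilcoxon signed-rank tests between each method and its bootstrap
#' variant (alpha = 0.05); a Friedman test across the bootstrap variants
#' (alpha = 0.05) with, when significant, post-hoc pairwise Wilcoxon tests
#' at alpha = 0.05/6; and, when SAM results are present, Wilcoxon tests of
#' SAM against the eight classification variants at alpha = 0.05/8. All
#' tests are paired across common datasets within each sample size.
#'
#' @param result a \code{\link{run_experiment}} result.
#' @param metric one of \code{"mcc"}, \code{"precision"}, \code{"aupr"}.
#' @return List of data.frames: \code{bootstrap_vs_single},
#'   \code{friedman}, \code{posthoc}, \code{sam_vs_rest} (the latter two
#'   possibly empty), each carrying its alpha.
#' @export
compare_methods <- function(result, metric = c("mcc", "precision", "aupr")) {
  metric <- match.arg(metric)
  runs <- result$runs
  methods <- setdiff(unique(runs$method), "SAM")
  sizes <- unique(runs$size)
  wt <- function(a, b) {
    if (all(a == b)) return(1)
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                        exact = FALSE)$p.value)
  }
  bvs <- do.call(rbind, lapply(sizes, function(sz) {
    do.call(rbind, lapply(methods, function(m) {
      a <- pairable_(runs, metric, m, sz, "bootstrap")
      b <- pairable_(runs, metric, m, sz, "single")
      if (!length(a) || length(a) != length(b)) return(NULL)
      data.frame(size = sz, method = m, p_value = wt(a, b),
                 mean_single = mean(b, na.rm = TRUE),
                 mean_bootstrap = mean(a, na.rm = TRUE), alpha = 0.05)
    }))
  }))
  fr <- NULL; ph <- NULL
  for (sz in sizes) {
    mat <- sapply(methods, function(m)
      pairable_(runs, metric, m, sz, "bootstrap"))
    if (!is.matrix(mat) || nrow(mat) < 2 || anyNA(mat)) next
    fr <- rbind(fr, data.frame(
      size = sz, p_value = stats::friedman.test(mat)$p.value, alpha = 0.05))
    cmb <- utils::combn(methods, 2)
    ph <- rbind(ph, do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      data.frame(size = sz, method_a = cmb[1, k], method_b = cmb[2, k],
                 p_value = wt(mat[, cmb[1, k]], mat[, cmb[2, k]]),
                 alpha = 0.05 / 6)
    })))
  }
  sam <- NULL
  if ("SAM" %in% runs$method && metric != "mcc") {
    for (sz in sizes) {
      s <- pairable_(runs, metric, "SAM", sz, "single")
      if (!length(s)) next
      for (m in methods) for (md in intersect(unique(runs$mode), c("single", "bootstrap"))) {
        o <- pairable_(runs, metric, m, sz, md)
        if (length(o) != length(s)) next
        sam <- rbind(sam, data.frame(size = sz, method = paste0(m, if (md == "bootstrap") "_B" else ""),
                                     p_value = wt(s, o), alpha = 0.05 / 8))
      }
    }
  }
  list(bootstrap_vs_single = bvs, friedman = fr, posthoc = ph,
       sam_vs_rest = sam)
}

#' Summary tables of a benchmark result
#'
#' Produces the per-size-per-method MCC table in "mean (min, max)" format,
#' quartile summaries of precision and AUPR, the interquartile range of the
#' number of selected features, and the stability table. Optionally writes
#' them as CSV plus a JSON bundle.
#'
#' @param result a \code{\link{run_experiment}} result.
#' @param dir optional output directory.
#' @return List of data.frames (\code{mcc_table}, \code{precision},
#'   \code{aupr}, \code{selected_iqr}, \code{stability}).
#' @export
summarize_benchmark <- function(result, dir = NULL) {
  runs <- result$runs
  fmt <- function(v) sprintf("%.2f (%.2f, %.2f)", mean(v), min(v), max(v))
  rows <- unique(runs[, c("method", "mode", "size")])
  mcc_table <- cbind(rows, mcc = vapply(seq_len(nrow(rows)), function(k) {
    v <- runs$mcc[runs$method == rows$method[k] & runs$mode == rows$mode[k] &
                    runs$size == rows$size[k]]
    if (all(is.na(v))) NA_character_ else fmt(v[!is.na(v)])
  }, character(1)))
  qsum <- function(metric) {
    cbind(rows, t(vapply(seq_len(nrow(rows)), function(k) {
      v <- runs[[metric]][runs$method == rows$method[k] &
                            runs$mode == rows$mode[k] &
                            runs$size == rows$size[k]]
      stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    }, numeric(3))))
  }
  sel <- cbind(rows, t(vapply(seq_len(nrow(rows)), function(k) {
    v <- runs$n_selected[runs$method == rows$method[k] &
                           runs$mode == rows$mode[k] &
                           runs$size == rows$size[k]]
    stats::quantile(v, c(0.25, 0.75), na.rm = TRUE)
  }, numeric(2))))
  out <- list(mcc_table = mcc_table, precision = qsum("precision"),
              aupr = qsum("aupr"), selected_iqr = sel,
              stability = result$stability)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(out, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
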