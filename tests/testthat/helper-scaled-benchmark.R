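# Reduced-scale benchmark shared by the heavier suites: one simulated
# population (p = 2000, 300-gene evolvable subnetwork, M = 400, 30
# generations), 10 datasets each at 20 and 10 subjects per group, evaluated
# with the four multivariate methods in single and bootstrap (B = 20) mode
# at 10 per group, and with SAM plus a single-mode reference at 20 per
# group. Computed once per session and cached.

.scaled_cache <- new.env(parent = emptyenv())

scaled_benchmark <- function() {
  if (!is.null(.scaled_cache$res)) return(.scaled_cache$res)
  cfg <- experiment_config(sizes = c(20, 10), n_datasets = 10, seed = 101)
  sim <- simulate_benchmark(cfg)
  truth <- sim$truth_ids
  methods <- c("LSVM", "GSVM", "SRDA", "IRELIEF")

  runs <- list()
  sel <- list()   # selected lists per method:mode, for stability
  for (di in 1:10) {
    ds <- sim$datasets$size_10[[di]]
    for (m in methods) {
      seed <- 101 + 1000L * di + match(m, methods)
      sp <- tune_hyperparams(method_spec(m), ds$x, ds$labels, seed = seed)
      single <- erfe_rank(sp, ds$x, ds$labels, seed = seed + 1)
      boot <- bootstrap_rank(method_spec(m), ds$x, ds$labels, B = cfg$B,
                             seed = seed + 2)
      for (mode in c("single", "bootstrap")) {
        run <- if (mode == "single") single else boot
        pr <- precision_recall(run$selected, truth)
        runs[[length(runs) + 1L]] <- data.frame(
          method = m, mode = mode, dataset = di,
          n_star = run$n_star, precision = pr$precision,
          aupr = aupr(run$ranking, truth))
        key <- paste(m, mode, sep = ":")
        sel[[key]] <- c(sel[[key]], list(run$selected))
      }
    }
  }

  lsvm20_sel <- list()
  sam <- list()
  for (di in 1:10) {
    ds <- sim$datasets$size_20[[di]]
    seed <- 90101 + di
    sp <- tune_hyperparams(method_spec("LSVM"), ds$x, ds$labels, seed = seed)
    r20 <- erfe_rank(sp, ds$x, ds$labels, seed = seed + 1)
    lsvm20_sel[[di]] <- r20$selected
    sr <- sam_test(ds$x, ds$labels, fdr = 0.05, n_perm = 200,
                   seed = seed + 2)
    sam[[di]] <- data.frame(
      dataset = di, n_selected = length(sr$selected),
      precision = if (length(sr$selected)) precision_recall(sr$selected, truth)$precision
                  else NA_real_)
  }

  # permuted-label global null at 20 per group
  sam_null <- vapply(1:20, function(r) {
    ds <- sim$datasets$size_20[[(r - 1) %% 10 + 1]]
    y <- withr::with_seed(70000 + r, sample(ds$labels))
    length(sam_test(ds$x, y, fdr = 0.05, n_perm = 200,
                    seed = 70100 + r)$selected)
  }, numeric(1))

  .scaled_cache$res <- list(
    cfg = cfg, truth = truth, p = cfg$p,
    runs = do.call(rbind, runs), sel = sel,
    lsvm20_sel = lsvm20_sel,
    sam = do.call(rbind, sam), sam_null = sam_null)
  .scaled_cache$res
}
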