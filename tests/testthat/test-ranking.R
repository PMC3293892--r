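test_that("every weighting engine puts the informative feature on top", {
  toy <- toy_dataset(p = 50, n = 30, k = 1, shift = 4)
  for (m in c("LSVM", "GSVM", "SRDA", "IRELIEF")) {
    w <- weight_features(method_spec(m), toy$x, toy$y)
    expect_length(w, 50)
    expect_true(all(w >= 0))
    expect_equal(which.max(w), 1L, info = m)
  }
  # I-Relief weights are a probability vector
  wi <- weight_features(method_spec("IRELIEF"), toy$x, toy$y)
  expect_equal(sum(wi), 1, tolerance = 1e-9)

  # duplicated feature columns receive (near-)equal weights
  x2 <- rbind(toy$x, dup = toy$x[1, ])
  for (m in c("LSVM", "SRDA", "IRELIEF")) {
    w <- weight_features(method_spec(m), x2, toy$y)
    expect_equal(w[1], w[51], tolerance = 1e-6, info = m)
  }
})

test_that("hyperparameter tuning minimises CV error with regularisation-first ties", {
  toy <- toy_dataset(p = 20, n = 24, k = 2, shift = 5)
  # single grid point: returned as-is
  sp1 <- method_spec("LSVM", grid = list(c = 2))
  expect_equal(tune_hyperparams(sp1, toy$x, toy$y, seed = 1)$c, 2)
  # separable toy: the tuned model reaches zero CV error somewhere on the grid
  sp <- tune_hyperparams(method_spec("LSVM"), toy$x, toy$y, seed = 1)
  expect_true(sp$tuned)
  expect_equal(min(sp$tuning$cv_error), 0)
  # determinism
  sp2 <- tune_hyperparams(method_spec("LSVM"), toy$x, toy$y, seed = 1)
  expect_identical(sp$c, sp2$c)
  # ties resolved toward the smallest cost
  errs <- sp$tuning$cv_error
  expect_equal(sp$c, min(sp$tuning$c[errs == min(errs)]))
  expect_error(tune_hyperparams(method_spec("LSVM"), toy$x,
                                factor(rep("A", 24))), "two classes")
})

test_that("ERFE returns a complete ranking with the signal on top", {
  toy <- toy_dataset(p = 60, n = 30, k = 3, shift = 4)
  sp <- tune_hyperparams(method_spec("LSVM"), toy$x, toy$y, seed = 1)
  run <- erfe_rank(sp, toy$x, toy$y, seed = 2)
  expect_setequal(run$ranking, rownames(toy$x))      # permutation of all p
  expect_true(all(toy$informative %in% run$ranking[1:6]))
  expect_equal(run$selected, run$ranking[seq_len(run$n_star)])
  expect_equal(min(run$errors, na.rm = TRUE),
               run$errors[match(run$n_star, run$sizes)])

  # agreement with a plain fixed-fraction RFE oracle on the top features
  rfe_oracle <- function(spec, x, y, frac = 0.2) {
    active <- seq_len(nrow(x)); tail_ids <- integer(0)
    while (length(active) > 1) {
      w <- weight_features(spec, x[active, , drop = FALSE], y)
      k <- max(1, floor(frac * length(active)))
      drop <- order(w)[seq_len(k)]
      tail_ids <- c(active[drop[order(-w[drop])]], tail_ids)
      active <- active[-drop]
    }
    rownames(x)[c(active, tail_ids)]
  }
  oracle_top <- rfe_oracle(sp, toy$x, toy$y)[1:10]
  # the informative features agree exactly; the noise tail may shuffle
  expect_true(all(toy$informative %in% oracle_top))
  expect_gte(length(intersect(run$ranking[1:10], oracle_top)), 8)

  # single feature input degenerates gracefully
  one <- erfe_rank(sp, toy$x[1, , drop = FALSE], toy$y, seed = 1)
  expect_equal(one$ranking, "g1")
})

test_that("model-size choice takes the error minimum with parsimony ties", {
  expect_equal(choose_n_features(c(10, 20, 40), c(0.3, 0.1, 0.2)), 20)
  expect_equal(choose_n_features(c(10, 20), c(0.1, 0.1)), 10)
  expect_equal(choose_n_features(c(5, 10, 40), c(0.3, 0.2, 0.1)), 40)
  expect_error(choose_n_features(numeric(0), numeric(0)), "non-empty")
})

test_that("bootstrap ranking aggregates splits reproducibly and finds the signal", {
  toy <- toy_dataset(p = 40, n = 30, k = 2, shift = 5)
  br <- bootstrap_rank(method_spec("LSVM"), toy$x, toy$y, B = 8, seed = 3)
  expect_equal(br$mode, "bootstrap")
  expect_setequal(br$ranking, rownames(toy$x))
  expect_true(all(toy$informative %in% br$ranking[1:5]))
  expect_length(br$errors, length(br$sizes))
  br2 <- bootstrap_rank(method_spec("LSVM"), toy$x, toy$y, B = 8, seed = 3)
  expect_identical(br$ranking, br2$ranking)
  expect_identical(br$n_star, br2$n_star)

  b1 <- bootstrap_rank(method_spec("LSVM"), toy$x, toy$y, B = 1, seed = 5,
                       tune = FALSE)
  expect_setequal(b1$ranking, rownames(toy$x))
})

test_that("ranking runs serialise to rank/weight, error-curve and provenance files", {
  toy <- toy_dataset(p = 20, n = 20, k = 1, shift = 5)
  run <- erfe_rank(method_spec("LSVM"), toy$x, toy$y, seed = 1)
  dir <- tempfile()
  write_ranking_run(run, dir)
  r <- utils::read.table(file.path(dir, "ranking.tsv"), header = TRUE,
                         sep = "\t")
  expect_equal(r$feature_id, run$ranking)
  expect_false(anyNA(r$weight))
  curve <- utils::read.table(file.path(dir, "error_curve.tsv"), header = TRUE,
                             sep = "\t")
  expect_equal(curve$size, run$sizes)
  expect_equal(readLines(file.path(dir, "selected.txt")), run$selected)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$method, "LSVM")
  expect_equal(prov$n_star, run$n_star)
  unlink(dir, recursive = TRUE)
})
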