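test_that("pairing mixes evolvable rows fairly and keeps the background intact", {
  a <- generate_topology(40, 15, 30, seed = 2)
  child <- pair_offspring(a, a, seed = 1)
  expect_equal(as.matrix(child$W), as.matrix(a$W))   # identical parents

  b <- mutate_network(a, subject_rate = 15, seed = 3)$net  # heavily mutated copy
  bg <- setdiff(seq_len(a$p), a$evolvable)
  # restrict the row-origin count to rows where the parents actually differ
  differing <- a$evolvable[vapply(a$evolvable, function(r)
    any(as.numeric(a$W[r, ]) != as.numeric(b$W[r, ])), logical(1))]
  expect_gt(length(differing), 5)
  withr::with_seed(5, {
    fracA <- replicate(300, {
      ch <- pair_offspring(a, b)
      mean(vapply(differing, function(r)
        isTRUE(all.equal(as.numeric(ch$W[r, ]), as.numeric(a$W[r, ]))),
        logical(1)))
    })
  })
  expect_equal(mean(fracA), 0.5, tolerance = 0.05)   # Binomial(n_diff, 1/2)
  ch <- pair_offspring(a, b, seed = 9)
  expect_equal(as.matrix(ch$W[bg, bg]), as.matrix(a$W[bg, bg]))

  bad <- generate_topology(40, 16, 30, seed = 2)
  expect_error(pair_offspring(a, bad), "incompatible")
})

test_that("mutation hits only existing nonzeros at the per-subject rate", {
  net <- generate_topology(40, 20, 30, seed = 1)
  expect_false(mutate_network(net, subject_rate = 0)$mutated)
  expect_identical(mutate_network(net, subject_rate = 0)$net$W, net$W)

  # sparsity pattern never changes
  m <- mutate_network(net, subject_rate = 15, seed = 4)$net
  expect_identical(which(as.matrix(m$W) != 0), which(as.matrix(net$W) != 0))

  # per-subject mutated frequency ~ rate, replacement values ~ N(0, 1)
  withr::with_seed(6, {
    nnz <- net$nnz_evolvable
    hitcounts <- stats::rbinom(1e6, nnz, 0.025 / nnz)
    expect_equal(mean(hitcounts >= 1), 1 - (1 - 0.025 / nnz)^nnz,
                 tolerance = 0.02)
    vals <- replicate(400, {
      mm <- mutate_network(net, subject_rate = 10)
      w <- as.matrix(mm$net$W); w0 <- as.matrix(net$W)
      w[w != w0]
    })
    vals <- unlist(vals)
    expect_gt(length(vals), 1000)
    expect_equal(mean(vals), 0, tolerance = 0.05)
    expect_equal(stats::sd(vals), 1, tolerance = 0.05)
  })
})

test_that("selection keeps exactly the candidates within theta", {
  prof <- rep(0.5, 10)
  ph <- cbind(prof, prof + 0.01, prof + 1)
  expect_equal(select_survivors(ph, prof, 0.5), c(1, 2))
  expect_equal(select_survivors(ph, prof, 1e-9), 1)
})

test_that("threshold calibration is deterministic and percentile-monotone", {
  f <- generate_topology(60, 30, 54, seed = 11)
  t1 <- calibrate_threshold(f, n_probe = 150, seed = 5)
  t2 <- calibrate_threshold(f, n_probe = 150, seed = 5)
  expect_identical(t1, t2)
  t95 <- calibrate_threshold(f, n_probe = 150, percentile = 95, seed = 5)
  expect_gte(t1, t95)
  tmax <- calibrate_threshold(f, n_probe = 150, percentile = 100, seed = 5)
  expect_gte(tmax, t1)
  expect_error(calibrate_threshold(f, n_probe = 150, percentile = 0), "percentile")
})

test_that("evolve maintains population invariants and reproducibility", {
  f <- generate_topology(60, 30, 54, seed = 11)
  cfg <- evolution_config(M = 25, generations = 6, n_probe = 100, seed = 3)
  pop <- evolve(f, cfg)
  expect_equal(ncol(pop$values), 25)
  expect_equal(nrow(pop$log), 6)
  d <- sqrt(colSums((pop$phenotypes - pop$founder_profile)^2))
  expect_true(all(d <= pop$theta + 1e-12))

  pop2 <- evolve(f, cfg)
  expect_equal(pop$values, pop2$values)
  expect_equal(pop$phenotypes, pop2$phenotypes)

  # G = 0 returns the founder population unchanged
  pop0 <- evolve(f, evolution_config(M = 5, generations = 0, n_probe = 100,
                                     seed = 1))
  expect_true(all(pop0$values == pop0$pattern$x))
  expect_equal(pop0$phenotypes[, 1], pop0$founder_profile)

  # subject reconstruction matches the stored genotype
  net5 <- subject_network(pop, 5)
  expect_equal(net5$W[cbind(pop$pattern$i, pop$pattern$j)], pop$values[, 5])
})

test_that("genotype divergence accumulates over generations in expectation", {
  f <- generate_topology(60, 50, 100, seed = 21)
  div_at <- function(G, seed) {
    pop <- evolve(f, evolution_config(M = 20, generations = G,
                                      mutation_rate = 0.4, n_probe = 100,
                                      seed = seed))
    utils::tail(pop$log$n_divergent, 1)
  }
  early <- mean(vapply(1:3, function(s) div_at(2, s), numeric(1)))
  late <- mean(vapply(1:3, function(s) div_at(10, s), numeric(1)))
  expect_gte(late, early)
})

test_that("population serialisation writes the promised artefacts", {
  f <- generate_topology(30, 15, 25, seed = 4)
  pop <- evolve(f, evolution_config(M = 6, generations = 2, n_probe = 100,
                                    seed = 2))
  dir <- tempfile()
  write_population(pop, dir)
  expect_true(file.exists(file.path(dir, "founder_edges.tsv")))
  expect_length(list.files(file.path(dir, "subjects")), 6)
  log <- read.table(file.path(dir, "evolution_log.tsv"), header = TRUE,
                    sep = "\t")
  expect_named(log, c("generation", "n_offspring", "n_mutated",
                      "n_eliminated", "n_divergent"))
  ph <- read.table(file.path(dir, "phenotypes.tsv"), header = TRUE, sep = "\t")
  expect_equal(dim(ph), c(30, 7))
  unlink(dir, recursive = TRUE)
})
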