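test_that("noise model matches the stated lognormal moments", {
  nm <- noise_model()
  # exact moment conversion identities
  expect_equal(nm$meanlog, log(0.22^2 / sqrt(0.22^2 + 0.35^2)), tolerance = 1e-12)
  expect_equal(nm$sdlog, sqrt(log(1 + 0.35^2 / 0.22^2)), tolerance = 1e-12)
  expect_equal(nm$meanlog, -2.1449, tolerance = 1e-4)
  expect_equal(nm$sdlog, 1.1233, tolerance = 1e-4)

  v <- sample_gene_variances(1e5, nm, seed = 1)
  expect_true(all(v > 0))
  expect_equal(mean(v), 0.22, tolerance = 0.02)
  expect_equal(stats::sd(v), 0.35, tolerance = 0.03)

  # degenerate spread collapses to the mean
  tight <- sample_gene_variances(100, noise_model(0.22, 1e-8), seed = 1)
  expect_equal(tight, rep(0.22, 100), tolerance = 1e-4)
})

test_that("additive noise has the configured gene-wise spread and zero mean", {
  x <- matrix(0.5, nrow = 3, ncol = 1e4)
  v <- c(0.0, 0.1, 0.5)
  noisy <- add_noise(x, v, seed = 2)
  expect_equal(noisy[1, ], x[1, ])                  # zero variance: unchanged
  expect_equal(apply(noisy - x, 1, stats::sd), sqrt(v), tolerance = 0.03)
  expect_equal(rowMeans(noisy), rowMeans(x), tolerance = 0.02)  # unbiased
  expect_error(add_noise(x, c(1, 2)), "feature count")

  clipped <- add_noise(matrix(0.01, 2, 1000), c(0.5, 0.5), seed = 3,
                       clip_negative = TRUE)
  expect_true(all(clipped >= 0))
})

test_that("partitioning yields balanced, disjoint, capacity-checked datasets", {
  h <- paste0("h", 1:500); d <- paste0("d", 1:500)
  parts <- partition_cohorts(h, d, study_design(c(50, 10), 10), seed = 4)
  # 10 x 50 uses every subject of each class exactly once
  all50 <- unlist(lapply(parts$size_50, `[[`, "healthy"))
  expect_setequal(all50, h)
  expect_equal(anyDuplicated(all50), 0)
  # size 10: 100 distinct subjects per class, no reuse
  all10 <- unlist(lapply(parts$size_10, function(p) c(p$healthy, p$diseased)))
  expect_equal(anyDuplicated(all10), 0)
  expect_length(all10, 200)
  for (p in parts$size_10) {
    expect_length(p$healthy, 10)
    expect_length(p$diseased, 10)
  }
  expect_error(partition_cohorts(h, d, study_design(50, 11)), "size-set 50")
})

test_that("dataset serialisation round-trips and validates its inputs", {
  withr::with_seed(5, {
    x <- matrix(rnorm(30), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  })
  ds <- expression_dataset(x, rep(c("healthy", "diseased"), each = 3),
                           truth = c("g2", "g4"),
                           provenance = list(seed = 5))
  dir <- tempfile()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$x, ds$x, tolerance = 1e-11)
  expect_identical(as.character(back$labels), as.character(ds$labels))
  expect_identical(back$truth, ds$truth)

  # duplicated feature id is rejected with a line number
  lines <- readLines(file.path(dir, "expression.tsv"))
  writeLines(c(lines, lines[2]), file.path(dir, "expression.tsv"))
  expect_error(read_dataset(dir), "duplicated feature id")
  writeLines(lines, file.path(dir, "expression.tsv"))

  # missing label entry is rejected
  lab <- utils::read.table(file.path(dir, "labels.tsv"), header = TRUE,
                           sep = "\t")
  utils::write.table(lab[-2, ], file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(dir), "no label entry")
  unlink(dir, recursive = TRUE)

  expect_error(expression_dataset(x, rep("a", 6)), "two classes")
  expect_error(expression_dataset(matrix(c(1, Inf), 1, 2), c("a", "b")),
               "non-finite")
})
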