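test_that("full-list Canberra distance matches hand-evaluated cases", {
  expect_equal(canberra_full(1:5, 1:5), 0)
  expect_equal(canberra_full(c(1, 2), c(2, 1)), 2 / 3)
  expect_equal(canberra_full(c(1, 2, 3), c(2, 1, 3)), 2 / 3)
  # symmetry on random permutation pairs
  withr::with_seed(11, {
    for (r in 1:5) {
      a <- sample(20); b <- sample(20)
      expect_equal(canberra_full(a, b), canberra_full(b, a))
    }
  })
  expect_error(canberra_full(1:3, c(1, 2, 4)), "universe")
})

test_that("partial-list distances match exhaustive enumeration for p <= 6", {
  withr::with_seed(21, {
    cases <- list()
    for (p in 3:6) for (r in 1:6) {
      l1 <- sample(0:p, 1); l2 <- sample(0:p, 1)
      cases[[length(cases) + 1]] <- list(
        p = p,
        t1 = if (l1 > 0) sample(p, l1) else integer(0),
        t2 = if (l2 > 0) sample(p, l2) else integer(0))
    }
  })
  for (cs in cases) {
    expect_equal(canberra_partial(cs$t1, cs$t2, cs$p, type = "complete"),
                 brute_partial_canberra(cs$t1, cs$t2, cs$p, core = FALSE),
                 tolerance = 1e-9)
    expect_equal(canberra_partial(cs$t1, cs$t2, cs$p, type = "core"),
                 brute_partial_canberra(cs$t1, cs$t2, cs$p, core = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("partial distances degenerate to the full distance and core <= complete", {
  withr::with_seed(31, {
    a <- sample(8); b <- sample(8)
    expect_equal(canberra_partial(a, b, 8, "complete"), canberra_full(a, b))
    expect_equal(canberra_partial(a, b, 8, "core"), canberra_full(a, b))
    for (r in 1:100) {
      p <- sample(5:30, 1)
      t1 <- sample(p, sample(p, 1)); t2 <- sample(p, sample(p, 1))
      expect_lte(canberra_partial(t1, t2, p, "core"),
                 canberra_partial(t1, t2, p, "complete") + 1e-12)
    }
  })
  # identical top-2 lists are closer than disjoint top-2 lists
  expect_lt(canberra_partial(c(1, 2), c(1, 2), 4, "complete"),
            canberra_partial(c(1, 2), c(3, 4), 4, "complete"))
})

test_that("expected Canberra distance is exact at small p and ~0.3863 p asymptotically", {
  expect_equal(expected_canberra(1), 0)
  # p = 2: the four ordered permutation pairs give {0, 2/3, 2/3, 0}
  expect_equal(expected_canberra(2), 1 / 3)
  # direct O(p^2) definition at p = 7
  p <- 7
  expect_equal(expected_canberra(p),
               sum(abs(outer(1:p, 1:p, "-")) / outer(1:p, 1:p, "+")) / p)
  expect_equal(expected_canberra(1000) / 1000, 2 * log(2) - 1,
               tolerance = 2e-3)
})

test_that("stability indicator is 0 for identical lists, ~1 for random, <= 1.4 always", {
  ls <- replicate(4, 1:50, simplify = FALSE)
  expect_equal(stability_indicator(ls, 50)$value, 0)
  withr::with_seed(41, {
    rnd <- lapply(1:60, function(i) sample(300))
    v <- stability_indicator(rnd, 300)$value
    expect_lt(abs(v - 1), 0.05)
    # reversal is the unstable extreme, still below the 1.4 cap
    expect_lte(canberra_full(1:2000, 2000:1) / expected_canberra(2000), 1.4)
    for (r in 1:50) {
      d <- canberra_full(sample(500), sample(500)) / expected_canberra(500)
      expect_lte(d, 1.4)
    }
  })
  expect_error(stability_indicator(list(1:5), 5), "two lists")
})

test_that("MCC follows the confusion-matrix formula with safe degenerate cases", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(40, 35, 15, 10), 1250 / sqrt(55 * 50 * 45 * 50))
  expect_equal(mcc(0, 0, 10, 10), -1) # perfectly wrong
  expect_equal(mcc(20, 0, 20, 0), 0)  # all predicted one class: 0 by convention
  withr::with_seed(51, {
    for (r in 1:200) {
      cm <- rpois(4, 8)
      m <- mcc(cm[1], cm[2], cm[3], cm[4])
      expect_true(m >= -1 && m <= 1)
      # class-label swap invariance
      expect_equal(m, mcc(cm[2], cm[1], cm[4], cm[3]))
      # cross-check against the Pearson correlation formulation
      truth <- rep(c(1, 0, 0, 1), cm)
      pred <- rep(c(1, 0, 1, 0), cm)
      if (stats::sd(truth) > 0 && stats::sd(pred) > 0)
        expect_equal(m, stats::cor(truth, pred), tolerance = 1e-9)
    }
  })
})

test_that("precision/recall and AUPR follow their definitions", {
  tr <- paste0("g", 1:155)
  pr <- precision_recall(paste0("g", 1:50), tr)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 50 / 155)
  sel <- c(paste0("g", 1:40), paste0("x", 1:10))
  pr <- precision_recall(sel, tr)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 40 / 155)
  pr0 <- precision_recall(character(0), tr)
  expect_equal(pr0$precision, 0)
  expect_true(pr0$empty_selection)

  u <- paste0("g", 1:200); truth <- paste0("g", 1:20)
  expect_equal(aupr(u, truth), 1)          # truth ranked first
  expect_lt(aupr(rev(u), truth), 1)        # reversal strictly worse
  withr::with_seed(61, {
    # uniformly random ranking scores near the prevalence (155/10000)
    ub <- paste0("g", 1:10000); tb <- paste0("g", 1:155)
    rnd <- mean(replicate(20, aupr(sample(ub), tb)))
    expect_lt(abs(rnd - 155 / 10000), 0.002)
  })
  expect_error(aupr(u, character(0)), "empty")
})
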