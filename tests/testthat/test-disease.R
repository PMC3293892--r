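test_that("hub selection filters by expression and ranks by out-degree with tie-breaks", {
  # gene 1 regulates 5 targets, gene 2 regulates 3, gene 3 regulates 1
  W <- matrix(0, 9, 9)
  W[2:6, 1] <- 1; W[7:9, 2] <- 1; W[4, 3] <- 1
  net <- grn_network(W, evolvable = 1:9)
  expr <- rep(0.9, 9)
  hubs <- select_hubs(net, expr, k = 2, expr_min = 0.88)
  expect_equal(hubs$gene, c(1, 2))
  expect_equal(hubs$out_degree, c(5, 3))

  expect_equal(nrow(select_hubs(net, expr, k = 0)), 0)

  # out-degree tie broken by higher expression
  W2 <- matrix(0, 12, 12)
  W2[2:6, 1] <- 1; W2[7:11, 12] <- 1
  net2 <- grn_network(W2, evolvable = 1:12)
  expr2 <- rep(0.9, 12); expr2[1] <- 0.95; expr2[12] <- 0.90
  expect_equal(select_hubs(net2, expr2, k = 1)$gene, 1)

  # not enough eligible genes: actionable error
  expect_error(select_hubs(net, rep(0.5, 9), k = 2), "expr_min")
})

test_that("knock-out zeroes inputs and clamps expression; knock-down halves both", {
  net <- chain_network()
  ph <- steady_state(net)
  ko <- knock_out(net, ph, 1)
  expect_equal(as.numeric(ko$net$W[1, ]), rep(0, 3))
  expect_equal(ko$phenotype$x[1], 0)
  # downstream activation chain decreases
  expect_lt(ko$phenotype$x[2], ph$x[2])
  expect_lt(ko$phenotype$x[3], ph$x[3])

  kd <- knock_down(net, ph, 1)
  expect_equal(as.matrix(kd$net$W)[1, ], as.matrix(net$W)[1, ] / 2)
  expect_equal(kd$phenotype$x[1], ph$x[1] / 2, tolerance = 1e-6)
  # knock-down is a milder perturbation than knock-out downstream
  expect_lte(abs(kd$phenotype$x[3] - ph$x[3]),
             abs(ko$phenotype$x[3] - ph$x[3]) + 1e-9)

  # KO of a gene with no outgoing edges leaves the rest untouched
  ko3 <- knock_out(net, ph, 3)
  expect_equal(ko3$phenotype$x[1:2], ph$x[1:2], tolerance = 1e-7)

  # KD of an isolated unregulated gene halves it only
  iso <- grn_network(matrix(0, 3, 3))
  phi <- steady_state(iso)
  kdi <- knock_down(iso, phi, 2)
  expect_equal(kdi$phenotype$x, c(0.5, 0.25, 0.5), tolerance = 1e-6)
})

test_that("perturbation plans meet the stated proportions exactly", {
  plan <- assign_perturbations(300, 1:6, seed = 2)
  per_subject <- table(plan$subject)
  expect_equal(unname(table(factor(per_subject, levels = 4:6))),
               array(c(100L, 100L, 100L)))
  for (g in 1:6) {
    rows <- plan[plan$hub == g, ]
    expect_equal(sum(rows$type == "KO"), nrow(rows) %/% 3)
  }
  expect_true(all(plan$hub %in% 1:6))

  expect_equal(nrow(assign_perturbations(0, 1:6)), 0)
  expect_warning(p2 <- assign_perturbations(2, 1:6, seed = 1), "round-robin")
  expect_equal(unname(table(p2$subject)), array(c(4L, 5L)))
  # remainders go to the smaller sizes
  p301 <- assign_perturbations(301, 1:6, seed = 3)
  expect_equal(sum(table(p301$subject) == 4), 101)

  ident <- assign_perturbations(10, 1:6, seed = 9)
  expect_identical(ident, assign_perturbations(10, 1:6, seed = 9))
})

test_that("ground-truth derivation is reachability plus an effect threshold", {
  tr <- derive_truth(chain_network(), steady_state(chain_network()), hubs = 1,
                     epsilon = 0.01)
  expect_equal(tr$genes, 1:3)
  # epsilon -> Inf empties the truth set
  tr_inf <- derive_truth(chain_network(), steady_state(chain_network()),
                         hubs = 1, epsilon = Inf)
  expect_length(tr_inf$genes, 0)

  # hub reaches B and C but only B moves beyond epsilon
  W <- matrix(0, 3, 3); W[2, 1] <- 4; W[3, 2] <- 0.05
  net <- grn_network(W, evolvable = 1:3)
  ph <- steady_state(net)
  tr2 <- derive_truth(net, ph, hubs = 1, epsilon = 0.05)
  expect_true(all(c(1, 2) %in% tr2$genes))
  expect_false(3 %in% tr2$genes)

  # truth never leaves the hub-reachable set (block separation)
  big <- generate_topology(40, 15, 30, seed = 8)
  phb <- steady_state(big)
  hubs <- select_hubs(big, phb, k = 2, expr_min = 0)
  trb <- derive_truth(big, phb, hubs, epsilon = 1e-4)
  reach <- union(hubs$gene,
                 which(seq_len(big$p) %in% grnbench:::reachable_from_(big$W, hubs$gene)))
  expect_true(all(trb$genes %in% reach))
  expect_true(all(trb$genes %in% big$evolvable))
})

test_that("cohort assembly perturbs only planned subjects and stays in-block", {
  f <- generate_topology(50, 20, 40, seed = 10)
  pop <- evolve(f, evolution_config(M = 20, generations = 3, n_probe = 100,
                                    seed = 4))
  hubs <- select_hubs(f, pop$founder_profile, k = 2, expr_min = 0)
  empty_plan <- assign_perturbations(0, hubs$gene, sizes = c(1, 2), seed = 1)
  ch <- build_cohorts(pop, empty_plan, n_healthy = 5, n_diseased = 5, seed = 2)
  expect_equal(ch$diseased, pop$phenotypes[, ch$diseased_ids])
  expect_length(intersect(ch$healthy_ids, ch$diseased_ids), 0)

  plan <- assign_perturbations(10, hubs$gene, sizes = c(1, 2), seed = 3)
  ch2 <- build_cohorts(pop, plan, n_healthy = 10, n_diseased = 10, seed = 2)
  # all subjects used exactly once when the population is exhausted
  expect_setequal(c(ch2$healthy_ids, ch2$diseased_ids), 1:20)
  # KO'd hubs sit exactly at zero, KD'd at most half their unperturbed value
  for (s in 1:10) {
    rows <- plan[plan$subject == s, ]
    base <- pop$phenotypes[, ch2$diseased_ids[s]]
    for (r in seq_len(nrow(rows))) {
      if (rows$type[r] == "KO") {
        expect_equal(ch2$diseased[rows$hub[r], s], 0)
      } else {
        # halved ceiling caps any KD'd gene at 0.5; the stronger
        # half-of-baseline bound holds when no co-perturbed hub feeds back
        # into this one
        expect_lte(ch2$diseased[rows$hub[r], s], 0.5 + 1e-9)
        if (nrow(rows) == 1 && base[rows$hub[r]] > 0.5)
          expect_lte(ch2$diseased[rows$hub[r], s],
                     base[rows$hub[r]] / 2 + 1e-9)
      }
    }
  }
  # background genes never differ between groups before noise
  bg <- setdiff(seq_len(f$p), f$evolvable)
  expect_equal(ch2$diseased[bg, ], pop$phenotypes[bg, ch2$diseased_ids])

  expect_error(build_cohorts(pop, plan, 15, 15), "disjoint")
})
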