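test_that("doubling a later-step load doubles every predicted collected mass", {
  ds <- scaling_toy(scale = 2)
  rt <- compute_ratios(ds)
  met <- evaluate_decision(ds, rt, process_decision(
    c("S1", "S2"), c("R1", "R2"), c("C1", "C2"), c(1, 1), c(1, 4)))
  cm2 <- ds$records$S2$cm[1, , ]
  pred <- met$collected$S2
  expect_equal(unname(met$LM["S2", ]), unname(2 * ds$records$S2$lm[1, ]))
  nz <- cm2 > 0
  expect_equal(unname(pred[nz] / cm2[nz]), rep(2, sum(nz)), tolerance = 1e-12)
})

test_that("halving a later-step load halves every predicted collected mass", {
  ds <- scaling_toy(scale = 0.5)
  rt <- compute_ratios(ds)
  met <- evaluate_decision(ds, rt, process_decision(
    c("S1", "S2"), c("R1", "R2"), c("C1", "C2"), c(1, 1), c(1, 4)))
  cm2 <- ds$records$S2$cm[1, , ]
  nz <- cm2 > 0
  expect_equal(unname(met$collected$S2[nz] / cm2[nz]), rep(0.5, sum(nz)),
               tolerance = 1e-12)
})

test_that("full recovery over the whole window gives yield 1; clean windows give purity 1", {
  ds <- manual_one_step(lm = c(10, 2), cm = rbind(c(0, 6, 4), c(2, 0, 0)),
                        proteins = c("tgt", "imp"), target = "tgt")
  rt <- compute_ratios(ds)
  full <- evaluate_decision(ds, rt, process_decision("S1", "R1", "C1", 1, 3))
  expect_equal(full$yield, 1)
  # impurity elutes only in T1: pooling T2-T3 is impurity-free
  clean <- evaluate_decision(ds, rt, process_decision("S1", "R1", "C1", 2, 3))
  expect_equal(clean$purity, 1)
  expect_equal(clean$yield, 1)
})

test_that("an empty pool is flagged instead of reporting a 0/0 purity", {
  ds <- manual_one_step(lm = 10, cm = c(0, 5, 3, 0))
  rt <- compute_ratios(ds)
  met <- evaluate_decision(ds, rt, process_decision("S1", "R1", "C1", 4, 4))
  expect_true(met$empty_collection)
  expect_true(is.na(met$purity))
  expect_equal(met$yield, 0)
})

test_that("decisions violating salt linking or naming unknown tuples are rejected", {
  ds <- generate_hts(small_two_step_spec(6))
  rt <- compute_ratios(ds)
  # step A finish at max salt (200 mM), step B start at 0 mM: must fail
  d <- process_decision(c("A", "B"),
                        c(ds$records$A$combos$resin[1], ds$records$B$combos$resin[1]),
                        c(ds$records$A$combos$condition[1], ds$records$B$combos$condition[1]),
                        c(7, 1), c(7, 6))
  expect_error(evaluate_decision(ds, rt, d), "salt linking")
  d2 <- process_decision(c("A", "B"), c("R-missing", ds$records$B$combos$resin[1]),
                         c("C1", ds$records$B$combos$condition[1]), c(1, 1), c(1, 6))
  expect_error(evaluate_decision(ds, rt, d2), "not in the dataset")
  d3 <- process_decision("A", ds$records$A$combos$resin[1],
                         ds$records$A$combos$condition[1], 3, 2)
  expect_error(evaluate_decision(subset_steps(ds, "A"), rt["A"], d3), "window")
})

test_that("yield and purity are invariant to a common scaling of the first-step experiment", {
  ds <- generate_hts(small_two_step_spec(12))
  rt <- compute_ratios(ds)
  d <- process_decision(c("A", "B"),
                        c(ds$records$A$combos$resin[2], ds$records$B$combos$resin[1]),
                        c(ds$records$A$combos$condition[2], ds$records$B$combos$condition[1]),
                        c(2, 3), c(4, 5))
  base <- evaluate_decision(ds, rt, d)
  scaled <- ds
  scaled$records$A$lm <- scaled$records$A$lm * 3
  scaled$records$A$cm <- scaled$records$A$cm * 3
  met <- evaluate_decision(scaled, compute_ratios(scaled), d)
  expect_equal(met$yield, base$yield, tolerance = 1e-12)
  expect_equal(met$purity, base$purity, tolerance = 1e-12)
})
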