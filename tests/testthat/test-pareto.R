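test_that("dominance filtering matches the quadratic reference on random clouds", {
  set.seed(421)
  for (rep in 1:1000) {
    n <- sample(2:40, 1)
    pts <- data.frame(yield = round(stats::runif(n), sample(1:3, 1)),
                      purity = round(stats::runif(n), sample(1:3, 1)))
    got <- filter_dominated(pts)
    keep <- brute_force_front(pts$yield, pts$purity)
    ref <- unique(pts[keep, c("yield", "purity")])
    ref <- ref[order(ref$purity, -ref$yield), ]
    expect_identical(unname(as.matrix(got[, c("yield", "purity")])),
                     unname(as.matrix(ref)))
  }
})

test_that("hand-picked dominance cases behave as documented", {
  a <- data.frame(yield = c(0.9, 0.9), purity = c(0.90, 0.92))
  expect_equal(filter_dominated(a)$purity, 0.92)
  b <- data.frame(yield = c(0.966, 0.859), purity = c(0.913, 0.924))
  expect_equal(nrow(filter_dominated(b)), 2L)   # trade-off pair coexists
  d <- data.frame(yield = c(0.5, 0.5), purity = c(0.9, 0.9))
  expect_equal(nrow(filter_dominated(d)), 1L)   # duplicates collapse
})

test_that("the epsilon sweep honors its contract on the default grid", {
  ds <- generate_hts(small_two_step_spec(14))
  rt <- compute_ratios(ds)
  grid <- seq(0.90, 0.99, by = 0.01)
  expect_length(grid, 10L)
  front <- sweep_pareto(ds, rt, grid)
  expect_lte(nrow(front), 10L)
  for (k in seq_len(nrow(front)))
    expect_gte(front$purity[k], front$eps[k] - 1e-9)
  expect_true(all(diff(front$purity) >= 0))
  expect_true(all(diff(front$yield) <= 1e-12))
  # points reproduce their own forward simulation
  for (k in seq_len(nrow(front))) {
    met <- evaluate_decision(ds, rt, front$decision[[k]])
    expect_equal(front$yield[k], met$yield, tolerance = 1e-12)
    expect_equal(front$purity[k], met$purity, tolerance = 1e-12)
  }
  # infeasible floors are recorded, not silently dropped
  dsi <- manual_one_step(lm = c(10, 5), cm = rbind(c(4, 4), c(2, 2)),
                         proteins = c("tgt", "imp"), target = "tgt")
  high <- sweep_pareto(dsi, compute_ratios(dsi), c(0.5, 1))
  expect_identical(attr(high, "infeasible_eps"), 1)
  expect_equal(nrow(high), 1L)
})

test_that("refining the grid never loses a nondominated pair already found", {
  ds <- generate_hts(small_two_step_spec(15))
  rt <- compute_ratios(ds)
  coarse <- sweep_pareto(ds, rt, c(0.80, 0.90))
  fine <- sweep_pareto(ds, rt, c(0.80, 0.85, 0.90, 0.95))
  for (k in seq_len(nrow(coarse))) {
    covered <- any(fine$yield >= coarse$yield[k] - 1e-9 &
                   fine$purity >= coarse$purity[k] - 1e-9)
    expect_true(covered)
  }
})

test_that("single-step mode drops linking; integrated mode enforces it", {
  ds <- generate_hts(small_two_step_spec(16))
  single <- run_mode(ds, "single:A", eps_grid = c(0.7, 0.8))
  expect_identical(attr(single, "dataset")$steps, "A")
  expect_error(run_mode(ds, "single:zz"), "unknown step")
  integ <- run_mode(ds, "integrated", eps_grid = c(0.7, 0.8))
  for (k in seq_len(nrow(integ))) {
    d <- integ$decision[[k]]
    sA <- effective_salt(ds$gradients$A); sB <- effective_salt(ds$gradients$B)
    expect_lte(sA[d$finish[1]], sB[d$start[2]] + 1e-9)
  }
  # a two-step train can only lose target mass relative to its first step
  if (nrow(integ) && nrow(single)) {
    pA <- max(single$purity)
    comparable <- integ[integ$purity <= pA + 1e-9, ]
    if (nrow(comparable))
      expect_lte(max(comparable$yield), max(single$yield) + 1e-9)
  }
})

test_that("sweep equals the oracle frontier restricted to the grid", {
  ds <- generate_hts(small_two_step_spec(18))
  rt <- compute_ratios(ds)
  grid <- c(0.5, 0.7, 0.9, 0.95)
  front <- sweep_pareto(ds, rt, grid)
  exact <- oracle_pareto(ds, rt)
  for (k in seq_len(nrow(front))) {
    # every sweep point must be on (or dominated-equal to) the exact front
    hit <- any(abs(exact$yield - front$yield[k]) < 1e-9 &
               abs(exact$purity - front$purity[k]) < 1e-9)
    expect_true(hit)
    # and must equal the oracle's constrained optimum at its floor
    o <- oracle_max_yield(ds, rt, front$eps[k])
    expect_equal(front$yield[k], o$metrics$yield, tolerance = 1e-9)
  }
})
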