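test_that("constraint family counts follow from the index-set sizes", {
  ds <- generate_hts(small_two_step_spec(1))
  rt <- compute_ratios(ds)
  m <- build_model(ds, rt, eps = 0.9, f = 0.3)
  fam <- constraint_families(m)
  np <- 3; nrc <- c(4, 2); Tn <- c(7, 6)
  expect_equal(unname(fam["select_one"]), 2)
  expect_equal(unname(fam["one_start"]), 2)
  expect_equal(unname(fam["one_finish"]), 2)
  expect_equal(unname(fam["window"]), sum(Tn))
  expect_equal(unname(fam["gate_w_x"]), sum(Tn))
  expect_equal(unname(fam["gate_w_z"]), sum(nrc))
  expect_equal(unname(fam["gate_w_on"]), sum(nrc * Tn))   # one row per (s,r,c,t)
  expect_equal(unname(fam["load_first"]), np)
  expect_equal(unname(fam["collect_first"]), nrc[1] * np * Tn[1])
  expect_equal(unname(fam["ratio_ub"]), nrc[2] * np * Tn[2])
  expect_equal(unname(fam["ratio_lb"]), nrc[2] * np * Tn[2])
  expect_equal(unname(fam["ratio_gate"]), nrc[2] * np * Tn[2])
  expect_equal(unname(fam["pool"]), 2 * np)
  expect_equal(unname(fam["carry"]), np)                  # only s < last
  expect_equal(unname(fam["salt_link"]), 1)
  expect_equal(unname(fam["purity"]), 1)
})

test_that("a single-step model carries no linking or ratio-prediction rows", {
  ds <- manual_one_step(lm = c(10, 2), cm = rbind(c(0, 6, 4), c(2, 0, 0)),
                        proteins = c("tgt", "imp"), target = "tgt")
  m <- build_model(ds, compute_ratios(ds), eps = 0.5)
  fam <- constraint_families(m)
  expect_false(any(c("carry", "salt_link", "ratio_ub", "ratio_lb", "ratio_gate")
                   %in% names(fam)))
  expect_error(build_model(ds, compute_ratios(ds), eps = 1.2), "eps")
})

test_that("big-M bounds dominate every mass the oracle ever observes", {
  ds <- generate_hts(small_two_step_spec(3))
  rt <- compute_ratios(ds)
  pol <- default_bigm(ds, rt)
  # one protein loaded at a constant mass: its bound is that mass at every step
  expect_equal(unname(pol$U_LM[, "tgt"]), rep(max(ds$records$A$lm[, "tgt"]), 2))
  maxLM <- matrix(0, 2, 3, dimnames = dimnames(pol$U_LM))
  for (d in enumerate_decisions(ds)) {
    met <- evaluate_decision(ds, rt, d)
    maxLM <- pmax(maxLM, met$LM)
  }
  expect_true(all(pol$U_LM >= maxLM - 1e-12))
})

test_that("a zero calibration ratio forces zero predicted mass", {
  ds <- scaling_toy(scale = 1)
  rt <- compute_ratios(ds)
  expect_equal(rt$S2[1, 1, 1], 0)   # target absent from interval 1
  m <- build_model(ds, rt, eps = 0)
  id <- var_id(m, "M|S2|1|1|1")
  expect_equal(m$ub[id], 0)
})

test_that("shrinking a big-M bound below the observed maximum degrades the optimum", {
  ds <- scaling_toy(scale = 2)    # later-step load is twice the calibration
  rt <- compute_ratios(ds)
  good <- solve_milfp(ds, rt, 0)
  pol <- default_bigm(ds, rt)
  pol$U_LM["S2", ] <- pol$U_LM["S2", ] / 4   # below the true 2 * lm2 load
  m <- build_model(ds, rt, eps = 0, f = 0, policy = pol)
  sol <- solve_milp(m)
  # an undersized bound either caps the pooled mass below the true optimum
  # or (because the lower big-M row no longer relaxes) kills feasibility
  if (sol$status == "optimal") {
    expect_lt(sol$objective / attr(m, "mass_scale"),
              good$metrics$CM["S2", "tgt"] - 1e-9)
  } else {
    expect_identical(sol$status, "infeasible")
  }
})

test_that("fixing a decision in the MILP reproduces the forward simulation", {
  ds <- generate_hts(small_two_step_spec(5))
  rt <- compute_ratios(ds)
  d <- process_decision(c("A", "B"),
                        c(ds$records$A$combos$resin[3], ds$records$B$combos$resin[2]),
                        c(ds$records$A$combos$condition[3], ds$records$B$combos$condition[2]),
                        c(2, 3), c(4, 5))   # A ends at 80 mM, B starts at 100 mM
  met <- evaluate_decision(ds, rt, d)
  m <- build_model(ds, rt, eps = 0)
  for (k in 1:2) {
    s <- ds$steps[k]
    rec <- ds$records[[s]]
    i <- which(rec$combos$resin == d$resin[k] & rec$combos$condition == d$condition[k])
    nrc <- nrow(rec$combos); Tn <- nrow(ds$gradients[[s]])
    fix_vars(m, paste("Z", s, seq_len(nrc), sep = "|"),
             as.numeric(seq_len(nrc) == i))
    fix_vars(m, paste("Xs", s, seq_len(Tn), sep = "|"),
             as.numeric(seq_len(Tn) == d$start[k]))
    fix_vars(m, paste("Xf", s, seq_len(Tn), sep = "|"),
             as.numeric(seq_len(Tn) == d$finish[k]))
  }
  sol <- solve_milp(m)
  expect_identical(sol$status, "optimal")
  v <- sol$values / attr(m, "mass_scale")   # mass variables are rescaled internally
  for (k in 1:2) for (p in 1:3) {
    s <- ds$steps[k]
    expect_equal(unname(v[paste("LM", s, p, sep = "|")]), unname(met$LM[k, p]),
                 tolerance = 1e-8)
    expect_equal(unname(v[paste("CM", s, p, sep = "|")]), unname(met$CM[k, p]),
                 tolerance = 1e-8)
  }
})

test_that("feasible fixings select one contiguous window with W = X * Z (exhaustive, small T)", {
  ds <- manual_one_step(lm = c(10, 2), cm = rbind(c(0, 3, 4, 1), c(1, 0.5, 0, 0.2)),
                        proteins = c("tgt", "imp"), target = "tgt")
  ds$records$S1$combos <- data.frame(resin = c("R1", "R1"), condition = c("C1", "C2"))
  ds$records$S1$lm <- rbind(ds$records$S1$lm, ds$records$S1$lm)
  ds$records$S1$cm <- array(rep(ds$records$S1$cm, each = 2) *
                              rep(c(1, 0.8), 2 * 4), c(2, 2, 4))
  validate_hts_dataset(ds)
  rt <- compute_ratios(ds)
  Tn <- 4
  for (i in 1:2) for (t1 in 1:Tn) for (t2 in 1:Tn) {
    m <- build_model(ds, rt, eps = 0)
    fix_vars(m, paste("Z", "S1", 1:2, sep = "|"), as.numeric(1:2 == i))
    fix_vars(m, paste("Xs", "S1", 1:Tn, sep = "|"), as.numeric(1:Tn == t1))
    fix_vars(m, paste("Xf", "S1", 1:Tn, sep = "|"), as.numeric(1:Tn == t2))
    sol <- solve_milp(m)
    if (t1 > t2) {
      expect_identical(sol$status, "infeasible")
    } else {
      expect_identical(sol$status, "optimal")
      x <- round(sol$values[paste("X", "S1", 1:Tn, sep = "|")])
      expect_equal(unname(x), as.numeric(1:Tn %in% t1:t2))  # contiguous block
      for (ii in 1:2) {
        w <- round(sol$values[paste("W", "S1", ii, 1:Tn, sep = "|")])
        expect_equal(unname(w), unname(x * as.numeric(ii == i)))  # W = X * Z
      }
    }
  }
})

test_that("salt linking admits exactly the non-decreasing cut-point pairs (exhaustive)", {
  # step 1 salts 0/50/100, step 2 salts 0/60/120 (single combos, T = 3)
  proteins <- "p"
  mk <- function(salts, cm) list(
    combos = data.frame(resin = "R", condition = "C"),
    lm = matrix(10, 1, 1, dimnames = list(NULL, proteins)),
    cm = array(cm, c(1, 1, 3)))
  ds <- hts_dataset(c("S1", "S2"), proteins, "p",
                    list(S1 = gradient_schedule(rep("elution", 3), c(0, 50, 100)),
                         S2 = gradient_schedule(rep("elution", 3), c(0, 60, 120))),
                    list(S1 = mk(NULL, c(2, 3, 4)), S2 = mk(NULL, c(1, 2, 3))))
  rt <- compute_ratios(ds)
  s1 <- c(0, 50, 100); s2 <- c(0, 60, 120)
  for (t1 in 1:3) for (t2 in 1:3) {
    m <- build_model(ds, rt, eps = 0)
    fix_vars(m, paste("Xs", "S1", 1:3, sep = "|"), as.numeric(1:3 == t1))
    fix_vars(m, paste("Xf", "S1", 1:3, sep = "|"), as.numeric(1:3 == t1))
    fix_vars(m, paste("Xs", "S2", 1:3, sep = "|"), as.numeric(1:3 == t2))
    fix_vars(m, paste("Xf", "S2", 1:3, sep = "|"), as.numeric(1:3 == t2))
    sol <- solve_milp(m)
    expect_identical(sol$status,
                     if (s1[t1] <= s2[t2]) "optimal" else "infeasible")
  }
})
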