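test_that("gradient schedules enforce phase order and gradient monotonicity", {
  expect_silent(gradient_schedule(c("load", "wash", "elution"), c(NA, NA, 0)))
  expect_error(gradient_schedule(c("wash", "load"), c(NA, NA)), "order")
  expect_error(gradient_schedule(c("elution", "elution"), c(100, 50)),
               "non-decreasing")
  expect_error(gradient_schedule(c("elution"), NA), "elution")
  expect_error(gradient_schedule("elution", -5), "non-negative")
})

test_that("effective salt resolves undefined entries: 0 before the gradient, carry-forward after", {
  cex <- effective_salt(default_gradient("CEX"))
  expect_equal(unname(cex[1:4]), c(0, 0, 0, 0))
  expect_equal(unname(cex[16:17]), c(300, 300))
  mm <- effective_salt(default_gradient("MM"))
  expect_equal(unname(mm[28:29]), c(1000, 1000))  # regeneration carries 1000
  # fully defined all-elution schedule passes through unchanged
  g <- gradient_schedule(rep("elution", 4), c(10, 20, 30, 40))
  expect_equal(unname(effective_salt(g)), c(10, 20, 30, 40))
  # non-decreasing over load + wash + elution
  sub <- cex[default_gradient("CEX")$phase != "regeneration"]
  expect_false(is.unsorted(sub))
})

test_that("dataset validation rejects mass creation, missing records and shape mismatches", {
  expect_error(manual_one_step(lm = 10, cm = c(6, 5, 0)), "exceeds loaded")
  expect_error(manual_one_step(lm = 0, cm = c(0, 0, 0)), "> 0")
  expect_error(manual_one_step(lm = 10, cm = c(0, -1, 0)), "negative")
  ds <- manual_one_step(lm = 10, cm = c(0, 5, 3))
  bad <- ds
  bad$records$S1$cm <- bad$records$S1$cm[, , 1:2, drop = FALSE]
  expect_error(validate_hts_dataset(bad), "interval count")
  dup <- ds
  dup$records$S1$combos <- rbind(dup$records$S1$combos, dup$records$S1$combos)
  expect_error(validate_hts_dataset(dup), "lm must be|duplicated")
})

test_that("load-collection ratios divide collected by loaded mass elementwise", {
  ds <- manual_one_step(lm = 10, cm = c(0, 5, 3, 0))
  rt <- compute_ratios(ds)
  expect_equal(as.vector(rt$S1), c(0, 0.5, 0.3, 0))
  ds0 <- manual_one_step(lm = 7, cm = c(0, 0, 0))
  expect_equal(as.vector(compute_ratios(ds0)$S1), c(0, 0, 0))
})

test_that("ratios recover the collected-mass table exactly (round trip) and stay in [0,1]", {
  for (seed in 1:4) {
    ds <- generate_hts(small_two_step_spec(seed))
    rt <- compute_ratios(ds)
    for (s in ds$steps) {
      lcr <- rt[[s]]
      expect_true(all(lcr >= 0 & lcr <= 1))
      sums <- apply(lcr, c(1, 2), sum)
      expect_true(all(sums <= 1 + 1e-12))
      rebuilt <- lcr * array(ds$records[[s]]$lm, dim = dim(lcr))
      expect_equal(rebuilt, ds$records[[s]]$cm, tolerance = 1e-12)
    }
  }
})

test_that("CSV round trip preserves every mass, gradient and identity", {
  ds <- generate_hts(small_two_step_spec(11))
  dir <- withr::local_tempdir()
  write_hts_dataset(ds, dir)
  ds2 <- read_hts_dataset(dir)
  expect_same_masses(ds, ds2)
  # a second write/read cycle is a fixed point
  dir2 <- withr::local_tempdir()
  write_hts_dataset(ds2, dir2)
  ds3 <- read_hts_dataset(dir2)
  expect_identical(ds2$proteins, ds3$proteins)
  expect_same_masses(ds2, ds3)
})

test_that("reading rejects files that violate the schema", {
  ds <- generate_hts(small_two_step_spec(3))
  dir <- withr::local_tempdir()
  write_hts_dataset(ds, dir)
  cond <- utils::read.csv(file.path(dir, "conditions.csv"))
  utils::write.csv(cond[-1, ], file.path(dir, "conditions.csv"), row.names = FALSE)
  expect_error(read_hts_dataset(dir), "missing loaded mass")
  utils::write.csv(cond, file.path(dir, "conditions.csv"), row.names = FALSE)
  coll <- utils::read.csv(file.path(dir, "collected.csv"))
  coll$collected_mass_mg[1] <- 1e6
  utils::write.csv(coll, file.path(dir, "collected.csv"), row.names = FALSE)
  expect_error(read_hts_dataset(dir), "exceeds loaded")
})

test_that("paper-shaped files load with the documented cardinalities", {
  ds <- generate_hts(preset_cex_mm(seed = 1))
  dir <- withr::local_tempdir()
  write_hts_dataset(ds, dir)
  ds2 <- read_hts_dataset(dir)
  expect_identical(ds2$steps, c("CEX", "MM"))
  expect_equal(length(unique(ds2$records$CEX$combos$resin)), 8L)
  expect_equal(length(unique(ds2$records$MM$combos$resin)), 3L)
  expect_equal(nrow(ds2$gradients$CEX), 17L)
  expect_equal(nrow(ds2$gradients$MM), 29L)
  expect_equal(nrow(ds2$records$MM$combos), 7L + 8L + 12L)
})

test_that("subsetting steps keeps a contiguous subsequence and re-validates", {
  ds <- generate_hts(small_two_step_spec(5))
  one <- subset_steps(ds, "B")
  expect_identical(one$steps, "B")
  expect_error(subset_steps(ds, c("B", "A")), "contiguous")
  expect_error(subset_steps(ds, "nope"), "unknown step")
})
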