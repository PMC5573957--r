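# Fixture builders shared across the suite.  Everything is generated in
# code; no data files.

# Hand-built single-step dataset: one resin/condition, one protein unless
# more are supplied.  `cm` is a proteins x intervals matrix (or vector).
manual_one_step <- function(lm, cm, phase = NULL, salt = NULL,
                            proteins = NULL, target = NULL, step = "S1") {
  cm <- rbind(cm)
  if (is.null(proteins)) proteins <- paste0("p", seq_len(nrow(cm)))
  if (is.null(target)) target <- proteins[1L]
  Tn <- ncol(cm)
  if (is.null(phase)) phase <- rep("elution", Tn)
  if (is.null(salt)) salt <- ifelse(phase == "elution", seq_len(Tn) * 10, NA)
  g <- gradient_schedule(phase, salt)
  rec <- list(combos = data.frame(resin = "R1", condition = "C1"),
              lm = matrix(lm, 1L, nrow(cm), dimnames = list(NULL, proteins)),
              cm = array(cm, c(1L, nrow(cm), Tn)))
  hts_dataset(step, proteins, target, stats::setNames(list(g), step),
              stats::setNames(list(rec), step))
}

# Small randomized two-step campaign used for oracle-equivalence checks:
# 2 resins x 2 conditions (step A) + 2 resins x 1 condition (step B),
# 7 and 6 intervals.
small_two_step_spec <- function(seed, condition_sd = 0.15) {
  synthetic_spec(
    steps = list(
      list(id = "A", n_resins = 2L, conditions_per_resin = 2L,
           gradient = gradient_schedule(c("load", rep("elution", 6L)),
                                        c(NA, 0, 40, 80, 120, 160, 200))),
      list(id = "B", n_resins = 2L, conditions_per_resin = 1L,
           gradient = gradient_schedule(c("wash", rep("elution", 5L)),
                                        c(NA, 0, 100, 200, 300, 400)))),
    proteins = data.frame(name = c("tgt", "i1", "i2"),
                          fraction = c(0.75, 0.20, 0.05),
                          center_mM = c(100, 190, 30),
                          width_mM = c(35, 45, 30)),
    target = "tgt", seed = seed, condition_sd = condition_sd)
}

# Two-step toy for the constant-ratio scaling checks: step 1 delivers a
# pool equal to `scale` times step 2's calibration load for every protein.
scaling_toy <- function(scale, lm2 = c(4, 1), cm2 = NULL) {
  proteins <- c("tgt", "imp")
  if (is.null(cm2))
    cm2 <- rbind(c(0.0, 2.0, 1.2, 0.0),
                 c(0.3, 0.1, 0.2, 0.2))
  g1 <- gradient_schedule("elution", 0)
  g2 <- gradient_schedule(rep("elution", ncol(cm2)), c(0, 50, 100, 150))
  pool1 <- scale * lm2
  rec1 <- list(combos = data.frame(resin = "R1", condition = "C1"),
               lm = matrix(pool1 * 2, 1L, 2L, dimnames = list(NULL, proteins)),
               cm = array(pool1, c(1L, 2L, 1L)))
  rec2 <- list(combos = data.frame(resin = "R2", condition = "C2"),
               lm = matrix(lm2, 1L, 2L, dimnames = list(NULL, proteins)),
               cm = array(cm2, c(1L, 2L, ncol(cm2))))
  hts_dataset(c("S1", "S2"), proteins, "tgt",
              list(S1 = g1, S2 = g2), list(S1 = rec1, S2 = rec2))
}

# Quadratic reference dominance filter: point i survives iff no j is >=
# in both coordinates and > in at least one.
brute_force_front <- function(yield, purity) {
  n <- length(yield)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (is.na(purity[i])) { keep[i] <- FALSE; next }
    for (j in seq_len(n)) {
      if (i == j || is.na(purity[j])) next
      if (yield[j] >= yield[i] && purity[j] >= purity[i] &&
          (yield[j] > yield[i] || purity[j] > purity[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# content equality of datasets irrespective of protein / combo ordering
expect_same_masses <- function(a, b) {
  expect_setequal(a$steps, b$steps)
  expect_setequal(a$proteins, b$proteins)
  expect_identical(a$target, b$target)
  for (s in a$steps) {
    pa <- match(a$proteins, b$proteins)
    ka <- paste(a$records[[s]]$combos$resin, a$records[[s]]$combos$condition)
    kb <- paste(b$records[[s]]$combos$resin, b$records[[s]]$combos$condition)
    expect_setequal(ka, kb)
    ia <- match(ka, kb)
    expect_equal(unname(a$records[[s]]$lm),
                 unname(b$records[[s]]$lm[ia, pa, drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(unname(a$records[[s]]$cm),
                 unname(b$records[[s]]$cm[ia, pa, , drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(a$gradients[[s]], b$gradients[[s]])
  }
}
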