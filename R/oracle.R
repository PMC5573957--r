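#' @title Exhaustive enumeration oracle
#' @description Brute-force evaluation of the finite decision space --
#'   every (resin, condition) choice and collection window per step,
#'   filtered by salt linking -- used to verify the MILP route on small
#'   instances.  Deliberately free of pruning so that its correctness is
#'   self-evident.
#' @name oracle
NULL

# Per-step option table: one row per (combo, start <= finish window).
# A holds the pooled quantity per protein: collected mass (first step) or
# load-collection-ratio window sums (later steps).
step_option_table <- function(ds, rt, s, is_first) {
  rec <- ds$records[[s]]
  Tn <- n_intervals(ds, s)
  np <- length(ds$proteins)
  nrc <- nrow(rec$combos)
  salt <- effective_salt(ds$gradients[[s]])
  wins <- which(upper.tri(matrix(0, Tn, Tn), diag = TRUE), arr.ind = TRUE)
  wins <- wins[order(wins[, 1L], wins[, 2L]), , drop = FALSE]  # (start, finish)
  src <- if (is_first) rec$cm else rt[[s]]
  # cumulative sums over the interval dimension for O(1) window sums
  cum <- aperm(apply(src, c(1L, 2L), cumsum), c(2L, 3L, 1L))   # nrc x np x T
  nw <- nrow(wins)
  winsum <- function(i) {  # combo i -> nw x np matrix
    hi <- matrix(cum[i, , wins[, 2L]], np, nw)
    lo <- matrix(0, np, nw)
    has_lo <- wins[, 1L] > 1L
    if (any(has_lo))
      lo[, has_lo] <- matrix(cum[i, , wins[has_lo, 1L] - 1L], np, sum(has_lo))
    t(hi - lo)
  }
  A <- do.call(rbind, lapply(seq_len(nrc), winsum))
  list(
    combo  = rep(seq_len(nrc), each = nw),
    start  = rep(wins[, 1L], nrc),
    finish = rep(wins[, 2L], nrc),
    salt_s = rep(salt[wins[, 1L]], nrc),
    salt_f = rep(salt[wins[, 2L]], nrc),
    A = A, n = nrc * nw
  )
}

# Cross-step join under salt linking; returns option-row indices per step.
# Aborts loudly when the row count exceeds the budget.
join_steps <- function(opts, budget, salt_tol = 1e-9) {
  ns <- length(opts)
  idx <- matrix(seq_len(opts[[1L]]$n), ncol = 1L)
  fin <- opts[[1L]]$salt_f
  for (k in seq_len(ns)[-1L]) {
    ok <- outer(fin, opts[[k]]$salt_s, function(a, b) a <= b + salt_tol)
    pairs <- which(ok, arr.ind = TRUE)
    if (as.double(nrow(pairs)) > budget)
      stop("enumeration budget exceeded: more than ", budget,
           " partial decisions at step ", k, "; reduce the instance or raise the budget")
    idx <- cbind(idx[pairs[, 1L], , drop = FALSE], pairs[, 2L])
    fin <- opts[[k]]$salt_f[pairs[, 2L]]
  }
  idx
}

#' Enumerate every feasible process decision
#'
#' Yields every decision satisfying the structural constraints: one
#' (resin, condition) per step, one collection window with
#' `start <= finish`, and non-decreasing effective salt across consecutive
#' cut-points.  Aborts with an error when more than `budget` decisions
#' would be produced.
#'
#' @param ds an `hts_dataset`.
#' @param budget cap on the number of enumerated decisions.
#' @return A list of [process_decision()] objects.
#' @export
enumerate_decisions <- function(ds, budget = 5e6) {
  validate_hts_dataset(ds)
  rt <- compute_ratios(ds)
  opts <- lapply(seq_along(ds$steps), function(k)
    step_option_table(ds, rt, ds$steps[k], k == 1L))
  idx <- join_steps(opts, budget)
  lapply(seq_len(nrow(idx)), function(rw) {
    rows <- idx[rw, ]
    process_decision(
      step = ds$steps,
      resin = vapply(seq_along(rows), function(k)
        ds$records[[k]]$combos$resin[opts[[k]]$combo[rows[k]]], ""),
      condition = vapply(seq_along(rows), function(k)
        ds$records[[k]]$combos$condition[opts[[k]]$combo[rows[k]]], ""),
      start = vapply(seq_along(rows), function(k) opts[[k]]$start[rows[k]], 0L),
      finish = vapply(seq_along(rows), function(k) opts[[k]]$finish[rows[k]], 0L)
    )
  })
}

# Evaluate the whole decision space at once.  Returns per-decision yield,
# purity (NA for an empty pool) and the option-row index per step.
oracle_evaluate_all <- function(ds, rt, budget = 5e6) {
  opts <- lapply(seq_along(ds$steps), function(k)
    step_option_table(ds, rt, ds$steps[k], k == 1L))
  idx <- join_steps(opts, budget)
  mass <- opts[[1L]]$A[idx[, 1L], , drop = FALSE]   # pooled mass after step 1
  for (k in seq_along(ds$steps)[-1L])
    mass <- mass * opts[[k]]$A[idx[, k], , drop = FALSE]
  dp <- target_idx(ds)
  lm1 <- ds$records[[1L]]$lm[opts[[1L]]$combo[idx[, 1L]], dp]
  total <- rowSums(mass)
  list(opts = opts, idx = idx,
       yield = mass[, dp] / lm1,
       purity = ifelse(total > 0, mass[, dp] / total, NA_real_),
       total = total)
}

oracle_decision <- function(ds, ev, rw) {
  rows <- ev$idx[rw, ]
  process_decision(
    step = ds$steps,
    resin = vapply(seq_along(rows), function(k)
      ds$records[[k]]$combos$resin[ev$opts[[k]]$combo[rows[k]]], ""),
    condition = vapply(seq_along(rows), function(k)
      ds$records[[k]]$combos$condition[ev$opts[[k]]$combo[rows[k]]], ""),
    start = vapply(seq_along(rows), function(k) ev$opts[[k]]$start[rows[k]], 0L),
    finish = vapply(seq_along(rows), function(k) ev$opts[[k]]$finish[rows[k]], 0L)
  )
}

# deterministic lexicographic key (combo, start, finish per step)
oracle_order <- function(ev) {
  keys <- list()
  for (k in seq_len(ncol(ev$idx))) {
    keys[[length(keys) + 1L]] <- ev$opts[[k]]$combo[ev$idx[, k]]
    keys[[length(keys) + 1L]] <- ev$opts[[k]]$start[ev$idx[, k]]
    keys[[length(keys) + 1L]] <- ev$opts[[k]]$finish[ev$idx[, k]]
  }
  do.call(order, keys)
}

#' Exact maximum yield under a purity floor, by enumeration
#'
#' Evaluates every feasible decision and returns the one maximizing yield
#' among those with purity at least `eps` (an empty pool satisfies the
#' purity side-constraint vacuously).  Ties are broken lexicographically
#' by (resin, condition, start, finish) per step.
#'
#' @param ds an `hts_dataset`.
#' @param rt its [compute_ratios()] table.
#' @param eps purity lower bound in `[0, 1]`.
#' @param budget enumeration cap.
#' @param tol numeric slack on the purity comparison.
#' @return A list with `decision` and `metrics` ([evaluate_decision()]
#'   output), or status `"infeasible"` when no decision qualifies.
#' @export
oracle_max_yield <- function(ds, rt, eps, budget = 5e6, tol = 1e-9) {
  stopifnot(eps >= 0, eps <= 1)
  ev <- oracle_evaluate_all(ds, rt, budget)
  feas <- is.na(ev$purity) | ev$purity >= eps - tol
  if (!length(ev$yield) || !any(feas))
    return(structure(list(status = "infeasible", eps = eps), class = "oracle_result"))
  cand <- which(feas)
  atmax <- cand[ev$yield[cand] == max(ev$yield[cand])]
  rw <- atmax[which.min(match(atmax, oracle_order(ev)))]
  d <- oracle_decision(ds, ev, rw)
  structure(list(status = "optimal", eps = eps, decision = d,
                 metrics = evaluate_decision(ds, rt, d)),
            class = "oracle_result")
}

# Maximal set under the componentwise (yield, purity) order: a point is
# dropped iff some other point is >= in both coordinates and > in one.
# Exact duplicates of a maximal point are all retained (they dominate
# nothing and are dominated by nothing).  NA-purity rows (empty pools) are
# never retained.  O(n log n): scan equal-yield groups by decreasing yield;
# within a group only the max-purity points survive, and only if their
# purity strictly exceeds every purity seen at higher yield.
pareto_max_mask <- function(yield, purity) {
  mask <- logical(length(yield))
  idx <- which(!is.na(purity))
  if (!length(idx)) return(mask)
  ord <- idx[order(-yield[idx], -purity[idx])]
  y <- yield[ord]
  grp <- cumsum(!duplicated(y))
  best_p <- -Inf
  for (g in split(ord, grp)) {
    pg <- purity[g]
    pmax <- pg[1L]          # groups are sorted purity-descending
    if (pmax > best_p) {
      mask[g[pg == pmax]] <- TRUE
      best_p <- pmax
    }
  }
  mask
}

#' Exact Pareto frontier by enumeration
#'
#' The dominance-maximal set of (yield, purity) pairs over every feasible
#' decision, with one representative decision per distinct pair.
#'
#' @inheritParams oracle_max_yield
#' @return A data frame sorted by purity ascending with columns `yield`,
#'   `purity` and a list column `decision`.
#' @export
oracle_pareto <- function(ds, rt, budget = 5e6) {
  ev <- oracle_evaluate_all(ds, rt, budget)
  mask <- pareto_max_mask(ev$yield, ev$purity)
  rws <- which(mask)
  if (!length(rws))
    return(data.frame(yield = numeric(0), purity = numeric(0)))
  # one representative per distinct (yield, purity), deterministic pick
  key <- paste(format(ev$yield[rws], digits = 17),
               format(ev$purity[rws], digits = 17))
  ordall <- oracle_order(ev)
  rws <- rws[order(match(rws, ordall))]
  key <- paste(format(ev$yield[rws], digits = 17),
               format(ev$purity[rws], digits = 17))
  rws <- rws[!duplicated(key)]
  out <- data.frame(yield = ev$yield[rws], purity = ev$purity[rws])
  out$decision <- lapply(rws, function(rw) oracle_decision(ds, ev, rw))
  out[order(out$purity), , drop = FALSE]
}
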