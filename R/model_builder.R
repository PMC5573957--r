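#' @title MILP formulation of the resin / cut-point selection problem
#' @description Builds the mixed-integer constraint system over binaries
#'   `Z` (condition selection), `Xs`/`Xf` (start/finish cut-points), `X`
#'   (interval selected) and `W` (joint selection), and continuous mass
#'   flows `LM`, `M`, `CM`, plus the purity side-constraint and the
#'   Dinkelbach-parameterized objective `CM[last, target] - f * LM[first,
#'   target]`.  Constraint families carry stable labels (`select_one`,
#'   `one_start`, `one_finish`, `window`, `gate_w_x`, `gate_w_z`,
#'   `gate_w_on`, `load_first`, `collect_first`, `pool`, `carry`,
#'   `ratio_ub`, `ratio_lb`, `ratio_gate`, `salt_link`, `purity`) so tests
#'   can count and inspect rows.
#' @name model_builder
NULL

vn <- function(...) paste(..., sep = "|")

rescale_masses <- function(ds, k) {
  for (s in ds$steps) {
    ds$records[[s]]$lm <- ds$records[[s]]$lm * k
    ds$records[[s]]$cm <- ds$records[[s]]$cm * k
  }
  ds
}

#' Big-M policy for the mass-prediction constraints
#'
#' Returns per-family bounds guaranteed to dominate the quantity each
#' big-M row relaxes.  For the selection-gating rows the bound is the
#' number of summed binaries; for the ratio rows it is
#' `lcr * UB(LM)`, where the loaded-mass upper bound is the maximum
#' experimental load at the first step and is propagated unchanged to
#' later steps (interval ratio sums never exceed 1, so pooled mass cannot
#' grow along the train).
#'
#' @param ds an `hts_dataset`.
#' @param rt its [compute_ratios()] table.
#' @return A `bigm_policy` list: `U_LM` (step x protein matrix), `gate_x`
#'   and `gate_z` (per-step counts).
#' @export
default_bigm <- function(ds, rt) {
  ns <- length(ds$steps); np <- length(ds$proteins)
  U_LM <- matrix(0, ns, np, dimnames = list(ds$steps, ds$proteins))
  U_LM[1L, ] <- apply(ds$records[[1L]]$lm, 2L, max)
  if (ns > 1L) for (k in 2:ns) U_LM[k, ] <- U_LM[k - 1L, ]
  structure(list(
    U_LM = U_LM,
    gate_x = vapply(ds$steps, function(s) n_combos(ds, s), 0),
    gate_z = vapply(ds$steps, function(s) n_intervals(ds, s), 0)
  ), class = "bigm_policy")
}

#' Build the selection MILP for fixed purity bound and fractional parameter
#'
#' Constructs the full constraint system: one condition per step; one
#' start and one finish cut-point whose window recursion
#' `X[t] = X[t-1] + Xs[t] - Xf[t-1]` forces a contiguous collection block
#' (the start-marked interval included); `W = X * Z` linearized by gating
#' rows; first-step mass fixed to the experiment (`LM` from the selected
#' load, `M = cm * W`); later-step mass predicted by the constant
#' load-collection ratio (`M = lcr * LM` when selected, else 0, via big-M
#' rows); pooled mass carried to the next step's load; effective eluent
#' salt non-decreasing across consecutive cut-points; and the pool purity
#' floor `CM[last, target] >= eps * sum_p CM[last, p]`.  The objective is
#' `CM[last, target] - f * LM[first, target]`, maximized.
#'
#' Two numerical-conditioning choices are applied, both invisible to the
#' caller: mass coefficients are rescaled internally so the largest
#' first-step load sits at 1e4 (solver feasibility tolerances are
#' absolute, so this makes them ~1e-11 relative to the data; the scale is
#' attached as attribute `"mass_scale"` and solution masses are on the
#' scaled axis), and load-collection ratios or scaled collected masses
#' below `ratio_floor` are treated as exact zeros.  Such entries are far
#' below any quantification limit (about 1e-12 of the load at the default
#' floor), and matrix coefficients that small are dropped or mangled by
#' MILP solvers' presolve (HiGHS removes values below 1e-9), which is far
#' worse than an explicit, documented zero.
#'
#' @param ds an `hts_dataset`.
#' @param rt its [compute_ratios()] table.
#' @param eps purity lower bound in `[0, 1]`.
#' @param f Dinkelbach fractional parameter (>= 0).
#' @param policy a [default_bigm()] policy.
#' @param ratio_floor load-collection ratios (and scaled collected
#'   masses) below this are exact zeros.
#' @return A [milp_model()] ready for [solve_milp()]; attribute
#'   `"mass_scale"` gives the factor mass variables were multiplied by.
#' @export
build_model <- function(ds, rt, eps, f = 0, policy = default_bigm(ds, rt),
                        ratio_floor = 1e-8) {
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0 || eps > 1)
    stop("eps must be a single value in [0, 1]")
  validate_hts_dataset(ds)
  force(policy)   # must see the caller-scale dataset, not the rescaled one
  np <- length(ds$proteins); ns <- length(ds$steps)
  dp <- target_idx(ds)
  kscale <- 1e4 / max(ds$records[[1L]]$lm)
  ds <- rescale_masses(ds, kscale)
  for (s in ds$steps)
    ds$records[[s]]$cm[ds$records[[s]]$cm < ratio_floor] <- 0
  rt <- lapply(rt, function(a) { a[a < ratio_floor] <- 0; a })
  policy$U_LM <- policy$U_LM * kscale
  m <- milp_model()
  attr(m, "mass_scale") <- kscale

  for (k in seq_len(ns)) {
    s <- ds$steps[k]
    rec <- ds$records[[s]]
    nrc <- nrow(rec$combos); Tn <- n_intervals(ds, s)
    add_vars(m, vn("Z", s, seq_len(nrc)), "B")
    add_vars(m, vn("Xs", s, seq_len(Tn)), "B")
    add_vars(m, vn("Xf", s, seq_len(Tn)), "B")
    # X and W are implied-integer: the window recursion determines X from
    # the binary cut-points, and the gating rows pinch W to X * Z exactly.
    # Declaring them continuous in [0, 1] keeps every integer solution and
    # removes ~T + |rc| * T variables per step from the branching space.
    add_vars(m, vn("X", s, seq_len(Tn)), "C", 0, 1)
    for (i in seq_len(nrc)) add_vars(m, vn("W", s, i, seq_len(Tn)), "C", 0, 1)
    for (p in seq_len(np))
      add_vars(m, vn("LM", s, p), "C", 0, policy$U_LM[k, p])
    for (i in seq_len(nrc)) for (p in seq_len(np)) {
      ub <- if (k == 1L) rec$cm[i, p, ] else rt[[s]][i, p, ] * policy$U_LM[k, p]
      add_vars(m, vn("M", s, i, p, seq_len(Tn)), "C", 0, ub)
    }
    for (p in seq_len(np))
      add_vars(m, vn("CM", s, p), "C", 0, policy$U_LM[k, p])
  }

  for (k in seq_len(ns)) {
    s <- ds$steps[k]
    rec <- ds$records[[s]]
    nrc <- nrow(rec$combos); Tn <- n_intervals(ds, s)
    zid <- var_id(m, vn("Z", s, seq_len(nrc)))
    xsid <- var_id(m, vn("Xs", s, seq_len(Tn)))
    xfid <- var_id(m, vn("Xf", s, seq_len(Tn)))
    xid <- var_id(m, vn("X", s, seq_len(Tn)))

    add_constr(m, zid, rep(1, nrc), "=", 1, "select_one")
    add_constr(m, xsid, rep(1, Tn), "=", 1, "one_start")
    add_constr(m, xfid, rep(1, Tn), "=", 1, "one_finish")
    # window recursion: X[1] = Xs[1]; X[t] = X[t-1] + Xs[t] - Xf[t-1]
    add_constr(m, c(xid[1L], xsid[1L]), c(1, -1), "=", 0, "window")
    if (Tn > 1L) for (t in 2:Tn)
      add_constr(m, c(xid[t], xid[t - 1L], xsid[t], xfid[t - 1L]),
                 c(1, -1, -1, 1), "=", 0, "window")
    # the recursion alone admits one degenerate encoding -- a start cut
    # immediately after the finish cut yields the all-zero (empty) window;
    # a pooling step that collects nothing is operationally meaningless,
    # so require at least one selected interval
    add_constr(m, xid, rep(1, Tn), ">=", 1, "nonempty")

    wid <- matrix(var_id(m, as.vector(vapply(seq_len(nrc), function(i)
      vn("W", s, i, seq_len(Tn)), character(Tn)))), Tn, nrc)
    for (t in seq_len(Tn))
      add_constr(m, c(wid[t, ], xid[t]), c(rep(1, nrc), -policy$gate_x[k]),
                 "<=", 0, "gate_w_x")
    for (i in seq_len(nrc))
      add_constr(m, c(wid[, i], zid[i]), c(rep(1, Tn), -policy$gate_z[k]),
                 "<=", 0, "gate_w_z")
    for (i in seq_len(nrc)) for (t in seq_len(Tn))
      add_constr(m, c(wid[t, i], xid[t], zid[i]), c(1, -1, -1),
                 ">=", -1, "gate_w_on")
    # valid cuts, redundant on integer points but tightening the LP
    # relaxation substantially on full-scale instances: disaggregated
    # W <= X, W <= Z, and the aggregation equality sum_rc W[t] = X[t]
    # (exactly one condition is active, so a selected interval contributes
    # exactly one W)
    for (i in seq_len(nrc)) for (t in seq_len(Tn)) {
      add_constr(m, c(wid[t, i], xid[t]), c(1, -1), "<=", 0, "cut_w_x")
      add_constr(m, c(wid[t, i], zid[i]), c(1, -1), "<=", 0, "cut_w_z")
    }
    for (t in seq_len(Tn))
      add_constr(m, c(wid[t, ], xid[t]), c(rep(1, nrc), -1), "=", 0, "cut_w_sum")

    lmid <- var_id(m, vn("LM", s, seq_len(np)))
    cmid <- var_id(m, vn("CM", s, seq_len(np)))
    if (k == 1L) {
      for (p in seq_len(np))
        add_constr(m, c(lmid[p], zid), c(1, -rec$lm[, p]), "=", 0, "load_first")
      for (i in seq_len(nrc)) for (p in seq_len(np)) {
        mid <- var_id(m, vn("M", s, i, p, seq_len(Tn)))
        for (t in seq_len(Tn))
          add_constr(m, c(mid[t], wid[t, i]), c(1, -rec$cm[i, p, t]),
                     "=", 0, "collect_first")
      }
    } else {
      for (i in seq_len(nrc)) for (p in seq_len(np)) {
        mid <- var_id(m, vn("M", s, i, p, seq_len(Tn)))
        for (t in seq_len(Tn)) {
          lcr <- rt[[s]][i, p, t]
          U <- lcr * policy$U_LM[k, p]
          add_constr(m, c(mid[t], lmid[p]), c(1, -lcr), "<=", 0, "ratio_ub")
          add_constr(m, c(mid[t], lmid[p], wid[t, i]), c(1, -lcr, -U),
                     ">=", -U, "ratio_lb")
          add_constr(m, c(mid[t], wid[t, i]), c(1, -U), "<=", 0, "ratio_gate")
        }
      }
    }
    for (p in seq_len(np)) {
      mids <- unlist(lapply(seq_len(nrc), function(i)
        var_id(m, vn("M", s, i, p, seq_len(Tn)))))
      add_constr(m, c(cmid[p], mids), c(1, rep(-1, length(mids))),
                 "=", 0, "pool")
    }
  }

  for (k in seq_len(ns)[-1L]) {
    s_prev <- ds$steps[k - 1L]; s <- ds$steps[k]
    for (p in seq_len(np))
      add_constr(m, c(var_id(m, vn("LM", s, p)), var_id(m, vn("CM", s_prev, p))),
                 c(1, -1), "=", 0, "carry")
    salt_prev <- effective_salt(ds$gradients[[s_prev]])
    salt_cur <- effective_salt(ds$gradients[[s]])
    add_constr(m,
               c(var_id(m, vn("Xf", s_prev, seq_along(salt_prev))),
                 var_id(m, vn("Xs", s, seq_along(salt_cur)))),
               c(salt_prev, -salt_cur), "<=", 0, "salt_link")
  }

  cml <- var_id(m, vn("CM", ds$steps[ns], seq_len(np)))
  coef <- rep(-eps, np); coef[dp] <- 1 - eps
  add_constr(m, cml, coef, ">=", 0, "purity")

  set_objective(m, c(cml[dp], var_id(m, vn("LM", ds$steps[1L], dp))),
                c(1, -f), maximize = TRUE)
  m
}

#' Read the selected decision out of a MILP solution
#'
#' Also verifies that the implied-integer selection variables actually
#' took integral values, as the formulation guarantees.
#'
#' @param ds the `hts_dataset` the model was built from.
#' @param sol a [solve_milp()] solution with `values`.
#' @param int_tol tolerance on integrality of the selection variables.
#' @return A [process_decision()].
#' @export
extract_decision <- function(ds, sol, int_tol = 1e-5) {
  stopifnot(!is.null(sol$values))
  v <- sol$values
  sel <- grepl("^(Z|Xs|Xf|X|W)\\|", names(v))
  if (max(abs(v[sel] - round(v[sel]))) > int_tol)
    stop("selection variables are not integral; solver returned a ",
         "fractional solution")
  rows <- lapply(ds$steps, function(s) {
    rec <- ds$records[[s]]
    nrc <- nrow(rec$combos); Tn <- n_intervals(ds, s)
    i <- which(v[vn("Z", s, seq_len(nrc))] > 0.5)
    t1 <- which(v[vn("Xs", s, seq_len(Tn))] > 0.5)
    t2 <- which(v[vn("Xf", s, seq_len(Tn))] > 0.5)
    if (length(i) != 1L || length(t1) != 1L || length(t2) != 1L)
      stop("solution does not encode a unique decision at step ", s)
    data.frame(step = s, resin = rec$combos$resin[i],
               condition = rec$combos$condition[i],
               start = t1, finish = t2, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  class(d) <- c("process_decision", "data.frame")
  d
}
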