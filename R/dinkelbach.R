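#' Settings for the fractional-program solver
#'
#' @param delta absolute convergence tolerance on the Dinkelbach residual
#'   `CM* - f * LM*` (mg); iteration stops once the residual is within
#'   `delta` of zero.  With MILPs solved to a 0% gap the algorithm
#'   converges finitely with a residual at numerical zero, so the default
#'   is tight enough that the returned decision is exactly optimal, not
#'   merely delta-optimal.
#' @param max_iterations hard cap on Dinkelbach iterations; hitting it is
#'   reported as an explicit non-convergence status, never silently.
#' @param gap relative MILP optimality gap (0 = proven optimum, as the
#'   frontier guarantees require).
#' @param time_limit per-MILP wall-clock limit in seconds, or `NULL`.
#' @param persistent reuse one solver worker process across solves.
#' @return A `milfp_settings` list.
#' @export
milfp_settings <- function(delta = 1e-9, max_iterations = 50L, gap = 0,
                           time_limit = NULL, persistent = TRUE) {
  stopifnot(delta > 0, max_iterations >= 1L, gap >= 0)
  structure(list(delta = delta, max_iterations = as.integer(max_iterations),
                 gap = gap, time_limit = time_limit, persistent = persistent),
            class = "milfp_settings")
}

#' Maximize yield under a purity floor (mixed-integer linear fractional program)
#'
#' Solves `max CM[last, target] / LM[first, target]` subject to the full
#' constraint system and pool purity `>= eps`, by Dinkelbach's algorithm:
#' starting from `f = 0`, repeatedly solve the MILP with objective
#' `CM - f * LM`; if its optimum is within `delta` of zero stop, otherwise
#' set `f` to the incumbent ratio `CM*/LM*` and re-solve.  Each MILP is
#' solved to a 0% optimality gap, so on convergence the returned decision
#' maximizes yield at the requested purity.  The reported metrics are
#' recomputed by forward simulation ([evaluate_decision()]) from the
#' decision, never read off solver variables.
#'
#' @param ds an `hts_dataset`.
#' @param rt its [compute_ratios()] table.
#' @param eps purity lower bound in `[0, 1]`.
#' @param settings a [milfp_settings()].
#' @return A `milfp_result` list: `status` (`"converged"`, `"infeasible"`,
#'   `"iteration_limit"`), and on convergence `decision`, `metrics`, and
#'   `trace` -- a data frame with one row per iteration (`f`, `residual`
#'   = MILP objective, `ratio` = incumbent yield).
#' @export
solve_milfp <- function(ds, rt, eps, settings = milfp_settings()) {
  stopifnot(eps >= 0, eps <= 1)
  policy <- default_bigm(ds, rt)
  f <- 0
  trace <- data.frame(f = numeric(), residual = numeric(), ratio = numeric())
  decision <- NULL
  # only the objective depends on f: build the constraint system once
  m <- build_model(ds, rt, eps, f = 0, policy = policy)
  dp <- target_idx(ds)
  obj_ids <- var_id(m, c(vn("CM", ds$steps[length(ds$steps)], dp),
                         vn("LM", ds$steps[1L], dp)))
  for (it in seq_len(settings$max_iterations)) {
    set_objective(m, obj_ids, c(1, -f), maximize = TRUE)
    sol <- solve_milp(m, gap = settings$gap, time_limit = settings$time_limit,
                      persistent = settings$persistent)
    if (sol$status == "infeasible") {
      if (it > 1L) stop("MILP became infeasible after the first iteration; ",
                        "this cannot happen for a fixed eps")
      return(structure(list(status = "infeasible", eps = eps, trace = trace),
                       class = "milfp_result"))
    }
    if (sol$status != "optimal")
      stop("MILP solve returned status '", sol$status,
           "' (limit hit?); cannot certify the Dinkelbach iterate")
    decision <- extract_decision(ds, sol)
    k <- attr(m, "mass_scale")
    cm_star <- sol$values[vn("CM", ds$steps[length(ds$steps)], dp)] / k
    lm_star <- sol$values[vn("LM", ds$steps[1L], dp)] / k
    residual <- cm_star - f * lm_star
    trace <- rbind(trace, data.frame(f = f, residual = residual,
                                     ratio = cm_star / lm_star))
    if (residual <= settings$delta) {
      metrics <- evaluate_decision(ds, rt, decision)
      return(structure(list(status = "converged", eps = eps,
                            decision = decision, metrics = metrics,
                            trace = trace, iterations = it),
                       class = "milfp_result"))
    }
    f <- cm_star / lm_star
  }
  structure(list(status = "iteration_limit", eps = eps, trace = trace),
            class = "milfp_result")
}

#' @export
print.milfp_result <- function(x, ...) {
  cat("Dinkelbach fractional solve (eps =", format(x$eps), ")\n")
  cat("  status:", x$status, "\n")
  if (x$status == "converged") {
    cat("  iterations:", x$iterations, "\n")
    cat(sprintf("  yield = %.4f, purity = %.4f\n",
                x$metrics$yield, x$metrics$purity))
  }
  invisible(x)
}

#' Direct single-MILP solve for the equal-load special case
#'
#' When every first-step experiment loads the same target-protein mass,
#' the yield denominator is a constant and the fractional program
#' degenerates to a single MILP maximizing the pooled target mass.
#' Provided as an independent route for that special case.
#'
#' @inheritParams solve_milfp
#' @return A `milfp_result` with a single-row trace.
#' @export
solve_fixed_load <- function(ds, rt, eps, settings = milfp_settings()) {
  dp <- target_idx(ds)
  lm_dp <- ds$records[[1L]]$lm[, dp]
  if (diff(range(lm_dp)) > 1e-12)
    stop("first-step target loads differ; the objective is genuinely ",
         "fractional -- use solve_milfp()")
  m <- build_model(ds, rt, eps, f = 0)
  sol <- solve_milp(m, gap = settings$gap, time_limit = settings$time_limit,
                    persistent = settings$persistent)
  if (sol$status == "infeasible")
    return(structure(list(status = "infeasible", eps = eps), class = "milfp_result"))
  if (sol$status != "optimal")
    stop("MILP solve returned status '", sol$status, "'")
  decision <- extract_decision(ds, sol)
  metrics <- evaluate_decision(ds, rt, decision)
  obj <- sol$objective / attr(m, "mass_scale")
  structure(list(status = "converged", eps = eps, decision = decision,
                 metrics = metrics, iterations = 1L,
                 trace = data.frame(f = 0, residual = obj,
                                    ratio = obj / lm_dp[1L])),
            class = "milfp_result")
}
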