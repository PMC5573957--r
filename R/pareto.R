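#' Remove dominated points from a (yield, purity) cloud
#'
#' Keeps exactly the maximal set under the componentwise order: a point is
#' dropped iff another point is at least as good in both yield and purity
#' and strictly better in one.  Exact duplicates of a retained pair are
#' collapsed to the first occurrence.  The result is sorted by purity
#' ascending (hence yield non-increasing).
#'
#' @param points data frame with numeric columns `yield` and `purity`
#'   (other columns are carried along).
#' @return The filtered, sorted data frame.
#' @export
filter_dominated <- function(points) {
  stopifnot(is.data.frame(points), all(c("yield", "purity") %in% names(points)))
  if (!nrow(points)) return(points)
  mask <- pareto_max_mask(points$yield, points$purity)
  out <- points[mask, , drop = FALSE]
  key <- paste(format(out$yield, digits = 17), format(out$purity, digits = 17))
  out <- out[!duplicated(key), , drop = FALSE]
  out[order(out$purity, -out$yield), , drop = FALSE]
}

#' Map the yield-purity Pareto frontier by an epsilon sweep
#'
#' Runs one fractional solve ([solve_milfp()]) per purity floor in
#' `eps_grid`, records infeasible floors, and post-filters the solutions
#' for dominance: the epsilon-constraint method only guarantees weak
#' Pareto optimality when optima are non-unique, so dominated and
#' duplicate points are removed rather than trusted.
#'
#' @param ds an `hts_dataset`.
#' @param rt its [compute_ratios()] table; computed from `ds` if missing.
#' @param eps_grid purity floors to sweep; default is 90% to 99% in steps
#'   of 1%.
#' @param settings a [milfp_settings()].
#' @return A `pareto_front`: data frame with columns `eps`, `yield`,
#'   `purity`, `iterations` and a list column `decision`, sorted by purity
#'   ascending; attributes `infeasible_eps` (floors with no solution) and
#'   `traces` (Dinkelbach traces of the retained points).
#' @export
sweep_pareto <- function(ds, rt = compute_ratios(ds),
                         eps_grid = seq(0.90, 0.99, by = 0.01),
                         settings = milfp_settings()) {
  stopifnot(length(eps_grid) >= 1L, all(eps_grid >= 0), all(eps_grid <= 1))
  pts <- list(); infeas <- numeric(); traces <- list()
  for (eps in eps_grid) {
    res <- solve_milfp(ds, rt, eps, settings)
    if (res$status == "infeasible") {
      infeas <- c(infeas, eps)
    } else if (res$status == "converged") {
      pts[[length(pts) + 1L]] <- data.frame(
        eps = eps, yield = res$metrics$yield, purity = res$metrics$purity,
        iterations = res$iterations)
      pts[[length(pts)]]$decision <- list(res$decision)
      traces[[format(eps)]] <- res$trace
    } else {
      stop("fractional solve did not converge at eps = ", eps,
           " (status ", res$status, ")")
    }
  }
  if (!length(pts)) {
    front <- data.frame(eps = numeric(), yield = numeric(), purity = numeric(),
                        iterations = integer())
    front$decision <- list()
  } else {
    front <- filter_dominated(do.call(rbind, pts))
  }
  rownames(front) <- NULL
  structure(front, infeasible_eps = infeas, traces = traces,
            class = c("pareto_front", "data.frame"))
}

#' Optimize a single step or the integrated train
#'
#' `mode = "integrated"` sweeps the full step sequence with salt linking
#' between consecutive cut-points; `mode = "single:<step>"` (or a bare
#' step id) restricts the process to that one step, making it both the
#' load and the polish step, with no linking constraints.
#'
#' @param ds an `hts_dataset`.
#' @param mode `"integrated"`, `"single:<step id>"`, or a step id.
#' @param eps_grid,settings passed to [sweep_pareto()].
#' @return A `pareto_front`; the dataset actually swept is attached as
#'   attribute `"dataset"`.
#' @export
run_mode <- function(ds, mode = "integrated",
                     eps_grid = seq(0.90, 0.99, by = 0.01),
                     settings = milfp_settings()) {
  if (identical(mode, "integrated")) {
    sub <- ds
  } else {
    step <- sub("^single:", "", mode)
    if (!step %in% ds$steps)
      stop("unknown step id in mode '", mode, "'; steps are: ",
           paste(ds$steps, collapse = ", "))
    sub <- subset_steps(ds, step)
  }
  front <- sweep_pareto(sub, compute_ratios(sub), eps_grid, settings)
  attr(front, "dataset") <- sub
  front
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("Pareto frontier:", nrow(x), "nondominated solution(s)\n")
  if (nrow(x)) {
    df <- data.frame(eps = x$eps,
                     yield = sprintf("%.1f%%", 100 * x$yield),
                     purity = sprintf("%.1f%%", 100 * x$purity),
                     iterations = x$iterations)
    print(df, row.names = FALSE)
  }
  inf <- attr(x, "infeasible_eps")
  if (length(inf))
    cat("infeasible purity floor(s):", paste(format(inf), collapse = ", "), "\n")
  invisible(x)
}
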