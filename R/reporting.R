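#' Describe a collection window in process terms
#'
#' Formats a window as the phases it spans and the effective salt range,
#' e.g. `"Elution (0-250 mM NaCl): T4-T15"`.
#'
#' @param ds an `hts_dataset`.
#' @param step step id.
#' @param start,finish window cut-points (interval indices).
#' @return A single string.
#' @export
window_label <- function(ds, step, start, finish) {
  g <- ds$gradients[[step]]
  salt <- effective_salt(g)
  phases <- unique(g$phase[start:finish])
  phases <- paste0(toupper(substring(phases, 1, 1)), substring(phases, 2))
  lo <- salt[start]; hi <- salt[finish]
  range <- if (lo == hi) paste0(lo, " mM NaCl") else paste0(lo, "-", hi, " mM NaCl")
  sprintf("%s (%s): T%d-T%d", paste(phases, collapse = ", "), range, start, finish)
}

#' Flatten a Pareto frontier to a per-step table
#'
#' One row per (solution, step), in the layout of the package's CSV
#' export: purity floor, step, resin, condition, window cut-points, the
#' effective salt at each cut-point, and the solution's yield, purity and
#' Dinkelbach iteration count.
#'
#' @param front a [sweep_pareto()] / [run_mode()] result.
#' @param ds the `hts_dataset` it was computed on (defaults to the
#'   dataset attached by [run_mode()]).
#' @return A data frame.
#' @export
pareto_table <- function(front, ds = attr(front, "dataset")) {
  if (is.null(ds)) stop("supply the dataset the frontier was computed on")
  if (!nrow(front))
    return(data.frame(eps = numeric(), step = character(), resin = character(),
                      condition = character(), start_interval = integer(),
                      finish_interval = integer(), salt_start_mM = numeric(),
                      salt_finish_mM = numeric(), yield = numeric(),
                      purity = numeric(), dinkelbach_iterations = integer()))
  rows <- lapply(seq_len(nrow(front)), function(k) {
    d <- front$decision[[k]]
    do.call(rbind, lapply(seq_len(nrow(d)), function(j) {
      salt <- effective_salt(ds$gradients[[d$step[j]]])
      data.frame(eps = front$eps[k], step = d$step[j], resin = d$resin[j],
                 condition = d$condition[j],
                 start_interval = d$start[j], finish_interval = d$finish[j],
                 salt_start_mM = unname(salt[d$start[j]]),
                 salt_finish_mM = unname(salt[d$finish[j]]),
                 yield = front$yield[k], purity = front$purity[k],
                 dinkelbach_iterations = front$iterations[k])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a Pareto frontier to disk
#'
#' Writes `pareto.csv` (the [pareto_table()] layout) and, when traces are
#' present, `pareto_traces.json` with the per-epsilon Dinkelbach
#' iteration logs.
#'
#' @param front a `pareto_front`.
#' @param dir output directory (created if absent).
#' @param ds dataset the frontier was computed on.
#' @return `dir`, invisibly.
#' @export
write_pareto <- function(front, dir, ds = attr(front, "dataset")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pareto_table(front, ds), file.path(dir, "pareto.csv"),
                   row.names = FALSE)
  traces <- attr(front, "traces")
  payload <- list(
    infeasible_eps = attr(front, "infeasible_eps"),
    traces = traces
  )
  jsonlite::write_json(payload, file.path(dir, "pareto_traces.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Render a frontier as a solution table
#'
#' Human-readable summary, one block per nondominated solution listing
#' the resin, condition and collection window per step with yield and
#' purity in percent.
#'
#' @param front a `pareto_front`.
#' @param ds dataset the frontier was computed on.
#' @return Character vector of report lines, invisibly; printed unless
#'   `quiet = TRUE`.
#' @param quiet suppress printing.
#' @export
report_front <- function(front, ds = attr(front, "dataset"), quiet = FALSE) {
  if (is.null(ds)) stop("supply the dataset the frontier was computed on")
  lines <- c(sprintf("%-8s %-24s %-44s %7s %7s",
                     "Solution", "Resin / Condition", "Collection window",
                     "Yield", "Purity"))
  if (!nrow(front)) lines <- c(lines, "(no feasible solution)")
  for (k in seq_len(nrow(front))) {
    d <- front$decision[[k]]
    for (j in seq_len(nrow(d))) {
      lines <- c(lines, sprintf(
        "%-8s %-24s %-44s %7s %7s",
        if (j == 1L) paste0("S", k) else "",
        paste(d$resin[j], d$condition[j]),
        window_label(ds, d$step[j], d$start[j], d$finish[j]),
        if (j == 1L) sprintf("%.1f%%", 100 * front$yield[k]) else "",
        if (j == 1L) sprintf("%.1f%%", 100 * front$purity[k]) else ""))
    }
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
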