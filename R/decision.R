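#' Construct a process decision
#'
#' A process decision fixes, for every step of the train, the resin and
#' operating condition to run and the collection window: the first
#' (`start`) and last (`finish`) time interval pooled.
#'
#' @param step,resin,condition,start,finish vectors of equal length, one
#'   entry per step in process order.
#' @return A `process_decision` data frame.
#' @export
process_decision <- function(step, resin, condition, start, finish) {
  d <- data.frame(step = as.character(step), resin = as.character(resin),
                  condition = as.character(condition),
                  start = as.integer(start), finish = as.integer(finish),
                  stringsAsFactors = FALSE)
  class(d) <- c("process_decision", "data.frame")
  d
}

check_decision <- function(ds, d, salt_tol = 1e-9) {
  if (!identical(d$step, ds$steps))
    stop("decision must cover exactly the dataset's steps, in order")
  prev_fin_salt <- NULL
  for (k in seq_len(nrow(d))) {
    s <- d$step[k]
    rec <- ds$records[[s]]
    i <- which(rec$combos$resin == d$resin[k] & rec$combos$condition == d$condition[k])
    if (length(i) != 1L)
      stop("step ", s, ": (", d$resin[k], ", ", d$condition[k],
           ") not in the dataset")
    Tn <- n_intervals(ds, s)
    if (d$start[k] < 1L || d$finish[k] > Tn || d$start[k] > d$finish[k])
      stop("step ", s, ": collection window T", d$start[k], "-T", d$finish[k],
           " invalid for ", Tn, " intervals")
    salt <- effective_salt(ds$gradients[[s]])
    if (!is.null(prev_fin_salt) && prev_fin_salt > salt[d$start[k]] + salt_tol)
      stop("step ", s, ": salt linking violated (", prev_fin_salt,
           " mM at upstream finish > ", salt[d$start[k]], " mM at start)")
    prev_fin_salt <- salt[d$finish[k]]
  }
  invisible(d)
}

#' Forward-simulate a process decision
#'
#' Computes the mass flows of a fixed decision under the constant
#' load-collection-ratio assumption.  At the first step the loaded mass is
#' the experiment's load and the collected mass per interval is the
#' experiment's measurement; at every later step the load is the previous
#' step's pool and the predicted collected mass per interval is
#' `lcr * LM`, i.e. the calibration ratio times the actual load.  Yield is
#' the target's final-pool mass over its first-step load; purity is the
#' target's share of the final pool.
#'
#' @param ds an `hts_dataset`.
#' @param rt its [compute_ratios()] table.
#' @param d a [process_decision()]; must respect salt linking between
#'   consecutive steps.
#' @return A `solution_metrics` list: `yield`, `purity`, matrices `LM` and
#'   `CM` (step x protein, mg), and `collected` -- per step a protein x
#'   interval matrix of (predicted) collected mass, zero outside the
#'   window.  `purity` is `NA` (flag `empty_collection`) if the final pool
#'   is massless.
#' @export
evaluate_decision <- function(ds, rt, d) {
  check_decision(ds, d)
  np <- length(ds$proteins)
  ns <- length(ds$steps)
  LM <- CM <- matrix(0, ns, np, dimnames = list(ds$steps, ds$proteins))
  collected <- vector("list", ns)
  names(collected) <- ds$steps
  for (k in seq_len(ns)) {
    s <- ds$steps[k]
    rec <- ds$records[[s]]
    i <- which(rec$combos$resin == d$resin[k] & rec$combos$condition == d$condition[k])
    win <- d$start[k]:d$finish[k]
    Tn <- n_intervals(ds, s)
    M <- matrix(0, np, Tn, dimnames = list(ds$proteins, paste0("T", 1:Tn)))
    if (k == 1L) {
      LM[k, ] <- rec$lm[i, ]
      M[, win] <- array(rec$cm[i, , win, drop = FALSE], c(np, length(win)))
    } else {
      LM[k, ] <- CM[k - 1L, ]
      M[, win] <- array(rt[[s]][i, , win, drop = FALSE], c(np, length(win))) * LM[k, ]
    }
    CM[k, ] <- rowSums(M)
    collected[[k]] <- M
  }
  dp <- target_idx(ds)
  total <- sum(CM[ns, ])
  structure(list(
    yield  = CM[ns, dp] / LM[1L, dp],
    purity = if (total > 0) CM[ns, dp] / total else NA_real_,
    empty_collection = total <= 0,
    LM = LM, CM = CM, collected = collected, decision = d
  ), class = "solution_metrics")
}

#' @export
print.solution_metrics <- function(x, ...) {
  cat("Chromatography train forward simulation\n")
  for (k in seq_len(nrow(x$decision)))
    cat(sprintf("  %-6s %s / %s, window T%d-T%d\n", x$decision$step[k],
                x$decision$resin[k], x$decision$condition[k],
                x$decision$start[k], x$decision$finish[k]))
  cat(sprintf("  yield  Y = %.4f\n", x$yield))
  if (x$empty_collection) cat("  purity P undefined: empty collection\n")
  else cat(sprintf("  purity P = %.4f\n", x$purity))
  invisible(x)
}
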