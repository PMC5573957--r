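#' resinopt: resin, condition and cut-point selection from HTS chromatography screens
#'
#' High-throughput screening (HTS) microscale chromatography experiments test
#' many stationary-phase resins, each under several operating conditions
#' (pH / loading-salt combinations), recording the mass of every protein
#' species loaded and the mass recovered in each elution time interval of a
#' salt-gradient run.  resinopt turns those tables into process decisions:
#' which resin and condition to run at each chromatographic step of a
#' purification sequence, and between which time intervals (cut-points) to
#' pool the eluate, so that target-protein yield and purity are jointly
#' maximized.
#'
#' The forward model assumes the load-collection ratio of every protein --
#' the fraction of its loaded mass recovered in a given interval -- is
#' constant across load amounts, which lets single-step screening data
#' predict multi-step trains.  Optimization is by the epsilon-constraint
#' method (purity bounded below, yield maximized) over a mixed-integer
#' linear fractional program solved with Dinkelbach's algorithm.
#'
#' @keywords internal
"_PACKAGE"

PHASES <- c("load", "wash", "elution", "regeneration")

#' Construct a gradient schedule
#'
#' A gradient schedule describes the phases of one chromatographic step and
#' the eluent salt concentration in each time interval.  Intervals are
#' 1-based and contiguous; phases must appear in the order load, wash,
#' elution, regeneration (any block may be empty) and the salt concentration
#' over the elution block must be non-decreasing (gradient elution).
#' `NA` salt entries are allowed outside the elution block and are resolved
#' by [effective_salt()].
#'
#' @param phase character vector, one of `"load"`, `"wash"`, `"elution"`,
#'   `"regeneration"` per interval, in interval order.
#' @param salt_mM numeric vector of eluent salt concentrations (mM NaCl);
#'   `NA` where the experiment defines none (load/wash/regeneration).
#' @return A `gradient_schedule` data frame with columns `interval`,
#'   `phase`, `salt_mM`.
#' @seealso [effective_salt()], [default_gradient()]
#' @export
gradient_schedule <- function(phase, salt_mM) {
  stopifnot(length(phase) == length(salt_mM), length(phase) >= 1L)
  g <- data.frame(
    interval = seq_along(phase),
    phase    = as.character(phase),
    salt_mM  = as.numeric(salt_mM),
    stringsAsFactors = FALSE
  )
  class(g) <- c("gradient_schedule", "data.frame")
  validate_gradient(g)
  g
}

validate_gradient <- function(g) {
  if (!all(g$phase %in% PHASES))
    stop("unknown phase label(s): ", paste(setdiff(g$phase, PHASES), collapse = ", "))
  if (!identical(g$interval, seq_len(nrow(g))))
    stop("interval indices must be contiguous 1..T")
  ord <- match(g$phase, PHASES)
  if (is.unsorted(ord))
    stop("phases must appear in order load, wash, elution, regeneration")
  el <- g$salt_mM[g$phase == "elution"]
  if (anyNA(el))
    stop("salt concentration must be defined on every elution interval")
  if (length(el) > 1L && is.unsorted(el))
    stop("elution salt gradient must be non-decreasing")
  if (any(g$salt_mM < 0, na.rm = TRUE))
    stop("salt concentrations must be non-negative")
  invisible(g)
}

#' Resolve undefined salt concentrations of a gradient schedule
#'
#' Salt-linking between consecutive steps compares the eluent salt
#' concentration at the upstream finishing cut-point with the downstream
#' starting cut-point, so every interval needs an orderable value.
#' Load and wash intervals without a recorded concentration sit before the
#' gradient and resolve to 0 mM; regeneration intervals carry the last
#' elution concentration forward; recorded values pass through unchanged.
#'
#' @param g a [gradient_schedule()].
#' @return Numeric vector of length `nrow(g)`: fully defined salt (mM).
#' @export
effective_salt <- function(g) {
  validate_gradient(g)
  salt <- g$salt_mM
  na <- is.na(salt)
  pre <- g$phase %in% c("load", "wash")
  salt[na & pre] <- 0
  if (any(na & !pre)) {
    el <- g$salt_mM[g$phase == "elution"]
    carry <- if (length(el)) el[length(el)] else 0
    salt[na & !pre] <- carry
  }
  names(salt) <- paste0("T", g$interval)
  salt
}

#' Assemble an HTS chromatography dataset
#'
#' The central container for a screening campaign: an ordered sequence of
#' chromatographic steps, candidate resins and operating conditions per
#' step, one loaded-mass / collected-mass record per (step, resin,
#' condition), and the gradient schedule of each step.
#'
#' @param steps character vector of step identifiers, in process order
#'   (first entry is the load step of the train, last is the polish step).
#' @param proteins character vector of protein species identifiers.
#' @param target identifier of the target protein (must be in `proteins`).
#' @param gradients named list (by step) of [gradient_schedule()] objects.
#' @param records named list (by step); each element is a list with
#'   \describe{
#'     \item{combos}{data frame with columns `resin`, `condition`, one row
#'       per tested (resin, condition) pair;}
#'     \item{lm}{numeric matrix `nrow(combos) x length(proteins)` of loaded
#'       mass (mg);}
#'     \item{cm}{numeric array `nrow(combos) x length(proteins) x T` of
#'       collected mass (mg) per time interval.}
#'   }
#' @return A validated `hts_dataset` object.
#' @seealso [read_hts_dataset()], [generate_hts()]
#' @export
hts_dataset <- function(steps, proteins, target, gradients, records) {
  ds <- structure(
    list(steps = as.character(steps), proteins = as.character(proteins),
         target = as.character(target), gradients = gradients,
         records = records),
    class = "hts_dataset"
  )
  validate_hts_dataset(ds)
  ds
}

#' Validate an HTS dataset
#'
#' Checks the structural invariants: at least one step; a gradient and a
#' record block per step; within a step every record shares the interval
#' count and protein set; all masses non-negative; every loaded mass
#' strictly positive; and per protein the total collected mass never
#' exceeds the loaded mass (no mass creation).
#'
#' @param ds an `hts_dataset`.
#' @param tol numeric slack on the mass-conservation check (mg).
#' @return `ds`, invisibly; errors describe the offending tuple.
#' @export
validate_hts_dataset <- function(ds, tol = 1e-8) {
  stopifnot(inherits(ds, "hts_dataset"))
  if (length(ds$steps) < 1L) stop("dataset needs at least one step")
  if (anyDuplicated(ds$steps)) stop("duplicated step ids")
  if (anyDuplicated(ds$proteins)) stop("duplicated protein ids")
  if (!ds$target %in% ds$proteins)
    stop("target protein '", ds$target, "' not among proteins")
  if (!setequal(names(ds$gradients), ds$steps))
    stop("gradients must be named by step id")
  if (!setequal(names(ds$records), ds$steps))
    stop("records must be named by step id")
  for (s in ds$steps) {
    g <- ds$gradients[[s]]
    validate_gradient(g)
    rec <- ds$records[[s]]
    nrc <- nrow(rec$combos)
    if (is.null(nrc) || nrc < 1L) stop("step ", s, ": no (resin, condition) record")
    key <- paste(rec$combos$resin, rec$combos$condition)
    if (anyDuplicated(key))
      stop("step ", s, ": duplicated (resin, condition) record: ",
           key[duplicated(key)][1L])
    np <- length(ds$proteins); Tn <- nrow(g)
    if (!identical(dim(rec$lm), c(nrc, np)))
      stop("step ", s, ": lm must be ", nrc, " x ", np)
    if (!identical(dim(rec$cm), c(nrc, np, Tn)))
      stop("step ", s, ": cm must be ", nrc, " x ", np, " x ", Tn,
           " (interval count must match the gradient)")
    if (any(rec$cm < 0)) {
      idx <- which(rec$cm < 0, arr.ind = TRUE)[1L, ]
      stop("step ", s, ": negative collected mass at (",
           key[idx[1L]], ", ", ds$proteins[idx[2L]], ", T", idx[3L], ")")
    }
    if (any(rec$lm <= 0)) {
      idx <- which(rec$lm <= 0, arr.ind = TRUE)[1L, ]
      stop("step ", s, ": loaded mass must be > 0 for every protein; (",
           key[idx[1L]], ", ", ds$proteins[idx[2L]], ") is not")
    }
    tot <- apply(rec$cm, c(1L, 2L), sum)
    bad <- tot > rec$lm + tol
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop("step ", s, ": collected mass exceeds loaded mass for (",
           key[idx[1L]], ", ", ds$proteins[idx[2L]], "): ",
           format(tot[idx[1L], idx[2L]]), " > ", format(rec$lm[idx[1L], idx[2L]]), " mg")
    }
  }
  invisible(ds)
}

#' @export
print.hts_dataset <- function(x, ...) {
  cat("HTS chromatography dataset\n")
  cat("  steps:   ", paste(x$steps, collapse = " -> "), "\n")
  cat("  proteins: ", paste(x$proteins, collapse = ", "),
      " (target: ", x$target, ")\n", sep = "")
  for (s in x$steps) {
    rec <- x$records[[s]]
    cat(sprintf("  %-6s %2d resin(s), %2d (resin, condition) pair(s), %2d intervals\n",
                s, length(unique(rec$combos$resin)), nrow(rec$combos),
                nrow(x$gradients[[s]])))
  }
  invisible(x)
}

#' Restrict a dataset to a subsequence of steps
#'
#' Used for single-step (or partial-train) optimization: the retained steps
#' become the process, the first retained step is treated as the load step.
#'
#' @param ds an `hts_dataset`.
#' @param steps character vector of step ids to keep, a contiguous
#'   subsequence of `ds$steps`.
#' @return A new `hts_dataset`.
#' @export
subset_steps <- function(ds, steps) {
  idx <- match(steps, ds$steps)
  if (anyNA(idx))
    stop("unknown step id(s): ", paste(steps[is.na(idx)], collapse = ", "))
  if (!identical(idx, seq(min(idx), max(idx))))
    stop("steps must be a contiguous subsequence of the process, in order")
  hts_dataset(steps, ds$proteins, ds$target,
              ds$gradients[steps], ds$records[steps])
}

n_intervals <- function(ds, s) nrow(ds$gradients[[s]])
n_combos    <- function(ds, s) nrow(ds$records[[s]]$combos)
target_idx  <- function(ds) match(ds$target, ds$proteins)

#' Compute load-collection ratios
#'
#' For every (step, resin, condition, protein, interval) the ratio
#' `lcr = cm / lm` of collected to loaded mass.  These ratios are the
#' dataset's calibration of each separation: under the constant-ratio
#' assumption a later-step load `LM` is predicted to elute `lcr * LM` in
#' each interval.
#'
#' @param ds an `hts_dataset`.
#' @return A `ratio_table`: list (by step) of arrays shaped like the `cm`
#'   arrays of `ds`, entries in `[0, 1]` and per-(resin, condition, protein)
#'   interval sums at most 1.
#' @export
compute_ratios <- function(ds) {
  validate_hts_dataset(ds)
  rt <- lapply(ds$steps, function(s) {
    rec <- ds$records[[s]]
    lm3 <- array(rec$lm, dim = dim(rec$cm))   # recycle over intervals
    bad <- lm3 == 0 & rec$cm > 0
    if (any(bad))
      stop("step ", s, ": collected mass with zero loaded mass; ratio undefined")
    lcr <- rec$cm / lm3
    lcr[lm3 == 0] <- 0
    lcr
  })
  names(rt) <- ds$steps
  structure(rt, class = "ratio_table")
}
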