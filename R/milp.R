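#' @title Abstract mixed-integer linear program container
#' @description A solver-agnostic MILP representation: named variables with
#'   bounds and integrality, linear constraints in sparse triplet form with
#'   a family label per row (so structural tests can count rows per
#'   constraint family), and a linear objective.  [solve_milp()] hands the
#'   model to a backend.
#' @name milp
NULL

#' Create an empty MILP model
#'
#' @return A `milp_model` environment.
#' @seealso [add_vars()], [add_constr()], [set_objective()], [solve_milp()]
#' @export
milp_model <- function() {
  m <- new.env(parent = emptyenv())
  m$name <- character()
  m$type <- character()        # "B" binary, "C" continuous
  m$lb <- m$ub <- numeric()
  m$index <- new.env(parent = emptyenv())
  m$con_idx <- list()          # variable ids per row
  m$con_coef <- list()
  m$con_sense <- character()   # "<=", "=", ">="
  m$con_rhs <- numeric()
  m$con_family <- character()
  m$obj <- NULL                # dense, set by set_objective
  m$maximize <- TRUE
  class(m) <- "milp_model"
  m
}

#' Add decision variables to a MILP model
#'
#' @param m a [milp_model()].
#' @param names unique variable names.
#' @param type `"B"` (binary) or `"C"` (continuous), recycled.
#' @param lb,ub bounds, recycled; binaries default to `[0, 1]`.
#' @return The variable ids (column indices), invisibly.
#' @export
add_vars <- function(m, names, type = "C", lb = 0, ub = Inf) {
  n <- length(names)
  type <- rep_len(type, n); lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  ids <- length(m$name) + seq_len(n)
  for (k in seq_len(n)) {
    if (!is.null(m$index[[names[k]]])) stop("duplicate variable: ", names[k])
    m$index[[names[k]]] <- ids[k]
  }
  m$name <- c(m$name, names)
  m$type <- c(m$type, type)
  m$lb <- c(m$lb, lb)
  m$ub <- c(m$ub, ub)
  invisible(ids)
}

#' Look up variable ids by name
#' @param m a [milp_model()].
#' @param names variable names.
#' @return Integer column indices.
#' @export
var_id <- function(m, names) {
  ids <- vapply(names, function(nm) {
    v <- m$index[[nm]]
    if (is.null(v)) stop("unknown variable: ", nm)
    v
  }, 0L, USE.NAMES = FALSE)
  ids
}

#' Add a linear constraint
#'
#' @param m a [milp_model()].
#' @param ids variable ids of the nonzero coefficients.
#' @param coefs coefficients, same length as `ids`.
#' @param sense `"<="`, `"="` or `">="`.
#' @param rhs right-hand side.
#' @param family label naming the constraint family the row belongs to.
#' @return Row index, invisibly.
#' @export
add_constr <- function(m, ids, coefs, sense, rhs, family = "c") {
  stopifnot(length(ids) == length(coefs), sense %in% c("<=", "=", ">="))
  k <- length(m$con_sense) + 1L
  m$con_idx[[k]] <- as.integer(ids)
  m$con_coef[[k]] <- as.numeric(coefs)
  m$con_sense[k] <- sense
  m$con_rhs[k] <- rhs
  m$con_family[k] <- family
  invisible(k)
}

#' Set the linear objective
#'
#' @param m a [milp_model()].
#' @param ids,coefs nonzero objective terms.
#' @param maximize logical.
#' @export
set_objective <- function(m, ids, coefs, maximize = TRUE) {
  obj <- numeric(length(m$name))
  obj[ids] <- coefs
  m$obj <- obj
  m$maximize <- maximize
  invisible(m)
}

#' Count constraint rows per family
#' @param m a [milp_model()].
#' @return Named integer vector of row counts.
#' @export
constraint_families <- function(m) {
  c(table(m$con_family))
}

#' @export
print.milp_model <- function(x, ...) {
  cat("MILP model:", length(x$name), "variables (",
      sum(x$type == "B"), "binary ),", length(x$con_sense), "constraints\n")
  fam <- constraint_families(x)
  for (f in names(fam)) cat(sprintf("  %-10s %5d rows\n", f, fam[f]))
  invisible(x)
}

#' Fix a variable to a value (equal bounds)
#'
#' Used by structural tests to enumerate integer fixings.
#'
#' @param m a [milp_model()].
#' @param names variable names.
#' @param values values, recycled.
#' @export
fix_vars <- function(m, names, values) {
  ids <- var_id(m, names)
  values <- rep_len(values, length(ids))
  m$lb[ids] <- values
  m$ub[ids] <- values
  invisible(m)
}

# serialize to the backend request shape.  `obj_scale` multiplies the
# objective (undone by the helper when reporting the optimum): HiGHS
# prunes branch-and-bound nodes within an absolute MIP gap of 1e-6 that
# scipy does not expose, so callers whose objectives sit near that scale
# can scale up.  Models from build_model() already place masses around
# 1e4, making the absolute gap ~1e-10 relative, so no extra scaling is
# applied by default.
milp_request <- function(m, gap = 0, time_limit = NULL, obj_scale = 1) {
  stopifnot(!is.null(m$obj))
  nnz <- lengths(m$con_idx)
  i <- rep(seq_along(m$con_idx), nnz)
  j <- unlist(m$con_idx, use.names = FALSE)
  x <- unlist(m$con_coef, use.names = FALSE)
  rlb <- ifelse(m$con_sense == "<=", -Inf, m$con_rhs)
  rub <- ifelse(m$con_sense == ">=", Inf, m$con_rhs)
  list(cmd = "solve", ncol = length(m$name), obj = m$obj * obj_scale,
       obj_scale = obj_scale,
       maximize = m$maximize, lb = m$lb, ub = m$ub,
       integer = as.integer(m$type == "B"),
       i = i, j = j, x = x, rlb = as.numeric(rlb), rub = as.numeric(rub),
       gap = gap, time_limit = time_limit)
}
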