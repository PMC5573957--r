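#' @title MILP solver backend
#' @description Models built with [milp_model()] are solved by the HiGHS
#'   solver through `scipy.optimize.milp`, driven by the bundled helper
#'   script `inst/python/milp_server.py`.  By default a persistent worker
#'   process is kept alive over a local socket so that repeated small
#'   solves (Dinkelbach iterations, epsilon sweeps, structural tests) do
#'   not pay interpreter start-up per solve; `persistent = FALSE` falls
#'   back to one subprocess per solve.
#' @name backend
NULL

.solver <- new.env(parent = emptyenv())

python_bin <- function() {
  p <- getOption("resinopt.python", Sys.getenv("RESINOPT_PYTHON", "python"))
  if (Sys.which(p) == "" && !file.exists(p))
    stop("python interpreter not found (looked for '", p,
         "'); set options(resinopt.python=...) or RESINOPT_PYTHON")
  p
}

server_script <- function() {
  f <- system.file("python", "milp_server.py", package = "resinopt")
  if (f == "") f <- file.path("inst", "python", "milp_server.py")
  if (!file.exists(f)) stop("milp_server.py not found")
  normalizePath(f)
}

worker_start <- function() {
  script <- server_script()
  srv <- NULL
  for (port in sample(20000:49152, 32L)) {
    srv <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(srv)) break
  }
  if (is.null(srv)) stop("could not open a local port for the MILP worker")
  logf <- file.path(tempdir(), "resinopt-milp-worker.log")
  system2(python_bin(), c(shQuote(script), "--connect", port),
          stdout = logf, stderr = logf, wait = FALSE)
  con <- tryCatch(
    socketAccept(srv, blocking = TRUE, open = "r+", timeout = 60),
    error = function(e) NULL)
  close(srv)
  if (is.null(con))
    stop("MILP worker failed to connect; see ", logf)
  ready <- readLines(con, n = 1L)
  if (!length(ready) || !grepl("ready", ready)) {
    close(con)
    stop("MILP worker failed to start; see ", logf)
  }
  .solver$con <- con
  invisible(con)
}

worker_call <- function(req_json) {
  if (is.null(.solver$con)) worker_start()
  ans <- tryCatch({
    writeLines(req_json, .solver$con)
    flush(.solver$con)
    readLines(.solver$con, n = 1L)
  }, error = function(e) character())
  if (!length(ans)) {           # worker died: restart once and retry
    solver_stop()
    worker_start()
    writeLines(req_json, .solver$con)
    flush(.solver$con)
    ans <- readLines(.solver$con, n = 1L)
    if (!length(ans)) stop("MILP worker not responding")
  }
  ans
}

#' Shut down the persistent MILP worker
#'
#' Called automatically when the package unloads; safe to call any time.
#' @export
solver_stop <- function() {
  if (!is.null(.solver$con)) {
    tryCatch({
      writeLines('{"cmd":"quit"}', .solver$con)
      flush(.solver$con)
    }, error = function(e) NULL)
    tryCatch(close(.solver$con), error = function(e) NULL)
    .solver$con <- NULL
  }
  invisible(NULL)
}

.onUnload <- function(libpath) solver_stop()

subprocess_call <- function(req_json) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(req_json, fin)
  st <- system2(python_bin(),
                c(shQuote(server_script()), "--one-shot", shQuote(fin), shQuote(fout)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L || !file.exists(fout)) stop("MILP subprocess failed (exit ", st, ")")
  readLines(fout, warn = FALSE)
}

#' Solve a MILP model
#'
#' @param m a [milp_model()] with an objective set.
#' @param gap relative MIP optimality gap; 0 demands a proven optimum.
#' @param time_limit wall-clock limit in seconds, or `NULL`.
#' @param persistent use the persistent worker (default) or a fresh
#'   subprocess per call.
#' @return A `milp_solution` list: `status` (`"optimal"`, `"infeasible"`,
#'   `"limit"`, `"unbounded"`), `objective`, and `values` -- a named
#'   numeric vector over the model's variables (absent unless a solution
#'   was found).
#' @export
solve_milp <- function(m, gap = 0, time_limit = NULL, persistent = TRUE) {
  req <- milp_request(m, gap = gap, time_limit = time_limit)
  req_json <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA,
                               null = "null")
  ans <- if (persistent) worker_call(req_json) else subprocess_call(req_json)
  res <- jsonlite::fromJSON(ans, simplifyVector = TRUE)
  if (identical(res$status, "error"))
    stop("MILP backend error: ", res$message)
  out <- list(status = res$status, objective = res$objective)
  if (!is.null(res$x)) {
    v <- as.numeric(res$x)
    names(v) <- m$name
    out$values <- v
  }
  structure(out, class = "milp_solution")
}
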