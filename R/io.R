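#' Read an HTS dataset from CSV tables
#'
#' Expects the plain-text exchange layout:
#' \describe{
#'   \item{conditions.csv}{`step,resin,condition,protein,loaded_mass_mg` --
#'     one row per (step, resin, condition, protein);}
#'   \item{collected.csv}{`step,resin,condition,protein,interval,collected_mass_mg`
#'     -- long format, missing (protein, interval) rows read as 0 mg;}
#'   \item{gradient.csv}{`step,interval,phase,salt_mM` -- empty `salt_mM`
#'     means no recorded concentration;}
#'   \item{config.yaml}{keys `target_protein`, `step_order`, optional
#'     `solver` settings block.}
#' }
#'
#' @param dir directory containing the four files, or `NULL` when the
#'   individual paths are given.
#' @param conditions,collected,gradient,config individual file paths
#'   (override `dir`).
#' @return A validated [hts_dataset()]; the parsed config is attached as
#'   attribute `"config"`.
#' @export
read_hts_dataset <- function(dir = NULL, conditions = NULL, collected = NULL,
                             gradient = NULL, config = NULL) {
  pick <- function(given, name) {
    if (!is.null(given)) given
    else if (!is.null(dir)) file.path(dir, name)
    else stop("either `dir` or `", sub("\\..*$", "", name), "` must be given")
  }
  f_cond <- pick(conditions, "conditions.csv")
  f_coll <- pick(collected, "collected.csv")
  f_grad <- pick(gradient, "gradient.csv")
  f_conf <- pick(config, "config.yaml")
  for (f in c(f_cond, f_coll, f_grad, f_conf))
    if (!file.exists(f)) stop("input file not found: ", f)

  cfg <- yaml::read_yaml(f_conf)
  if (is.null(cfg$target_protein)) stop("config.yaml must set target_protein")
  cond <- utils::read.csv(f_cond, stringsAsFactors = FALSE)
  coll <- utils::read.csv(f_coll, stringsAsFactors = FALSE)
  grad <- utils::read.csv(f_grad, stringsAsFactors = FALSE)
  need <- function(df, cols, file)
    if (!all(cols %in% names(df)))
      stop(file, " must have columns ", paste(cols, collapse = ", "))
  need(cond, c("step", "resin", "condition", "protein", "loaded_mass_mg"), f_cond)
  need(coll, c("step", "resin", "condition", "protein", "interval",
               "collected_mass_mg"), f_coll)
  need(grad, c("step", "interval", "phase", "salt_mM"), f_grad)

  steps <- as.character(if (!is.null(cfg$step_order)) cfg$step_order
                        else unique(grad$step))
  proteins <- sort(unique(cond$protein))

  gradients <- lapply(steps, function(s) {
    g <- grad[grad$step == s, , drop = FALSE]
    if (!nrow(g)) stop("gradient.csv has no rows for step ", s)
    g <- g[order(g$interval), ]
    if (!identical(as.integer(g$interval), seq_len(nrow(g))))
      stop("step ", s, ": gradient intervals must be contiguous 1..T")
    gradient_schedule(g$phase, suppressWarnings(as.numeric(g$salt_mM)))
  })
  names(gradients) <- steps

  records <- lapply(steps, function(s) {
    cn <- cond[cond$step == s, , drop = FALSE]
    if (!nrow(cn)) stop("conditions.csv has no rows for step ", s)
    combos <- unique(cn[, c("resin", "condition")])
    combos <- combos[order(combos$resin, combos$condition), , drop = FALSE]
    rownames(combos) <- NULL
    Tn <- nrow(gradients[[s]])
    nrc <- nrow(combos); np <- length(proteins)
    lm <- matrix(NA_real_, nrc, np, dimnames = list(NULL, proteins))
    cm <- array(0, c(nrc, np, Tn))
    ckey <- paste(combos$resin, combos$condition)
    i <- match(paste(cn$resin, cn$condition), ckey)
    j <- match(cn$protein, proteins)
    lm[cbind(i, j)] <- cn$loaded_mass_mg
    if (anyNA(lm)) {
      miss <- which(is.na(lm), arr.ind = TRUE)[1L, ]
      stop("step ", s, ": missing loaded mass for (", ckey[miss[1L]], ", ",
           proteins[miss[2L]], ")")
    }
    cl <- coll[coll$step == s, , drop = FALSE]
    if (nrow(cl)) {
      ii <- match(paste(cl$resin, cl$condition), ckey)
      if (anyNA(ii))
        stop("step ", s, ": collected.csv names unknown (resin, condition): ",
             paste(cl$resin[is.na(ii)][1L], cl$condition[is.na(ii)][1L]))
      jj <- match(cl$protein, proteins)
      if (anyNA(jj))
        stop("step ", s, ": collected.csv names unknown protein: ",
             cl$protein[is.na(jj)][1L])
      tt <- as.integer(cl$interval)
      if (any(tt < 1L | tt > Tn))
        stop("step ", s, ": collected.csv interval outside 1..", Tn)
      cm[cbind(ii, jj, tt)] <- cm[cbind(ii, jj, tt)] + cl$collected_mass_mg
    }
    list(combos = combos, lm = lm, cm = cm)
  })
  names(records) <- steps

  ds <- hts_dataset(steps, proteins, as.character(cfg$target_protein),
                    gradients, records)
  attr(ds, "config") <- cfg
  ds
}

#' Write an HTS dataset as CSV tables
#'
#' Inverse of [read_hts_dataset()]: writes `conditions.csv`,
#' `collected.csv` (zero-mass rows omitted), `gradient.csv` and
#' `config.yaml` into `dir`.
#'
#' @param ds an `hts_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_hts_dataset <- function(ds, dir) {
  validate_hts_dataset(ds)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cond <- do.call(rbind, lapply(ds$steps, function(s) {
    rec <- ds$records[[s]]
    np <- length(ds$proteins)
    data.frame(step = s,
               resin = rep(rec$combos$resin, times = np),
               condition = rep(rec$combos$condition, times = np),
               protein = rep(ds$proteins, each = nrow(rec$combos)),
               loaded_mass_mg = as.vector(rec$lm))
  }))
  coll <- do.call(rbind, lapply(ds$steps, function(s) {
    rec <- ds$records[[s]]
    nz <- which(rec$cm != 0, arr.ind = TRUE)
    if (!nrow(nz)) return(NULL)
    data.frame(step = s,
               resin = rec$combos$resin[nz[, 1L]],
               condition = rec$combos$condition[nz[, 1L]],
               protein = ds$proteins[nz[, 2L]],
               interval = nz[, 3L],
               collected_mass_mg = rec$cm[nz])
  }))
  grad <- do.call(rbind, lapply(ds$steps, function(s) {
    g <- ds$gradients[[s]]
    data.frame(step = s, interval = g$interval, phase = g$phase,
               salt_mM = g$salt_mM)
  }))
  ordc <- order(coll$step, coll$resin, coll$condition, coll$protein, coll$interval)
  utils::write.csv(cond, file.path(dir, "conditions.csv"), row.names = FALSE)
  utils::write.csv(coll[ordc, ], file.path(dir, "collected.csv"), row.names = FALSE)
  utils::write.csv(grad, file.path(dir, "gradient.csv"), row.names = FALSE)
  yaml::write_yaml(list(target_protein = ds$target,
                        step_order = as.list(ds$steps)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
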