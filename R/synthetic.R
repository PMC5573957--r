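#' Canonical two-step gradient templates
#'
#' Interval/phase/salt layouts of the two screening formats the package
#' emulates: a bind-elute cation-exchange (CEX) run over 17 intervals with
#' a 0--300 mM NaCl gradient, and a flow-through mixed-mode (MM) run over
#' 29 intervals with a 0--1000 mM gradient followed by two regeneration
#' intervals.  Both formats load in T1--T2, wash in T3 and start the
#' gradient at T4; salt is unrecorded (NA) outside the elution block.
#'
#' @param type `"CEX"` or `"MM"`.
#' @return A [gradient_schedule()].
#' @export
default_gradient <- function(type = c("CEX", "MM")) {
  type <- match.arg(type)
  if (type == "CEX") {
    gradient_schedule(
      phase   = c("load", "load", "wash", rep("elution", 14L)),
      salt_mM = c(NA, NA, NA,
                  0, 0, 50, 50, 100, 100, 150, 150, 200, 200, 250, 250, 300, 300)
    )
  } else {
    gradient_schedule(
      phase   = c("load", "load", "wash", rep("elution", 24L),
                  "regeneration", "regeneration"),
      salt_mM = c(NA, NA, NA,
                  0, 0, 50, 50, 100, 100, 200, 200, 300, 300, 400, 400,
                  500, 500, 600, 600, 700, 700, 800, 800, 900, 900, 1000, 1000,
                  NA, NA)
    )
  }
}

#' Specify a synthetic HTS screening campaign
#'
#' Describes the shape and chemistry of a campaign to be generated by
#' [generate_hts()]: the step layout (resins, conditions per resin,
#' gradient), the protein mixture (load fractions, elution-center salt and
#' peak width per species), the recovered fraction of each load, and the
#' fraction lost to flow-through during load/wash.
#'
#' Elution is modelled as a Gaussian peak in salt concentration -- the
#' standard idealization of gradient chromatography -- discretized onto the
#' gradient's elution intervals; resin/condition identity perturbs peak
#' centers and widths multiplicatively so that no condition dominates by
#' construction.
#'
#' @param steps list of step descriptors: each a list with `id`,
#'   `n_resins`, `conditions_per_resin` (scalar or vector of length
#'   `n_resins`) and `gradient` (a [gradient_schedule()]).
#' @param proteins data frame with columns `name`, `fraction` (load
#'   fractions summing to 1), `center_mM` (elution-peak center),
#'   `width_mM` (peak standard deviation).
#' @param target name of the target protein.
#' @param recovery fraction of each loaded mass recovered over the run,
#'   in (0, 1].
#' @param flowthrough_frac fraction of the recovered mass appearing in the
#'   load/wash intervals rather than the elution peak, in [0, 1).
#' @param total_load_mg total protein mass loaded per experiment (mg).
#' @param condition_sd log-scale standard deviation of the per-(resin,
#'   condition, protein) multiplicative perturbation of peak centers and
#'   widths.
#' @param weight_floor quantification limit of the emulated assay,
#'   expressed as a fraction of a protein's recovered mass: elution-peak
#'   weights below it are reported as exactly zero (real HPLC tables
#'   contain zeros below the limit of quantification, not
#'   arbitrarily small tail masses), and the remaining weights are
#'   renormalized so the recovered total is unchanged.
#' @param seed default RNG seed used by [generate_hts()].
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(steps, proteins, target = proteins$name[1L],
                           recovery = 0.95, flowthrough_frac = 0.02,
                           total_load_mg = 10, condition_sd = 0.08,
                           weight_floor = 1e-6, seed = 1L) {
  stopifnot(is.list(steps), length(steps) >= 1L,
            is.data.frame(proteins),
            all(c("name", "fraction", "center_mM", "width_mM") %in% names(proteins)),
            recovery > 0, recovery <= 1,
            flowthrough_frac >= 0, flowthrough_frac < 1,
            total_load_mg > 0, condition_sd >= 0)
  if (abs(sum(proteins$fraction) - 1) > 1e-9)
    stop("protein load fractions must sum to 1")
  if (any(proteins$fraction <= 0)) stop("protein load fractions must be > 0")
  if (any(proteins$width_mM <= 0)) stop("peak widths must be > 0")
  if (!target %in% proteins$name) stop("target must be one of the proteins")
  for (st in steps) {
    stopifnot(!is.null(st$id), !is.null(st$n_resins),
              !is.null(st$conditions_per_resin))
    validate_gradient(st$gradient)
  }
  stopifnot(weight_floor >= 0, weight_floor < 1)
  structure(list(steps = steps, proteins = proteins, target = target,
                 recovery = recovery, flowthrough_frac = flowthrough_frac,
                 total_load_mg = total_load_mg, condition_sd = condition_sd,
                 weight_floor = weight_floor, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Two-step CEX + MM campaign template
#'
#' The default synthetic campaign mirrors the structure of an industrial
#' Fc-fusion polishing screen: a CEX step with 8 candidate resins at 2
#' operating conditions each over 17 intervals, followed by an MM step with
#' 3 resins at 7, 8 and 12 conditions over 29 intervals, gradients per
#' [default_gradient()], and a three-species mixture loading 86.2% monomer
#' (target), 10.6% aggregates and 3.2% fragments.
#'
#' @param seed default RNG seed for [generate_hts()].
#' @param ... overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
preset_cex_mm <- function(seed = 1L, ...) {
  steps <- list(
    list(id = "CEX", n_resins = 8L, conditions_per_resin = 2L,
         gradient = default_gradient("CEX")),
    list(id = "MM", n_resins = 3L, conditions_per_resin = c(7L, 8L, 12L),
         gradient = default_gradient("MM"))
  )
  proteins <- data.frame(
    name      = c("monomer", "aggregate", "fragment"),
    fraction  = c(0.862, 0.106, 0.032),
    center_mM = c(150, 260, 60),
    width_mM  = c(40, 50, 35)
  )
  synthetic_spec(steps = steps, proteins = proteins, target = "monomer",
                 seed = seed, ...)
}

#' Adjust separation difficulty of a synthetic spec
#'
#' Re-centers every impurity's elution peak at `delta_salt` mM from the
#' target's center (alternating above/below).  `delta_salt = 0` makes all
#' species co-elute -- purity can then never exceed the load purity --
#' while large values make near-baseline separation possible.
#'
#' @param spec a `synthetic_spec`.
#' @param delta_salt non-negative offset (mM) between target and impurity
#'   peak centers.
#' @return The modified `synthetic_spec`.
#' @export
separability_knob <- function(spec, delta_salt) {
  stopifnot(inherits(spec, "synthetic_spec"), delta_salt >= 0)
  p <- spec$proteins
  tgt <- p$center_mM[p$name == spec$target]
  imp <- which(p$name != spec$target)
  sgn <- rep_len(c(1, -1), length(imp))
  p$center_mM[imp] <- tgt + sgn * delta_salt
  spec$proteins <- p
  spec
}

#' Generate a synthetic HTS dataset
#'
#' Draws a complete screening campaign from a [synthetic_spec()]: for each
#' (step, resin, condition, protein) the loaded mass is
#' `total_load_mg * fraction`, and the collected-mass profile places
#' `recovery * (1 - flowthrough_frac)` of the load on the elution intervals
#' as a discretized Gaussian in effective salt (center and width perturbed
#' per resin/condition) and `recovery * flowthrough_frac` uniformly over
#' the load/wash intervals.  Deterministic for a fixed seed.
#'
#' @param spec a `synthetic_spec`.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A validated [hts_dataset()].
#' @export
generate_hts <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  proteins <- spec$proteins$name
  steps <- vapply(spec$steps, `[[`, "", "id")
  gradients <- lapply(spec$steps, `[[`, "gradient")
  names(gradients) <- steps

  records <- lapply(spec$steps, function(st) {
    g <- st$gradient
    Tn <- nrow(g)
    salt <- effective_salt(g)
    el <- which(g$phase == "elution")
    ft_iv <- which(g$phase %in% c("load", "wash"))
    ncond <- rep_len(st$conditions_per_resin, st$n_resins)
    combos <- data.frame(
      resin = rep(paste0("R", st$id, seq_len(st$n_resins)), times = ncond),
      condition = unlist(lapply(seq_len(st$n_resins), function(r)
        paste0("C", st$id, r, "-", seq_len(ncond[r]))))
    )
    nrc <- nrow(combos); np <- length(proteins)
    lm <- matrix(rep(spec$total_load_mg * spec$proteins$fraction, each = nrc),
                 nrc, np, dimnames = list(NULL, proteins))
    cm <- array(0, c(nrc, np, Tn))
    ft <- if (length(ft_iv)) spec$flowthrough_frac else 0
    for (i in seq_len(nrc)) {
      # one multiplicative perturbation per (resin, condition), shared by
      # all proteins: condition chemistry shifts the whole chromatogram,
      # so species with identical peak parameters stay indistinguishable
      cf <- exp(stats::rnorm(1L, 0, spec$condition_sd))
      wf <- exp(stats::rnorm(1L, 0, spec$condition_sd))
      for (j in seq_len(np)) {
        center <- spec$proteins$center_mM[j] * cf
        width <- spec$proteins$width_mM[j] * wf
        w <- exp(-((salt[el] - center)^2) / (2 * width^2))
        w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(el), length(el))
        # below the assay's quantification limit nothing is reported
        keep <- w >= spec$weight_floor
        if (!any(keep)) keep <- w == max(w)
        w[!keep] <- 0
        w <- w / sum(w)
        mass <- spec$recovery * lm[i, j]
        cm[i, j, el] <- (1 - ft) * mass * w
        if (length(ft_iv)) cm[i, j, ft_iv] <- ft * mass / length(ft_iv)
      }
    }
    list(combos = combos, lm = lm, cm = cm)
  })
  names(records) <- steps

  hts_dataset(steps, proteins, spec$target, gradients, records)
}
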