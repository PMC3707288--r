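## Configuration: defaults, YAML round trip, validation.

.CONFIG_KEYS <- c(target_energy = "targetEnergy", temperature = "temperature",
                  mu_E = "muE", mu_K = "muK", delta = "delta",
                  P_schedule = "PSchedule", seed = "seed",
                  grad_tol = "gradTol", max_iter = "maxIter",
                  anneal_decrement = "annealDecrement",
                  conservation_tol = "conservationTol", fix_tau = "fixTau",
                  k_B = "kB")

#' Construct an ADMD configuration
#'
#' Every unset field takes a documented default.  The target energy and
#' temperature default to 0 and must normally be chosen per problem (see
#' [annealTargetEnergy()] for estimating the target energy).  `muE = NA`
#' and (when a positive temperature is set) `muK = NA` are resolved at run
#' time so each penalty term starts about two orders of magnitude above the
#' classical action, per [resolvePenaltyWeights()].
#'
#' @param targetEnergy target total energy E.
#' @param temperature fictitious temperature of the kinetic restraint.
#' @param muE energy-penalty weight (`NA` = automatic; must be positive).
#' @param muK kinetic-restraint weight (0 disables; `NA` = automatic).
#' @param delta time step at the first frame count.
#' @param PSchedule increasing frame counts (default: doubling from 20 to
#'   1280, then 2000).
#' @param seed integer seed for all randomness.
#' @param gradTol L-BFGS projected-gradient max-norm tolerance.
#' @param maxIter iteration cap per multigrid level.
#' @param annealDecrement target-energy step of the annealing protocol
#'   (`NA` = 5 percent of the initial energy gap).
#' @param conservationTol accepted `sd(E_j)` relative to
#'   `max(|E|, barrier)`.
#' @param fixTau hold the duration fixed during refinement?
#' @param kB Boltzmann constant (1 in model units).
#' @return an [ADMDConfig].
#' @export
admdConfig <- function(targetEnergy = 0, temperature = 0, muE = NA_real_,
                       muK = 0, delta = 0.05,
                       PSchedule = multigridSchedule(20L, 2000L),
                       seed = 1L, gradTol = 1e-6, maxIter = 500L,
                       annealDecrement = NA_real_, conservationTol = 0.01,
                       fixTau = TRUE, kB = 1) {
  new("ADMDConfig", targetEnergy = as.numeric(targetEnergy),
      temperature = as.numeric(temperature), muE = as.numeric(muE),
      muK = as.numeric(muK), delta = as.numeric(delta),
      PSchedule = as.integer(PSchedule), seed = as.integer(seed),
      gradTol = as.numeric(gradTol), maxIter = as.integer(maxIter),
      annealDecrement = as.numeric(annealDecrement),
      conservationTol = as.numeric(conservationTol),
      fixTau = as.logical(fixTau), kB = as.numeric(kB))
}

#' Load / save a configuration file
#'
#' YAML key-value files with snake_case keys (`target_energy`, `mu_E`,
#' `P_schedule`, ...).  Unknown keys are rejected with the offending name;
#' an empty file yields all defaults.  An optional `potential` key (surface
#' name for [potentialByName()]) and `potential_params` mapping are carried
#' on the returned object as attributes.
#'
#' @param file YAML file path.
#' @return an [ADMDConfig] (with optional `potential` /`potentialParams`
#'   attributes).
#' @export
loadConfig <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  vals <- yaml::read_yaml(file)
  if (is.null(vals)) vals <- list()
  extra <- intersect(names(vals), c("potential", "potential_params"))
  unknown <- setdiff(names(vals), c(names(.CONFIG_KEYS), extra))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- vals[names(vals) %in% names(.CONFIG_KEYS)]
  names(args) <- .CONFIG_KEYS[names(args)]
  cfg <- do.call(admdConfig, args)
  if ("potential" %in% extra) attr(cfg, "potential") <- vals$potential
  if ("potential_params" %in% extra)
    attr(cfg, "potentialParams") <- vals$potential_params
  cfg
}

#' @rdname loadConfig
#' @param config an [ADMDConfig].
#' @export
dumpConfig <- function(config, file) {
  vals <- lapply(setNames(names(.CONFIG_KEYS), names(.CONFIG_KEYS)),
                 function(k) slot(config, .CONFIG_KEYS[[k]]))
  vals <- vals[!vapply(vals, function(v) length(v) == 1L && is.na(v),
                       logical(1))]
  yaml::write_yaml(vals, file)
  invisible(file)
}
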