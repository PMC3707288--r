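## Target-energy annealing: repeated action minimizations with a stepwise
## lowered target energy E, each warm-started from the previous solution.
## The accepted E is the smallest for which the optimized path still
## conserves total energy; pushing E below the physically attainable value
## makes the frame-energy spread blow up, which is the stop signal.

#' Anneal the target energy downward
#'
#' Starting from an overestimated target energy `EStart`, runs
#' [minimizePhi()], then repeatedly lowers the target by the annealing
#' decrement and re-optimizes, warm-starting each run from the previous
#' solution path.  Stops at the first run that fails the energy-conservation
#' tolerance (or after `maxSteps` runs) and returns the solution at the
#' smallest conserving target energy together with the full annealing
#' record.
#'
#' @param q0,qP endpoint conformations.
#' @param surface a [PotentialSurface].
#' @param config an [ADMDConfig]; its `targetEnergy` is overridden by the
#'   annealing sequence.  An `NA` `annealDecrement` resolves to 5 percent of
#'   the gap between `EStart` and the higher endpoint potential energy.
#' @param EStart initial (overestimated) target energy; must exceed both
#'   endpoint potential energies.
#' @param amplitude amplitude of the seeded random trial path used for the
#'   first run (0 = straight line).
#' @param start optional explicit starting [Path] (overrides the random
#'   trial construction).
#' @param maxSteps cap on the number of annealing runs.
#' @param masses,adim,system forwarded to the trial-path constructor.
#' @return list with `best` (the [PathwaySolution] at the smallest
#'   conserving E, or `NULL`), `record` (data.frame with columns `E`,
#'   `conserved`, `barrier`, `phi`, `energyStd`), and `decrement`.
#' @export
annealTargetEnergy <- function(q0, qP, surface, config, EStart,
                               amplitude = 0, start = NULL, maxSteps = 60L,
                               masses = NULL, adim = NULL, system = NULL) {
  vEnd <- c(evaluateSurface(surface, q0)$energy,
            evaluateSurface(surface, qP)$energy)
  if (EStart <= max(vEnd))
    stop("EStart (", signif(EStart, 6),
         ") must exceed both endpoint potential energies (max ",
         signif(max(vEnd), 6), ")")
  dec <- config@annealDecrement
  if (is.na(dec)) dec <- 0.05 * (EStart - max(vEnd))
  if (is.null(start))
    start <- randomTrialPath(q0, qP, P = config@PSchedule[1L],
                             seed = config@seed, amplitude = amplitude,
                             delta = config@delta, masses = masses,
                             adim = adim, system = system)
  record <- data.frame(E = numeric(0), conserved = logical(0),
                       barrier = numeric(0), phi = numeric(0),
                       energyStd = numeric(0))
  best <- NULL
  E <- EStart
  path <- start
  cfg <- config
  for (step in seq_len(maxSteps)) {
    cfg@targetEnergy <- E
    sol <- minimizePhi(path, surface, cfg)
    cfg <- sol@config                       # penalty weights resolved once
    record[nrow(record) + 1L, ] <-
      list(E, sol@energyConserved, sol@barrier, sol@breakdown@phi,
           stats::sd(sol@breakdown@frameEnergies))
    if (!sol@energyConserved) {
      if (step == 1L)
        stop("EStart too low: the first annealing run already fails ",
             "energy conservation")
      break
    }
    best <- sol
    path <- sol@path                        # warm start for the next E
    E <- E - dec
  }
  list(best = best, record = record, decrement = dec)
}
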