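## Multiple independent ADMD runs from randomly seeded trial pathways —
## the protocol used to separate robust folding features from artifacts of
## any single trial path: if the runs agree, their common observable trends
## are properties of the energy landscape, not of the initialization.

#' Seeded multi-run folding campaign
#'
#' Runs [minimizePhi()] once per seed, each from its own random trial path
#' between the same endpoints, and (when a system and native structure are
#' supplied) collects the per-frame observable tables plus the pairwise
#' correlation of the native-contact and hydrogen-bond fraction traces
#' across runs.  Consistently positive pairwise correlations mean the runs
#' share one folding sequence despite independent random starts.
#'
#' @param q0,qP endpoint conformations (disordered and native, typically).
#' @param surface a [PotentialSurface].
#' @param config an [ADMDConfig]; `NA` penalty weights are resolved per run
#'   on that run's trial path with `penaltyFactor`.
#' @param seeds integer vector, one independent run per seed.
#' @param amplitude trial-path randomness amplitude.
#' @param penaltyFactor forwarded to [resolvePenaltyWeights()].
#' @param system a [MolecularSystem] (enables the observable tables).
#' @param native native conformation for contact/H-bond fractions.
#' @return list with `solutions` (one [PathwaySolution] per seed), `tables`
#'   (per-run observable data.frames, or `NULL`), `contactCor` / `hbondCor`
#'   (matrices of pairwise trace correlations), and `conservedRuns`.
#' @export
foldingCampaign <- function(q0, qP, surface, config, seeds, amplitude = 1,
                            penaltyFactor = 1000, system = NULL,
                            native = NULL) {
  solutions <- vector("list", length(seeds))
  tables <- if (!is.null(system) && !is.null(native))
    vector("list", length(seeds)) else NULL
  for (i in seq_along(seeds)) {
    start <- randomTrialPath(q0, qP, P = config@PSchedule[1L],
                             seed = seeds[i], amplitude = amplitude,
                             delta = config@delta,
                             masses = if (!is.null(system)) system@masses,
                             adim = if (!is.null(system)) 3L,
                             system = system)
    cfg <- resolvePenaltyWeights(start, surface, config,
                                 factor = penaltyFactor)
    solutions[[i]] <- minimizePhi(start, surface, cfg)
    if (!is.null(tables))
      tables[[i]] <- pathwayReport(solutions[[i]]@path, native,
                                   system)$table
  }
  corOf <- function(col) {
    if (is.null(tables)) return(NULL)
    n <- length(tables)
    M <- diag(1, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      M[i, j] <- M[j, i] <- stats::cor(tables[[i]][[col]],
                                       tables[[j]][[col]])
    M
  }
  list(solutions = solutions, tables = tables,
       contactCor = corOf("contactFraction"),
       hbondCor = corOf("hbondFraction"),
       conservedRuns = sum(vapply(solutions, slot, logical(1),
                                  "energyConserved")))
}
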