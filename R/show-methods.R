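#' @describeIn newPath compact display
#' @param object object to display
#' @export
setMethod("show", "Path", function(object) {
  cat(sprintf("Path: P = %d (%d frames), %d coordinates (%d atoms x %d), ",
              frameCount(object), nrow(object@frames), ncol(object@frames),
              length(object@masses), object@adim),
      sprintf("delta = %g, tau = %g\n", object@delta, pathDuration(object)))
})

setMethod("show", "MolecularSystem", function(object) {
  cat(sprintf("MolecularSystem: %d atoms, %d residues (%s)\n",
              atomCount(object), residueCount(object),
              paste(unique(object@resname)[1:min(3, length(unique(object@resname)))],
                    collapse = ", ")))
})

setMethod("show", "PotentialSurface", function(object) {
  cat(sprintf("PotentialSurface '%s' (%s coordinates)\n", object@name,
              if (is.na(object@dim)) "any" else object@dim))
})

setMethod("show", "ADMDConfig", function(object) {
  cat(sprintf("ADMDConfig: E = %g, T = %g, muE = %s, muK = %s\n",
              object@targetEnergy, object@temperature,
              format(object@muE), format(object@muK)))
  cat(sprintf("  delta = %g, P schedule: %s\n", object@delta,
              paste(object@PSchedule, collapse = " -> ")))
  cat(sprintf("  seed = %d, gradTol = %g, maxIter = %d, conservationTol = %g\n",
              object@seed, object@gradTol, object@maxIter,
              object@conservationTol))
})

setMethod("show", "ActionBreakdown", function(object) {
  cat(sprintf("ActionBreakdown: Phi = %.6g\n", object@phi))
  cat(sprintf("  S = %.6g, energy penalty = %.6g, kinetic restraint = %.6g\n",
              object@S, object@energyPenalty, object@kineticRestraint))
  cat(sprintf("  frame energies: mean %.6g, sd %.3g (%d frames)\n",
              mean(object@frameEnergies), stats::sd(object@frameEnergies),
              length(object@frameEnergies)))
})

setMethod("show", "PathwaySolution", function(object) {
  cat(sprintf("PathwaySolution: P = %d, %senergy-conserving\n",
              frameCount(object@path),
              if (object@energyConserved) "" else "NOT "))
  cat(sprintf("  Phi = %.6g, barrier = %.6g, sd(E_j) = %.3g\n",
              object@breakdown@phi, object@barrier,
              stats::sd(object@breakdown@frameEnergies)))
  cat(sprintf("  multigrid levels: %d, evaluations: %s\n",
              length(object@iterations),
              paste(object@iterations, collapse = ", ")))
})

setMethod("show", "PCAResult", function(object) {
  nshow <- min(3L, length(object@values))
  cat(sprintf("PCAResult: %d modes over %d frames\n", length(object@values),
              nrow(object@projections)))
  cat("  leading variance fractions:",
      paste(sprintf("%.1f%%", 100 * object@varianceFractions[1:nshow]),
            collapse = ", "), "\n")
})
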